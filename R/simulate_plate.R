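# Ellman/Bradford plate generator. 406-nm sample absorbances are produced by
# inverting the reduction model from the arm's inhibition truth, so that a
# noiseless plate round-trips exactly through reduce_plate().

#' Simulate a 96-well assay plate for one treatment arm
#'
#' A plate carries, in long format: a Bradford standard series (595 nm),
#' blank wells (406 nm), control sample wells (no inhibitor), and — for
#' inhibitor arms — `replicates` sample wells per concentration. Every sample
#' well has paired 406-nm and 595-nm reads. Per-well 406-nm absorbance is
#' `blank + true_activity * (1 - inhibition(c)/100) * epsilon * path * mg /
#' volume` plus Gaussian read noise.
#'
#' @param preset An [assay_preset()].
#' @param arm Treatment arm, one of `names(arm_truths())`.
#' @param seed Integer seed.
#' @return Object of class `assay_plate`: a data.frame `wells` with columns
#'   `well`, `role` (sample / bradford_standard / blank), `wavelength_nm`,
#'   `absorbance`, `concentration_uM`, `replicate`, `arm`, plus the `arm`,
#'   `truth` (per-well true activity) and `calibration` attributes.
#' @export
#' @examples
#' p <- simulate_assay_plate(assay_preset(absorbance_noise_sd = 0), "bend", seed = 1)
#' head(p$wells)
simulate_assay_plate <- function(preset, arm, seed) {
  stopifnot(inherits(preset, "assay_preset"))
  truth_model <- if (!is.null(preset$inhibition_truth)) preset$inhibition_truth
                 else arm_truth(arm)

  cal <- preset$calibration
  # µmol of product per absorbance unit at 406 nm
  umol_per_au <- cal$well_volume / (cal$epsilon_tnb * cal$path_length)
  mg_per_well <- preset$protein_per_well * cal$well_volume / 1000

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  rows <- list()
  true_act <- list()
  nz <- function(k) if (preset$absorbance_noise_sd > 0)
    stats::rnorm(k, 0, preset$absorbance_noise_sd) else numeric(k)
  wid <- 0
  add <- function(role, wl, absorb, conc, repl, arm_lab) {
    wid <<- wid + 1
    rows[[length(rows) + 1]] <<- data.frame(
      well = sprintf("W%02d", wid), role = role, wavelength_nm = wl,
      absorbance = pmax(absorb, 0), concentration_uM = conc,
      replicate = repl, arm = arm_lab)
  }

  # Bradford standards (595 nm only)
  for (cs in cal$bradford_standard_concs) {
    a <- preset$bradford_intercept + preset$bradford_slope * cs + nz(1)
    add("bradford_standard", 595, a, NA_real_, NA_integer_, NA_character_)
  }
  # blank wells (406 nm only)
  for (k in seq_len(3)) {
    add("blank", 406, preset$blank_absorbance + nz(1), NA_real_,
        k, NA_character_)
  }

  sample_well <- function(conc, repl, arm_lab, inh_pct) {
    act <- preset$true_activity * (1 - inh_pct / 100)
    a406 <- preset$blank_absorbance + act * mg_per_well / umol_per_au + nz(1)
    a595 <- preset$bradford_intercept +
      preset$bradford_slope * preset$protein_per_well + nz(1)
    wid_before <- wid + 1
    add("sample", 406, a406, conc, repl, arm_lab)
    rows[[length(rows) + 1]] <<- data.frame(
      well = sprintf("W%02d", wid_before), role = "sample",
      wavelength_nm = 595, absorbance = max(a595, 0),
      concentration_uM = conc, replicate = repl, arm = arm_lab)
    true_act[[length(true_act) + 1]] <<- data.frame(
      well = sprintf("W%02d", wid_before), arm = arm_lab,
      concentration_uM = conc, true_activity = act)
  }

  # control wells on every plate (uninhibited)
  for (k in seq_len(preset$replicates)) {
    sample_well(NA_real_, k, "control", 0)
  }
  # dose series for inhibitor arms
  if (!identical(arm, "control") && length(preset$concentrations)) {
    for (conc in preset$concentrations) {
      inh <- if (is.null(truth_model)) 0 else predict(truth_model, conc)
      for (k in seq_len(preset$replicates)) {
        sample_well(conc, k, arm, inh)
      }
    }
  }

  wells <- do.call(rbind, rows)
  rownames(wells) <- NULL
  structure(list(wells = wells, arm = arm,
                 truth = do.call(rbind, true_act),
                 calibration = cal),
            class = "assay_plate")
}

#' Write / read an assay plate as long-format CSV
#'
#' @param plate An `assay_plate`.
#' @param path CSV file path.
#' @return `read_plate()` returns an `assay_plate` (without generator truth).
#' @export
write_plate <- function(plate, path) {
  utils::write.csv(plate$wells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate
#' @export
read_plate <- function(path, calibration = assay_calibration()) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("well", "role", "wavelength_nm", "absorbance",
              "concentration_uM", "replicate", "arm")
  if (!all(needed %in% names(wells)))
    stop("plate CSV must have columns: ", paste(needed, collapse = ", "))
  arms <- unique(stats::na.omit(wells$arm))
  structure(list(wells = wells,
                 arm = if (length(arms)) arms[length(arms)] else NA_character_,
                 truth = NULL, calibration = calibration),
            class = "assay_plate")
}
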