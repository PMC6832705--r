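# Reduction of Ellman/Bradford plate absorbances to specific AChE
# activities, percent-of-control normalization, and log-logistic
# dose-inhibition fitting with ED50 comparisons.

#' Fit a Bradford calibration line
#'
#' Ordinary least-squares line through the standard series; the inverse map
#' converts a 595-nm absorbance to protein concentration.
#'
#' @param standards data.frame with columns `conc` (mg/mL) and `a595` (AU),
#'   at least two distinct concentrations.
#' @return Object of class `bradford_fit`: `slope`, `intercept`,
#'   `inverse(a595)`.
#' @export
fit_bradford <- function(standards) {
  stopifnot(is.data.frame(standards), all(c("conc", "a595") %in% names(standards)))
  if (length(unique(standards$conc)) < 2)
    stop("need at least 2 distinct Bradford standards")
  fit <- stats::lm(a595 ~ conc, data = standards)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || abs(slope) < 1e-12)
    stop("degenerate Bradford standards: zero slope")
  structure(list(slope = slope, intercept = intercept,
                 inverse = function(a595) (a595 - intercept) / slope),
            class = "bradford_fit")
}

#' Reduce a plate to specific AChE activities
#'
#' Per sample well: the blank-corrected 406-nm absorbance is converted to
#' µmol of hydrolyzed substrate via the TNB molar absorptivity and optical
#' path (`µmol = A406 * volume / (epsilon * path)`), and divided by the mg of
#' protein obtained from that well's 595-nm read through the plate's Bradford
#' line. Activities are per total incubation, µmol/mg protein. Wells whose
#' inferred protein is non-positive are flagged invalid.
#'
#' @param plate An `assay_plate`.
#' @param calibration An [assay_calibration()]; defaults to the plate's own.
#' @return data.frame with columns `well`, `arm`, `concentration_uM`,
#'   `replicate`, `protein_mg_ml`, `activity` (µmol/mg protein), `valid`.
#' @export
reduce_plate <- function(plate, calibration = NULL) {
  stopifnot(inherits(plate, "assay_plate"))
  cal <- if (is.null(calibration)) plate$calibration else calibration
  w <- plate$wells

  std <- w[w$role == "bradford_standard" & w$wavelength_nm == 595, ]
  if (!nrow(std)) stop("plate has no Bradford standards")
  std_concs <- cal$bradford_standard_concs
  if (nrow(std) != length(std_concs))
    stop("Bradford standard wells do not match the calibration series")
  brad <- fit_bradford(data.frame(conc = std_concs, a595 = std$absorbance))

  blank <- w[w$role == "blank" & w$wavelength_nm == 406, ]
  blank_a <- if (nrow(blank)) mean(blank$absorbance) else 0

  s406 <- w[w$role == "sample" & w$wavelength_nm == 406, ]
  s595 <- w[w$role == "sample" & w$wavelength_nm == 595, ]
  if (!nrow(s406)) stop("plate has no sample wells")
  m <- match(s406$well, s595$well)
  if (anyNA(m))
    stop("missing paired 595 nm read for sample well(s): ",
         paste(s406$well[is.na(m)], collapse = ", "))

  umol_per_au <- cal$well_volume / (cal$epsilon_tnb * cal$path_length)
  protein_conc <- brad$inverse(s595$absorbance[m])
  mg <- protein_conc * cal$well_volume / 1000
  valid <- mg > 0
  activity <- rep(NA_real_, nrow(s406))
  activity[valid] <- pmax(s406$absorbance[valid] - blank_a, 0) *
    umol_per_au / mg[valid]
  data.frame(well = s406$well, arm = s406$arm,
             concentration_uM = s406$concentration_uM,
             replicate = s406$replicate,
             protein_mg_ml = protein_conc,
             activity = activity, valid = valid)
}

#' Normalize activities to percent of control
#'
#' @param results data.frame from [reduce_plate()] (rows from several plates
#'   may be concatenated).
#' @param control_arm Name of the uninhibited arm.
#' @return data.frame of inhibition points: `arm`, `concentration_uM`,
#'   `replicate`, `percent_activity`, `inhibition` (= 100 - percent_activity).
#' @export
percent_of_control <- function(results, control_arm = "control") {
  ctrl <- results$activity[results$arm == control_arm & results$valid]
  if (!length(ctrl)) stop("no control-arm wells found (arm '", control_arm, "')")
  ctrl_mean <- mean(ctrl)
  if (!is.finite(ctrl_mean) || ctrl_mean <= 0)
    stop("control-arm mean activity must be positive")
  s <- results[results$arm != control_arm & results$valid, ]
  pa <- 100 * s$activity / ctrl_mean
  data.frame(arm = s$arm, concentration_uM = s$concentration_uM,
             replicate = s$replicate, percent_activity = pa,
             inhibition = 100 - pa)
}

#' Fit a log-logistic dose-inhibition curve
#'
#' Unweighted nonlinear least squares of
#' `inhibition = imax / (1 + (ed50/x)^slope)` (lower bound fixed at 0) with
#' multi-start initialization over a grid of (imax, slope, ed50) and
#' Levenberg-Marquardt refinement; replicates enter individually.
#'
#' @param points data.frame with columns `concentration_uM` and `inhibition`
#'   (percent).
#' @param fix_imax Optional fixed upper asymptote, percent.
#' @return Object of class `log_logistic_fit`: `imax`, `slope`, `ed50`,
#'   `se` (named vector of asymptotic standard errors), `sse`, `n`,
#'   `fixed_imax`.
#' @export
fit_log_logistic <- function(points, fix_imax = NULL) {
  stopifnot(all(c("concentration_uM", "inhibition") %in% names(points)))
  pts <- points[is.finite(points$inhibition) & points$concentration_uM > 0, ]
  ncon <- length(unique(pts$concentration_uM))
  need <- if (is.null(fix_imax)) 3 else 2
  if (ncon < need)
    stop("need at least ", need, " distinct concentrations")
  if (all(abs(pts$inhibition) < 1e-9))
    stop("all inhibition values are zero; no curve to fit")

  x <- pts$concentration_uM
  y <- pts$inhibition
  ed50_grid <- exp(seq(log(min(x)), log(max(x)), length.out = 10))
  slope_grid <- seq(0.5, 4, length.out = 8)
  imax_grid <- if (is.null(fix_imax)) seq(50, 100, length.out = 5) else fix_imax

  best <- NULL
  best_sse <- Inf
  for (im in imax_grid) for (sl in slope_grid) for (e0 in ed50_grid) {
    fit <- tryCatch({
      if (is.null(fix_imax)) {
        minpack.lm::nlsLM(y ~ imax / (1 + (ed50 / x)^slope),
                          start = list(imax = im, slope = sl, ed50 = e0),
                          lower = c(imax = 1e-6, slope = 1e-6, ed50 = 1e-12),
                          upper = c(imax = 100, slope = 50, ed50 = Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(y ~ fix_imax / (1 + (ed50 / x)^slope),
                          start = list(slope = sl, ed50 = e0),
                          lower = c(slope = 1e-6, ed50 = 1e-12),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (sse < best_sse - 1e-10) {
        best_sse <- sse
        best <- fit
      }
    }
  }
  if (is.null(best))
    stop("log-logistic fit did not converge from any start (best SSE ",
         format(best_sse), ")")

  cf <- stats::coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  out <- list(imax = if (is.null(fix_imax)) unname(cf["imax"]) else fix_imax,
              slope = unname(cf["slope"]),
              ed50 = unname(cf["ed50"]),
              se = se, sse = best_sse, n = nrow(pts),
              fixed_imax = !is.null(fix_imax))
  class(out) <- c("log_logistic_fit", "log_logistic_model")
  out
}

#' @export
print.log_logistic_fit <- function(x, ...) {
  cat(sprintf(paste0("log-logistic dose-inhibition fit (n = %d, SSE = %.4g)\n",
                     "  imax  = %8.3f %%%s\n  slope = %8.3f\n  ED50  = %8.4g uM\n"),
              x$n, x$sse, x$imax, if (x$fixed_imax) " (fixed)" else "",
              x$slope, x$ed50))
  invisible(x)
}

#' Percent change in ED50 between two fitted curves
#'
#' `100 * (ed50_a - ed50_b) / ed50_a`: positive when curve `b` is shifted
#' toward lower concentrations (the compound became more potent).
#'
#' @param model_a,model_b `log_logistic_model` / `log_logistic_fit` objects.
#' @return Percent change, dimensionless.
#' @export
ed50_shift <- function(model_a, model_b) {
  100 * (model_a$ed50 - model_b$ed50) / model_a$ed50
}
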