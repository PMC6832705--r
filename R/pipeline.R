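# Pipeline configuration and the end-to-end driver wiring presets ->
# generators -> analyzers -> report.

.known_config_keys <- c("seed", "output_dir", "cohorts", "thresholds",
                        "preset_catalogue")
.known_cohort_keys <- c("traces", "plates", "images")
.known_threshold_keys <- c("depth_criterion", "min_duration", "max_gap",
                           "alpha", "blur_sigma", "threshold_frac")

#' Default pipeline configuration
#'
#' Cohort sizes follow the documented study design: 10 traces per
#' electrophysiology arm, 3 plates per assay arm, 15 images per imaging arm.
#'
#' @param seed Global seed.
#' @param output_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(seed = 1, output_dir = "results") {
  structure(list(
    seed = seed,
    output_dir = output_dir,
    cohorts = list(traces = 10, plates = 3, images = 15),
    thresholds = list(depth_criterion = 5, min_duration = 0.5, max_gap = 0.3,
                      alpha = 0.05, blur_sigma = 2, threshold_frac = 0.5),
    preset_catalogue = NA_character_),
    class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list; checks invariants and aggregates all
#' violations into one error. Unknown keys yield a warning (forward
#' compatibility), not an error.
#'
#' @param config Path to a YAML config, or a list.
#' @return A validated `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  base <- unclass(default_config())
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in intersect(names(config), .known_config_keys)) {
    if (k %in% c("cohorts", "thresholds")) {
      sub <- config[[k]]
      known <- if (k == "cohorts") .known_cohort_keys else .known_threshold_keys
      bad <- setdiff(names(sub), known)
      if (length(bad))
        warning("ignoring unknown ", k, " key(s): ", paste(bad, collapse = ", "))
      for (kk in intersect(names(sub), known)) base[[k]][[kk]] <- sub[[kk]]
    } else {
      base[[k]] <- config[[k]]
    }
  }
  errors <- character(0)
  if (!is.numeric(base$seed) || base$seed != round(base$seed))
    errors <- c(errors, "seed must be an integer")
  for (kk in .known_cohort_keys) {
    v <- base$cohorts[[kk]]
    if (!is.numeric(v) || v < 2)
      errors <- c(errors, paste0("cohorts$", kk, " must be a number >= 2"))
  }
  th <- base$thresholds
  if (!is.numeric(th$depth_criterion) || th$depth_criterion <= 0)
    errors <- c(errors, "thresholds$depth_criterion must be > 0")
  if (!is.numeric(th$min_duration) || th$min_duration <= 0)
    errors <- c(errors, "thresholds$min_duration must be > 0")
  if (!is.numeric(th$max_gap) || th$max_gap < 0)
    errors <- c(errors, "thresholds$max_gap must be >= 0")
  if (!is.numeric(th$alpha) || th$alpha <= 0 || th$alpha >= 1)
    errors <- c(errors, "thresholds$alpha must be in (0, 1)")
  if (!is.na(base$preset_catalogue) && !file.exists(base$preset_catalogue))
    errors <- c(errors, paste0("preset catalogue not found: ",
                               base$preset_catalogue))
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  structure(base, class = "pipeline_config")
}

.presets_from_config <- function(config) {
  if (!is.na(config$preset_catalogue)) read_presets(config$preset_catalogue)
  else lapply(list_presets(), `[[`, "preset")
}

#' Run the electrophysiology arm of the pipeline
#'
#' Simulates a cohort per ephys preset, analyzes every trace, and compares
#' cohort RSH across arms by ANOVA/Tukey.
#'
#' @param config A `pipeline_config`.
#' @param presets Named preset list (defaults to the shipped catalogue).
#' @return List with `per_trace` (data.frame), `cohorts` (data.frame),
#'   `anova` (`anova_result`), `tukey` (`tukey_result`).
#' @export
run_ephys <- function(config = default_config(),
                      presets = NULL) {
  if (is.null(presets)) presets <- .presets_from_config(config)
  arms <- grep("_ephys$", names(presets), value = TRUE)
  th <- config$thresholds
  per_trace <- list()
  for (arm in arms) {
    cohort <- simulate_trace_cohort(presets[[arm]], n = config$cohorts$traces,
                                    seed = config$seed, label = arm)
    for (i in seq_along(cohort)) {
      an <- analyze_trace(cohort[[i]]$trace,
                          depth_criterion = th$depth_criterion,
                          min_duration = th$min_duration,
                          max_gap = th$max_gap)
      per_trace[[length(per_trace) + 1]] <- data.frame(
        arm = arm, trace = i, seed = config$seed + i - 1,
        baseline_mV = an$baseline$value,
        firing_rate_hz = an$firing_rate_hz,
        rsh_mVs = an$rsh$rsh,
        duration_s = an$rsh$duration,
        fallback = an$window$fallback)
    }
  }
  per_trace <- do.call(rbind, per_trace)
  cohorts <- do.call(rbind, lapply(split(per_trace, per_trace$arm), function(d)
    data.frame(arm = d$arm[1], n = nrow(d),
               mean_rsh = mean(d$rsh_mVs),
               se_rsh = stats::sd(d$rsh_mVs) / sqrt(nrow(d)),
               mean_duration = mean(d$duration_s),
               se_duration = stats::sd(d$duration_s) / sqrt(nrow(d)))))
  rownames(cohorts) <- NULL
  tab <- data.frame(group = per_trace$arm, value = per_trace$rsh_mVs)
  list(per_trace = per_trace, cohorts = cohorts,
       anova = one_way_anova(tab),
       tukey = tukey_hsd(tab, alpha = th$alpha))
}

#' Run the dose-response arm of the pipeline
#'
#' Control-arm plates give the specific-activity summary; each inhibitor arm
#' is fitted with the log-logistic model; arms are compared at 0.5 µM by
#' ANOVA/Tukey on percent activity.
#'
#' @param config A `pipeline_config`.
#' @param presets Named preset list.
#' @param comparison_conc Concentration (µM) for the arm comparison.
#' @return List with `control_activity`, `fits`, `shifts`,
#'   `comparison` (`tukey_result` or NULL), `inhibition_points`.
#' @export
run_assay <- function(config = default_config(), presets = NULL,
                      comparison_conc = 0.5) {
  if (is.null(presets)) presets <- .presets_from_config(config)
  n_plates <- config$cohorts$plates
  seeds <- config$seed + seq_len(n_plates) - 1

  # control arm: mean specific activity over plates
  ctrl_acts <- unlist(lapply(seeds, function(s) {
    red <- reduce_plate(simulate_assay_plate(presets[["control_assay"]],
                                             "control", seed = s))
    red$activity[red$valid]
  }))
  control_activity <- data.frame(mean = mean(ctrl_acts),
                                 se = stats::sd(ctrl_acts) /
                                   sqrt(length(ctrl_acts)),
                                 n_wells = length(ctrl_acts),
                                 n_plates = n_plates)

  fit_arms <- intersect(c("bend", "ment_bend", "phent_ment_bend",
                          "ipkc_ment_bend", "ipka_ment_bend"),
                        names(presets))
  fits <- list()
  points_all <- list()
  for (arm in fit_arms) {
    plate <- simulate_assay_plate(presets[[arm]], arm, seed = config$seed)
    pts <- percent_of_control(reduce_plate(plate), control_arm = "control")
    points_all[[arm]] <- pts
    fits[[arm]] <- fit_log_logistic(pts)
  }
  shifts <- if ("bend" %in% names(fits)) {
    do.call(rbind, lapply(setdiff(names(fits), "bend"), function(arm)
      data.frame(from = "bend", to = arm,
                 ed50_from = fits[["bend"]]$ed50, ed50_to = fits[[arm]]$ed50,
                 shift_pct = ed50_shift(fits[["bend"]], fits[[arm]]))))
  } else NULL

  pts <- do.call(rbind, points_all)
  at_c <- pts[abs(pts$concentration_uM - comparison_conc) < 1e-9, ]
  comparison <- NULL
  if (nrow(at_c) && length(unique(at_c$arm)) >= 2) {
    comparison <- tukey_hsd(data.frame(group = at_c$arm,
                                       value = at_c$percent_activity),
                            alpha = config$thresholds$alpha)
  }
  list(control_activity = control_activity, fits = fits, shifts = shifts,
       comparison = comparison, inhibition_points = pts)
}

#' Run the calcium-imaging arm of the pipeline
#'
#' @param config A `pipeline_config`.
#' @param presets Named preset list.
#' @return List with `per_image`, `cohorts`, `anova`, `tukey`.
#' @export
run_imaging <- function(config = default_config(), presets = NULL) {
  if (is.null(presets)) presets <- .presets_from_config(config)
  arms <- grep("_calcium$", names(presets), value = TRUE)
  th <- config$thresholds
  per_image <- do.call(rbind, lapply(arms, function(arm) {
    cohort <- simulate_image_cohort(presets[[arm]],
                                    n = config$cohorts$images,
                                    seed = config$seed, label = arm)
    quantify_image_cohort(cohort, blur_sigma = th$blur_sigma,
                          threshold_frac = th$threshold_frac)
  }))
  cohorts <- summarize_groups(data.frame(group = per_image$label,
                                         value = per_image$mgv))
  tab <- data.frame(group = per_image$label, value = per_image$mgv)
  list(per_image = per_image, cohorts = cohorts,
       anova = one_way_anova(tab),
       tukey = tukey_hsd(tab, alpha = th$alpha))
}

#' Run the full pipeline
#'
#' Generates all synthetic cohorts, runs the three analyses and the group
#' statistics, and writes the intermediate tables plus the final JSON report
#' into the configured output directory. Any stage error aborts with the
#' stage name; artifacts written before the failure are preserved.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @return Invisibly, the report path.
#' @export
run_all <- function(config = default_config()) {
  config <- validate_config(config)
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  presets <- stage("presets", .presets_from_config(config))

  ephys <- stage("ephys", run_ephys(config, presets))
  utils::write.csv(ephys$per_trace, file.path(outdir, "ephys_per_trace.csv"),
                   row.names = FALSE)
  utils::write.csv(ephys$cohorts, file.path(outdir, "ephys_cohorts.csv"),
                   row.names = FALSE)

  assay <- stage("assay", run_assay(config, presets))
  utils::write.csv(assay$inhibition_points,
                   file.path(outdir, "assay_inhibition_points.csv"),
                   row.names = FALSE)

  imaging <- stage("imaging", run_imaging(config, presets))
  utils::write.csv(imaging$per_image, file.path(outdir, "mgv_per_image.csv"),
                   row.names = FALSE)

  report <- stage("report", build_report(
    ephys = list(cohorts = ephys$cohorts,
                 anova = unclass(ephys$anova),
                 letters = as.list(ephys$tukey$letters)),
    fits = list(control_activity = assay$control_activity,
                models = lapply(assay$fits, function(f)
                  list(imax = f$imax, slope = f$slope, ed50 = f$ed50)),
                shifts = assay$shifts,
                comparison_letters = if (is.null(assay$comparison)) NULL
                                     else as.list(assay$comparison$letters)),
    mgv = list(cohorts = imaging$cohorts,
               anova = unclass(imaging$anova),
               letters = as.list(imaging$tukey$letters)),
    seed = config$seed, config = config))
  path <- file.path(outdir, "report.json")
  write_report(report, path)
  invisible(path)
}
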