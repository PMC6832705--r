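# Pacemaker voltage-trace generator.
#
# A trace is baseline + recording noise + a train of template action
# potentials (raised-cosine depolarization followed by a raised-cosine AHP
# undershoot) + an optional programmed hyperpolarizing response episode with
# exponential onset/offset ramps + a brief depolarizing saline-application
# artifact. Spikes are suppressed while the programmed deviation is more
# than 1 mV below baseline.

# margin (mV) below baseline beyond which spiking is switched off
.spike_suppress_margin <- 1

#' Programmed response-deviation profile
#'
#' Deviation from baseline (mV) of the drug-induced episode at times `t`:
#' zero before onset, exponential approach to the plateau depth during the
#' plateau interval, exponential relaxation afterwards. With zero time
#' constants the episode is rectangular over `[onset, onset + plateau)`.
#'
#' @param t Sample times, s.
#' @param onset Episode onset time, s.
#' @param plateau Programmed plateau duration, s.
#' @param depth Plateau depth, mV (<= 0).
#' @param tau_on,tau_off Onset/offset ramp time constants, s.
#' @return Numeric vector of deviations, mV.
#' @export
response_profile <- function(t, onset, plateau, depth, tau_on, tau_off) {
  dev <- numeric(length(t))
  if (depth == 0 || plateau <= 0) return(dev)
  t1 <- onset + plateau
  during <- t >= onset & t < t1
  after <- t >= t1
  if (tau_on > 0) {
    dev[during] <- depth * (1 - exp(-(t[during] - onset) / tau_on))
    v_end <- depth * (1 - exp(-plateau / tau_on))
  } else {
    dev[during] <- depth
    v_end <- depth
  }
  if (tau_off > 0) {
    dev[after] <- v_end * exp(-(t[after] - t1) / tau_off)
  }
  dev
}

# raised-cosine bump of unit amplitude over [0, width]
.bump <- function(t_rel, width) sin(pi * t_rel / width)^2

#' Simulate a DUM-neuron voltage trace
#'
#' Generates one seeded trace together with its ground truth (emitted spike
#' times, programmed episode bounds and the discretized integral of the
#' programmed deviation profile).
#'
#' @param preset A [trace_preset()].
#' @param seed Integer seed; identical preset + seed gives bit-identical
#'   output.
#' @param label Treatment label stored on the trace.
#' @return A list with elements `trace` (class `voltage_trace`: `samples` in
#'   mV, `sampling_rate`, `application_time`, `label`) and `truth` (class
#'   `trace_truth`: `spike_times`, `response_start`, `response_end`,
#'   `response_duration`, `programmed_area` in mV*s).
#' @export
#' @examples
#' st <- simulate_voltage_trace(trace_preset(duration = 20, application_time = 10), seed = 1)
#' length(st$trace$samples)
simulate_voltage_trace <- function(preset, seed, label = "trace") {
  validate_trace_preset(preset)
  fs <- preset$sampling_rate
  dt <- 1 / fs
  n <- round(preset$duration * fs)
  t <- (seq_len(n) - 1) * dt

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  v <- rep(preset$baseline_potential, n)
  if (preset$noise_sd > 0) v <- v + stats::rnorm(n, 0, preset$noise_sd)

  # programmed response episode
  plateau <- 0
  onset <- NA_real_
  if (preset$response_depth < 0 && preset$response_duration_mean > 0) {
    plateau <- stats::rnorm(1, preset$response_duration_mean,
                            preset$response_duration_sd)
    plateau <- max(plateau, 1)
    onset <- preset$application_time + preset$response_onset_delay
  }
  dev <- response_profile(t, onset = if (is.na(onset)) 0 else onset,
                          plateau = plateau,
                          depth = preset$response_depth,
                          tau_on = preset$response_onset_tau,
                          tau_off = preset$response_offset_tau)
  v <- v + dev

  # saline-application artifact (depolarizing raised cosine)
  if (preset$saline_artifact_depol > 0 && preset$saline_artifact_duration > 0) {
    ta <- preset$application_time
    idx <- which(t >= ta & t < ta + preset$saline_artifact_duration)
    if (length(idx))
      v[idx] <- v[idx] + preset$saline_artifact_depol *
        .bump(t[idx] - ta, preset$saline_artifact_duration)
  }

  # pacemaker spike train with jitter; spikes suppressed during the episode
  spike_times <- numeric(0)
  w <- preset$spike_width / 1000
  ahp_T <- preset$ahp_duration / 1000
  if (preset$firing_rate > 0) {
    isi <- 1 / preset$firing_rate
    first <- stats::runif(1, 0, isi)
    grid <- seq(first, preset$duration, by = isi)
    jit <- stats::rnorm(length(grid), 0, preset$spike_jitter_sd)
    starts <- grid + jit
    starts <- starts[starts >= 0 & starts + w + ahp_T < preset$duration]
    dev_at <- response_profile(starts, onset = if (is.na(onset)) 0 else onset,
                               plateau = plateau,
                               depth = preset$response_depth,
                               tau_on = preset$response_onset_tau,
                               tau_off = preset$response_offset_tau)
    starts <- starts[dev_at > -.spike_suppress_margin]
    for (ts in starts) {
      i0 <- floor(ts * fs) + 1
      i1 <- min(floor((ts + w) * fs) + 1, n)
      if (i1 > i0)
        v[i0:i1] <- v[i0:i1] + preset$spike_amplitude *
          .bump(pmin(pmax(t[i0:i1] - ts, 0), w), w)
      j0 <- i1 + 1
      j1 <- min(floor((ts + w + ahp_T) * fs) + 1, n)
      if (j1 >= j0)
        v[j0:j1] <- v[j0:j1] - preset$ahp_depth *
          .bump(pmin(pmax(t[j0:j1] - ts - w, 0), ahp_T), ahp_T)
    }
    spike_times <- starts + w / 2  # truth records peak times
  }

  trace <- structure(list(samples = v,
                          sampling_rate = fs,
                          application_time = preset$application_time,
                          label = label),
                     class = "voltage_trace")
  truth <- structure(list(spike_times = spike_times,
                          response_start = onset,
                          response_end = if (is.na(onset)) NA_real_ else onset + plateau,
                          response_duration = if (is.na(onset)) 0 else plateau,
                          programmed_area = sum(dev) * dt),
                     class = "trace_truth")
  list(trace = trace, truth = truth)
}

#' Simulate a cohort of voltage traces
#'
#' @param preset A [trace_preset()].
#' @param n Number of traces.
#' @param seed Base seed; trace i uses `seed + i - 1`.
#' @param label Treatment label.
#' @return List of `simulate_voltage_trace()` results.
#' @export
simulate_trace_cohort <- function(preset, n, seed, label = "trace") {
  lapply(seq_len(n), function(i)
    simulate_voltage_trace(preset, seed = seed + i - 1, label = label))
}

# save/restore global RNG state so seeded generators do not disturb the
# caller's random stream
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write / read a voltage trace as delimited text with a JSON truth sidecar
#'
#' The trace is written as two-column tab-separated text (`time_s`,
#' `potential_mV`); the ground truth, when given, goes to `<path>.json`.
#'
#' @param st Result of [simulate_voltage_trace()], or a `voltage_trace`.
#' @param path File path for the delimited text.
#' @return `read_trace()` returns a list with `trace` and (if the sidecar
#'   exists) `truth`.
#' @export
write_trace <- function(st, path) {
  trace <- if (inherits(st, "voltage_trace")) st else st$trace
  n <- length(trace$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / trace$sampling_rate,
                   potential_mV = trace$samples)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(sampling_rate = trace$sampling_rate,
               application_time = trace$application_time,
               label = trace$label)
  if (!inherits(st, "voltage_trace") && !is.null(st$truth))
    meta$truth <- unclass(st$truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing sidecar ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  trace <- structure(list(samples = df$potential_mV,
                          sampling_rate = meta$sampling_rate,
                          application_time = meta$application_time,
                          label = meta$label),
                     class = "voltage_trace")
  truth <- NULL
  if (!is.null(meta$truth))
    truth <- structure(meta$truth, class = "trace_truth")
  list(trace = trace, truth = truth)
}
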