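# Quantification of drug responses in spontaneously active neuron traces:
# baseline estimation, spike detection, response-window detection, and the
# RSH (relative size of hyperpolarization) area statistic.

#' Estimate the pre-application baseline potential
#'
#' Median of the pre-application samples after masking a window around each
#' detected action potential (the mask must cover the AHP undershoot,
#' otherwise the estimate is dragged below the true interspike potential).
#'
#' @param trace A `voltage_trace`.
#' @param spike_mask Two values, s: mask extent before and after each spike
#'   peak. The default covers the template AHP.
#' @param threshold_margin,refractory Passed to [detect_spikes()] for the
#'   masking pass.
#' @return Object of class `baseline_estimate` with fields `value` (mV),
#'   `method`, `pre_window` (s).
#' @export
estimate_baseline <- function(trace, spike_mask = c(0.02, 0.30),
                              threshold_margin = 20, refractory = 0.05) {
  fs <- trace$sampling_rate
  app <- trace$application_time
  if (is.null(app) || app < 1)
    stop("insufficient pre-application data: need >= 1 s before application")
  n_pre <- floor(app * fs)
  v <- trace$samples[seq_len(n_pre)]
  t <- (seq_len(n_pre) - 1) / fs
  rough <- stats::median(v)
  pre_trace <- structure(list(samples = v, sampling_rate = fs,
                              application_time = app, label = trace$label),
                         class = "voltage_trace")
  sp <- detect_spikes(pre_trace, baseline = rough,
                      threshold_margin = threshold_margin,
                      refractory = refractory)
  keep <- rep(TRUE, n_pre)
  for (ts in sp$time) {
    keep[t >= ts - spike_mask[1] & t <= ts + spike_mask[2]] <- FALSE
  }
  value <- if (sum(keep) >= fs * 0.1) stats::median(v[keep]) else rough
  structure(list(value = value, method = "masked_median",
                 pre_window = c(0, app)),
            class = "baseline_estimate")
}

#' Detect action potentials
#'
#' Local maxima exceeding `baseline + threshold_margin`, thinned so that
#' successive detections are at least `refractory` apart.
#'
#' @param trace A `voltage_trace`.
#' @param baseline Baseline potential, mV (a `baseline_estimate` or a
#'   number).
#' @param threshold_margin Detection margin above baseline, mV.
#' @param refractory Minimal inter-spike interval, s.
#' @return data.frame with columns `time` (s, peak position) and `peak` (mV);
#'   zero rows when nothing crosses the threshold.
#' @export
detect_spikes <- function(trace, baseline, threshold_margin = 20,
                          refractory = 0.05) {
  b <- if (inherits(baseline, "baseline_estimate")) baseline$value else baseline
  v <- trace$samples
  n <- length(v)
  thr <- b + threshold_margin
  empty <- data.frame(time = numeric(0), peak = numeric(0))
  if (n < 3) return(empty)
  core <- 2:(n - 1)
  is_peak <- v[core] >= thr & v[core] > v[core + 1] & v[core] >= v[core - 1]
  idx <- core[is_peak]
  if (!length(idx)) return(empty)
  times <- (idx - 1) / trace$sampling_rate
  keep_t <- numeric(0)
  keep_p <- numeric(0)
  last <- -Inf
  for (k in seq_along(idx)) {
    if (times[k] - last >= refractory) {
      keep_t <- c(keep_t, times[k])
      keep_p <- c(keep_p, v[idx[k]])
      last <- times[k]
    }
  }
  data.frame(time = keep_t, peak = keep_p)
}

#' Firing frequency within a window
#'
#' @param spikes data.frame from [detect_spikes()].
#' @param window Two times, s, half-open `[start, end)`.
#' @return Frequency in Hz.
#' @export
firing_frequency <- function(spikes, window) {
  len <- window[2] - window[1]
  if (len <= 0) stop("window must have positive length")
  sum(spikes$time >= window[1] & spikes$time < window[2]) / len
}

#' Detect the post-application hyperpolarization window
#'
#' The response window runs from the first post-application sustained
#' excursion below `baseline - depth_criterion` until the potential re-crosses
#' that level for good. Brief returns above the criterion (the gaps between
#' AHP undershoots riding on the episode edges) shorter than `max_gap` are
#' bridged; an excursion only counts as a response if the bridged span lasts
#' at least `min_duration`. When no such excursion exists the conventional
#' fallback window of `fallback_duration` seconds after application is
#' returned with `fallback = TRUE`.
#'
#' @param trace A `voltage_trace`.
#' @param baseline A `baseline_estimate` or numeric baseline, mV.
#' @param depth_criterion Required depth below baseline, mV.
#' @param min_duration Minimal sustained (bridged) duration, s.
#' @param max_gap Maximal above-criterion gap that is bridged, s.
#' @param min_run Minimal length of a below-criterion run that counts as
#'   response evidence, s; shorter runs (isolated noise crossings) are
#'   discarded before bridging. AP-AHP undershoots (~0.1 s) survive this
#'   filter, single-sample noise excursions do not.
#' @param fallback_duration Length of the no-response window, s.
#' @return Object of class `response_window`: `start`, `end` (s), `fallback`.
#' @export
detect_response_window <- function(trace, baseline, depth_criterion = 5,
                                   min_duration = 0.5, max_gap = 0.3,
                                   min_run = 0.05, fallback_duration = 15) {
  b <- if (inherits(baseline, "baseline_estimate")) baseline$value else baseline
  fs <- trace$sampling_rate
  n <- length(trace$samples)
  app <- trace$application_time
  t_end_trace <- (n - 1) / fs
  if (t_end_trace < app + fallback_duration)
    stop("trace too short: need at least ", fallback_duration,
         " s after application")
  i_app <- floor(app * fs) + 1
  post <- trace$samples[i_app:n]
  below <- post < b - depth_criterion
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs <- runs[(runs$end - runs$start + 1) / fs >= min_run, ]
  win <- NULL
  if (nrow(runs)) {
    # bridge above-criterion gaps shorter than max_gap
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) {
      for (k in 2:nrow(runs)) {
        gap <- (runs$start[k] - merged$end[nrow(merged)] - 1) / fs
        if (gap <= max_gap) {
          merged$end[nrow(merged)] <- runs$end[k]
        } else {
          merged <- rbind(merged, runs[k, ])
        }
      }
    }
    dur <- (merged$end - merged$start) / fs
    ok <- which(dur >= min_duration)
    if (length(ok)) {
      k <- ok[1]
      win <- structure(list(
        start = app + (merged$start[k] - 1) / fs,
        end = app + (merged$end[k] - 1) / fs,
        fallback = FALSE), class = "response_window")
    }
  }
  if (is.null(win)) {
    win <- structure(list(start = app, end = app + fallback_duration,
                          fallback = TRUE),
                     class = "response_window")
  }
  win
}

#' Relative size of hyperpolarization (RSH)
#'
#' Signed time-integral (trapezoidal) of the deviation of the membrane
#' potential from baseline over the response window, in mV*s. Deviations of
#' both signs contribute: in control traces the AHP phase of each action
#' potential makes the statistic slightly negative, while a drug-induced
#' hyperpolarization makes it strongly negative.
#'
#' @param trace A `voltage_trace`.
#' @param baseline A `baseline_estimate` or numeric baseline, mV.
#' @param window A `response_window` (or list with `start`/`end` in s).
#' @return Object of class `rsh_result`: `rsh` (mV*s), `window`, `baseline`,
#'   `mean_deviation` (mV), `duration` (s).
#' @export
compute_rsh <- function(trace, baseline, window) {
  b <- if (inherits(baseline, "baseline_estimate")) baseline$value else baseline
  fs <- trace$sampling_rate
  n <- length(trace$samples)
  i0 <- floor(window$start * fs) + 1
  i1 <- floor(window$end * fs) + 1
  if (i0 < 1 || i1 > n || i1 <= i0)
    stop("response window lies outside the trace")
  dev <- trace$samples[i0:i1] - b
  m <- length(dev)
  dt <- 1 / fs
  rsh <- (sum(dev) - (dev[1] + dev[m]) / 2) * dt  # trapezoidal rule
  duration <- (m - 1) * dt
  structure(list(rsh = rsh,
                 window = window,
                 baseline = if (inherits(baseline, "baseline_estimate"))
                   baseline else list(value = b),
                 mean_deviation = rsh / duration,
                 duration = duration),
            class = "rsh_result")
}

#' Full per-trace electrophysiology analysis
#'
#' Baseline, spikes, pre-application firing rate, response window and RSH in
#' one call with the default thresholds (all overridable).
#'
#' @param trace A `voltage_trace`.
#' @param depth_criterion,min_duration,max_gap See
#'   [detect_response_window()].
#' @param threshold_margin,refractory See [detect_spikes()].
#' @return List with `baseline`, `spikes`, `firing_rate_hz` (pre-application),
#'   `window`, `rsh` (an `rsh_result`).
#' @export
analyze_trace <- function(trace, depth_criterion = 5, min_duration = 0.5,
                          max_gap = 0.3, threshold_margin = 20,
                          refractory = 0.05) {
  bl <- estimate_baseline(trace, threshold_margin = threshold_margin,
                          refractory = refractory)
  sp <- detect_spikes(trace, bl, threshold_margin = threshold_margin,
                      refractory = refractory)
  fr <- firing_frequency(sp, c(0, trace$application_time))
  win <- detect_response_window(trace, bl, depth_criterion = depth_criterion,
                                min_duration = min_duration,
                                max_gap = max_gap)
  rsh <- compute_rsh(trace, bl, win)
  list(baseline = bl, spikes = sp, firing_rate_hz = fr, window = win,
       rsh = rsh)
}

#' Summarize an RSH cohort
#'
#' Arithmetic mean and standard error (sd/sqrt(n)) of the RSH values of a
#' cohort, with the matching summaries of the detected window durations.
#'
#' @param results List of `rsh_result` objects (or a numeric vector of RSH
#'   values).
#' @return data.frame with one row: `mean`, `se`, `n`, and (for `rsh_result`
#'   input) `mean_duration`, `se_duration`, `n_fallback`.
#' @export
summarize_cohort <- function(results) {
  if (is.numeric(results)) {
    x <- results
    if (length(x) < 2) stop("need at least 2 observations")
    return(data.frame(mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
                      n = length(x)))
  }
  stopifnot(all(vapply(results, inherits, logical(1), "rsh_result")))
  if (length(results) < 2) stop("need at least 2 observations")
  x <- vapply(results, function(r) r$rsh, numeric(1))
  d <- vapply(results, function(r) r$duration, numeric(1))
  fb <- vapply(results, function(r) isTRUE(r$window$fallback), logical(1))
  data.frame(mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
             n = length(x),
             mean_duration = mean(d),
             se_duration = stats::sd(d) / sqrt(length(d)),
             n_fallback = sum(fb))
}
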