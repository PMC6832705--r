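# Independent oracles and small fixture builders used across the suite.

# Loop-based trapezoidal integral of (v - baseline) dt, written deliberately
# as a naive per-sample accumulation, independent of compute_rsh().
trapz_oracle <- function(v, baseline, dt) {
  s <- 0
  for (i in 2:length(v)) {
    s <- s + ((v[i - 1] - baseline) + (v[i] - baseline)) / 2 * dt
  }
  s
}

# a constant-potential trace
flat_trace <- function(value = -50, duration = 20, fs = 1000, app = 10) {
  structure(list(samples = rep(value, duration * fs), sampling_rate = fs,
                 application_time = app, label = "flat"),
            class = "voltage_trace")
}

# wrap a sample vector as a voltage_trace
as_trace <- function(v, fs, app) {
  structure(list(samples = v, sampling_rate = fs, application_time = app,
                 label = "test"), class = "voltage_trace")
}

# wrap a pixel matrix as a fluorescence_image
as_image <- function(px, um_per_pixel = 0.5, label = "test") {
  structure(list(pixels = px, um_per_pixel = um_per_pixel, label = label),
            class = "fluorescence_image")
}

# quiet trace preset used for deterministic episode geometry checks
quiet_preset <- function(...) {
  args <- list(noise_sd = 0, firing_rate = 0, saline_artifact_depol = 0,
               spike_jitter_sd = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(trace_preset, args)
}

# brute-force normal-equations slope/intercept for a straight-line fit
normal_equations_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# coarse grid-search oracle for the log-logistic least-squares problem
ll_grid_oracle <- function(conc, inh, imax_grid, slope_grid, ed50_grid) {
  best <- NULL
  best_sse <- Inf
  for (im in imax_grid) for (sl in slope_grid) for (e in ed50_grid) {
    pred <- im / (1 + (e / conc)^sl)
    sse <- sum((inh - pred)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- c(imax = im, slope = sl, ed50 = e)
    }
  }
  list(par = best, sse = best_sse)
}
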