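test_that("baseline of a constant trace is the constant", {
  bl <- estimate_baseline(flat_trace(value = -50))
  expect_equal(bl$value, -50)
  expect_identical(bl$method, "masked_median")
})

test_that("baseline of a generated control trace recovers the programmed potential", {
  st <- simulate_voltage_trace(get_preset("control_ephys"), seed = 1)
  bl <- estimate_baseline(st$trace)
  expect_lt(abs(bl$value - (-50)), 0.5)
})

test_that("spike masking makes the baseline robust to the spike train", {
  p_spiking <- trace_preset(noise_sd = 0.2, duration = 20, application_time = 10)
  p_clean <- trace_preset(noise_sd = 0.2, firing_rate = 0, duration = 20,
                          application_time = 10)
  b1 <- estimate_baseline(simulate_voltage_trace(p_spiking, seed = 5)$trace)
  b2 <- estimate_baseline(simulate_voltage_trace(p_clean, seed = 5)$trace)
  expect_lt(abs(b1$value - b2$value), 0.2)
})

test_that("baseline estimation refuses traces without pre-application data", {
  tr <- flat_trace(duration = 5, app = 0.5)
  expect_error(estimate_baseline(tr), "pre-application")
})

test_that("spike detection finds every programmed spike to sub-ms accuracy", {
  p <- trace_preset(duration = 20, application_time = 19)
  st <- simulate_voltage_trace(p, seed = 2)
  sp <- detect_spikes(st$trace, baseline = -50)
  expect_equal(nrow(sp), length(st$truth$spike_times))
  err <- abs(sp$time - st$truth$spike_times)
  expect_lt(max(err), 1e-3)
  expect_true(all(diff(sp$time) >= 0.05))
})

test_that("spike detection on a flat trace returns an empty table", {
  sp <- detect_spikes(flat_trace(), baseline = -50)
  expect_identical(nrow(sp), 0L)
})

test_that("firing frequency is count over window length", {
  expect_identical(firing_frequency(data.frame(time = numeric(0)), c(0, 15)), 0)
  sp <- data.frame(time = seq(0.25, by = 0.5, length.out = 30))
  expect_equal(firing_frequency(sp, c(0, 15)), 2)
  expect_error(firing_frequency(sp, c(3, 3)), "positive length")
})

test_that("no-response traces get the 15-s fallback window", {
  st <- simulate_voltage_trace(get_preset("control_ephys"), seed = 4)
  bl <- estimate_baseline(st$trace)
  win <- detect_response_window(st$trace, bl)
  expect_true(win$fallback)
  expect_equal(win$end - win$start, 15)
  expect_equal(win$start, st$trace$application_time)
})

test_that("a programmed rectangular episode is detected at its true duration", {
  p <- quiet_preset(noise_sd = 0.3, response_depth = -40,
                    response_duration_mean = 20, response_duration_sd = 0,
                    response_onset_tau = 0, response_offset_tau = 0,
                    duration = 60, application_time = 20)
  st <- simulate_voltage_trace(p, seed = 9)
  win <- detect_response_window(st$trace, baseline = -50)
  expect_false(win$fallback)
  expect_lt(abs((win$end - win$start) - 20), 0.05)
  expect_lt(abs(win$start - st$truth$response_start), 0.05)
})

test_that("window detection needs 15 s of post-application data", {
  tr <- flat_trace(duration = 12, app = 5)
  expect_error(detect_response_window(tr, baseline = -50), "too short")
})

test_that("RSH of trivial windows matches closed forms", {
  tr <- flat_trace(value = -50, duration = 30, fs = 1000, app = 10)
  win <- structure(list(start = 10, end = 15, fallback = TRUE),
                   class = "response_window")
  expect_equal(compute_rsh(tr, -50, win)$rsh, 0)
  tr2 <- flat_trace(value = -60, duration = 30, fs = 1000, app = 10)
  r <- compute_rsh(tr2, -50, win)
  expect_equal(r$rsh, -50)            # -10 mV times 5 s
  expect_equal(r$mean_deviation, -10)
  expect_equal(r$duration, 5)
  expect_equal(r$rsh, r$mean_deviation * r$duration)
})

test_that("RSH equals the independent per-sample sum oracle on random traces", {
  set.seed(42)
  for (k in 1:100) {
    fs <- 500
    v <- -50 + cumsum(rnorm(3 * fs, 0, 0.2))
    tr <- as_trace(v, fs, app = 1)
    win <- structure(list(start = 0.5, end = 2.5, fallback = FALSE),
                     class = "response_window")
    r <- compute_rsh(tr, -50, win)
    i0 <- floor(0.5 * fs) + 1
    i1 <- floor(2.5 * fs) + 1
    expect_equal(r$rsh, trapz_oracle(v[i0:i1], -50, 1 / fs),
                 tolerance = 1e-6)
  }
})

test_that("RSH is additive over a window split and invariant to potential shifts", {
  set.seed(7)
  fs <- 1000
  v <- -50 + rnorm(5 * fs, 0, 1)
  tr <- as_trace(v, fs, app = 1)
  whole <- structure(list(start = 1, end = 4.5), class = "response_window")
  left <- structure(list(start = 1, end = 2.2), class = "response_window")
  right <- structure(list(start = 2.2, end = 4.5), class = "response_window")
  expect_equal(compute_rsh(tr, -50, left)$rsh + compute_rsh(tr, -50, right)$rsh,
               compute_rsh(tr, -50, whole)$rsh, tolerance = 1e-9)
  shifted <- as_trace(v + 17, fs, app = 1)
  expect_equal(compute_rsh(shifted, -50 + 17, whole)$rsh,
               compute_rsh(tr, -50, whole)$rsh, tolerance = 1e-9)
  # stretching time by k multiplies the area by k
  slow <- as_trace(v, fs / 2, app = 2)
  stretched <- structure(list(start = 2, end = 9), class = "response_window")
  expect_equal(compute_rsh(slow, -50, stretched)$rsh,
               2 * compute_rsh(tr, -50, whole)$rsh, tolerance = 1e-9)
})

test_that("cohort summary reproduces hand-computed mean and SE", {
  s <- summarize_cohort(c(-2, -4, -6))
  expect_equal(s$mean, -4)
  expect_equal(s$se, 2 / sqrt(3))
  expect_identical(s$n, 3L)
  expect_error(summarize_cohort(c(-1)), "at least 2")
})

test_that("control RSH is small and menthol RSH an order of magnitude larger", {
  ctrl <- analyze_trace(simulate_voltage_trace(get_preset("control_ephys"),
                                               seed = 1)$trace)
  ment <- analyze_trace(simulate_voltage_trace(get_preset("menthol_ephys"),
                                               seed = 1)$trace)
  expect_lt(ctrl$rsh$rsh, 0)
  expect_gt(abs(ment$rsh$rsh), 10 * abs(ctrl$rsh$rsh))
  expect_true(ctrl$window$fallback)
  expect_false(ment$window$fallback)
})
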