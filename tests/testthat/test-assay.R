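test_that("Bradford fit matches trivial and noiseless standards exactly", {
  f <- fit_bradford(data.frame(conc = c(0, 1), a595 = c(0, 1)))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  concs <- c(0, 0.2, 0.4, 0.6, 1.0, 1.4)
  f2 <- fit_bradford(data.frame(conc = concs, a595 = 0.05 + 0.8 * concs))
  expect_equal(f2$slope, 0.8, tolerance = 1e-10)
  expect_equal(f2$intercept, 0.05, tolerance = 1e-10)
  expect_equal(f2$inverse(0.05 + 0.8 * 0.3), 0.3, tolerance = 1e-10)
  expect_error(fit_bradford(data.frame(conc = c(1, 1), a595 = c(0, 1))),
               "distinct")
})

test_that("noisy Bradford fit agrees with the normal-equations oracle", {
  set.seed(11)
  concs <- c(0, 0.2, 0.4, 0.6, 1.0, 1.4)
  a595 <- 0.05 + 0.8 * concs + rnorm(6, 0, 0.01)
  f <- fit_bradford(data.frame(conc = concs, a595 = a595))
  oracle <- normal_equations_oracle(concs, a595)
  expect_equal(f$slope, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(f$intercept, unname(oracle["intercept"]), tolerance = 1e-10)
  # slope within 3 SE of the generating truth
  se <- summary(lm(a595 ~ concs))$coefficients["concs", "Std. Error"]
  expect_lt(abs(f$slope - 0.8), 3 * se)
})

test_that("reduction is linear in blank-corrected absorbance", {
  plate <- simulate_assay_plate(assay_preset(absorbance_noise_sd = 0),
                                "bend", seed = 1)
  base <- reduce_plate(plate)
  doubled <- plate
  is406 <- doubled$wells$role == "sample" & doubled$wells$wavelength_nm == 406
  blank <- mean(doubled$wells$absorbance[doubled$wells$role == "blank"])
  doubled$wells$absorbance[is406] <-
    blank + 2 * (doubled$wells$absorbance[is406] - blank)
  expect_equal(reduce_plate(doubled)$activity, 2 * base$activity,
               tolerance = 1e-9)
})

test_that("reduction flags missing paired reads and non-positive protein", {
  plate <- simulate_assay_plate(assay_preset(absorbance_noise_sd = 0),
                                "control", seed = 1)
  broken <- plate
  drop <- which(broken$wells$role == "sample" &
                  broken$wells$wavelength_nm == 595)[1]
  broken$wells <- broken$wells[-drop, ]
  expect_error(reduce_plate(broken), "paired 595")
  zeroed <- plate
  is595 <- zeroed$wells$role == "sample" & zeroed$wells$wavelength_nm == 595
  zeroed$wells$absorbance[is595] <- 0
  red <- reduce_plate(zeroed)
  expect_true(all(!red$valid))
  expect_true(all(is.na(red$activity)))
})

test_that("percent of control follows its defining arithmetic", {
  res <- data.frame(well = c("a", "b", "c"), arm = c("control", "x", "x"),
                    concentration_uM = c(NA, 1, 2), replicate = 1,
                    protein_mg_ml = 0.3, activity = c(2, 2, 1), valid = TRUE)
  pts <- percent_of_control(res, "control")
  expect_equal(pts$inhibition, c(0, 50))
  expect_equal(pts$percent_activity, c(100, 50))
  expect_error(percent_of_control(res[2:3, ], "control"), "no control")
})

test_that("noiseless log-logistic data are recovered exactly", {
  truth <- log_logistic_model(imax = 90, slope = 2, ed50 = 0.1)
  conc <- c(0.05, 0.1, 0.2, 0.5, 1)
  pts <- data.frame(concentration_uM = conc, inhibition = predict(truth, conc))
  fit <- fit_log_logistic(pts)
  expect_equal(fit$imax, 90, tolerance = 1e-6)
  expect_equal(fit$slope, 2, tolerance = 1e-6)
  expect_equal(fit$ed50, 0.1, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-10)
})

test_that("the fit beats a coarse grid-search oracle and sits in its best cell", {
  truth <- log_logistic_model(imax = 90, slope = 2, ed50 = 0.1)
  conc <- c(0.05, 0.1, 0.2, 0.5, 1)
  inh <- predict(truth, conc)
  oracle <- ll_grid_oracle(conc, inh,
                           imax_grid = seq(80, 100, by = 2.5),
                           slope_grid = seq(0.5, 4, by = 0.25),
                           ed50_grid = exp(seq(log(0.02), log(0.5),
                                               length.out = 25)))
  fit <- fit_log_logistic(data.frame(concentration_uM = conc, inhibition = inh))
  expect_lte(fit$sse, oracle$sse + 1e-12)
  expect_lt(abs(fit$imax - oracle$par["imax"]), 2.5)
  expect_lt(abs(fit$slope - oracle$par["slope"]), 0.25)
  expect_lt(abs(log(fit$ed50) - log(oracle$par["ed50"])),
            diff(log(c(0.02, 0.5))) / 24)
})

test_that("rescaling concentrations rescales the ED50 and nothing else", {
  set.seed(21)
  truth <- log_logistic_model(imax = 85, slope = 1.5, ed50 = 0.2)
  conc <- c(0.05, 0.1, 0.2, 0.5, 1)
  inh <- predict(truth, conc) + rnorm(5, 0, 1)
  f1 <- fit_log_logistic(data.frame(concentration_uM = conc, inhibition = inh))
  k <- 7
  f2 <- fit_log_logistic(data.frame(concentration_uM = k * conc,
                                    inhibition = inh))
  expect_equal(f2$ed50, k * f1$ed50, tolerance = 1e-4)
  expect_equal(f2$imax, f1$imax, tolerance = 1e-4)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-4)
})

test_that("fitted inhibition is monotone over the tested dose range", {
  plate <- simulate_assay_plate(assay_preset(), "ment_bend", seed = 2)
  fit <- fit_log_logistic(percent_of_control(reduce_plate(plate), "control"))
  pred <- predict(fit, c(0.05, 0.1, 0.2, 0.5, 1))
  expect_true(all(diff(pred) >= 0))
})

test_that("fit errors are informative for degenerate inputs", {
  conc <- c(0.05, 0.1, 0.2, 0.5, 1)
  expect_error(fit_log_logistic(data.frame(concentration_uM = conc,
                                           inhibition = rep(0, 5))),
               "zero")
  expect_error(fit_log_logistic(data.frame(concentration_uM = c(0.1, 0.2),
                                           inhibition = c(10, 20))),
               "at least 3")
  fixed <- fit_log_logistic(data.frame(concentration_uM = c(0.05, 0.1, 0.2),
                                       inhibition = predict(
                                         log_logistic_model(90, 2, 0.1),
                                         c(0.05, 0.1, 0.2))),
                            fix_imax = 90)
  expect_equal(fixed$ed50, 0.1, tolerance = 1e-6)
  expect_true(fixed$fixed_imax)
})

test_that("median fitted ED50 across seeded datasets stays within 10% of truth", {
  ed50s <- vapply(1:25, function(s) {
    plate <- simulate_assay_plate(assay_preset(), "bend", seed = s)
    fit_log_logistic(percent_of_control(reduce_plate(plate), "control"))$ed50
  }, numeric(1))
  expect_lt(abs(stats::median(ed50s) - 0.10), 0.01)
})

test_that("ED50 shift is the relative change between fitted curves", {
  a <- log_logistic_model(90, 2, 0.10)
  b <- log_logistic_model(90, 2, 0.074)
  c <- log_logistic_model(90, 2, 0.05)
  expect_equal(ed50_shift(a, a), 0)
  expect_equal(ed50_shift(a, b), 26, tolerance = 1e-9)
  expect_equal(ed50_shift(a, c), 50)
})

test_that("arm curves keep the reference potency ordering at 0.5 uM", {
  act_at_05 <- vapply(c("ment_bend", "bend", "phent_ment_bend",
                        "ipka_ment_bend"),
                      function(arm) 100 - predict(arm_truth(arm), 0.5),
                      numeric(1))
  expect_true(act_at_05["ment_bend"] < act_at_05["bend"])
  expect_true(act_at_05["bend"] < act_at_05["phent_ment_bend"])
  expect_true(act_at_05["phent_ment_bend"] < act_at_05["ipka_ment_bend"])
})
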