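test_that("equal group means give F = 0", {
  tab <- list(a = c(1, 2, 3), b = c(0, 2, 4), c = c(-1, 2, 5))
  res <- one_way_anova(tab)
  expect_equal(res$f, 0, tolerance = 1e-12)
})

test_that("the toy table reproduces the hand-computed decomposition", {
  # groups {1,2,3}, {2,3,4}, {5,6,7}: SSB = 26 (df 2), SSW = 6 (df 6),
  # F = (26/2)/(6/6) = 13
  res <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4),
                            g3 = c(5, 6, 7)))
  expect_equal(res$f, 13, tolerance = 1e-10)
  expect_identical(res$df_between, 2L)
  expect_identical(res$df_within, 6L)
  expect_equal(res$p, stats::pf(13, 2, 6, lower.tail = FALSE))
})

test_that("six groups totalling 51 observations give df (5, 45)", {
  set.seed(1)
  sizes <- c(9, 9, 9, 8, 8, 8)
  tab <- lapply(sizes, function(n) rnorm(n))
  names(tab) <- paste0("g", 1:6)
  res <- one_way_anova(tab)
  expect_identical(res$df_between, 5L)
  expect_identical(res$df_within, 45L)
})

test_that("F is invariant under affine transformation of the observations", {
  set.seed(2)
  tab <- list(a = rnorm(5, 1), b = rnorm(7, 2), c = rnorm(6, 0))
  f0 <- one_way_anova(tab)$f
  tab2 <- lapply(tab, function(x) 3.7 * x - 11)
  expect_equal(one_way_anova(tab2)$f, f0, tolerance = 1e-9)
})

test_that("groups with fewer than two observations are rejected", {
  expect_error(one_way_anova(list(a = c(1, 2), b = 3)), "at least 2")
})

test_that("identical groups are not separated and a far outlier group is", {
  tk <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(tk$pairs$diff, 0)
  expect_gt(tk$pairs$p_adj, 0.99)
  expect_identical(unname(tk$letters["a"]), unname(tk$letters["b"]))

  tk2 <- tukey_hsd(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(50, 51, 52)))
  expect_false(grepl(tk2$letters["c"], tk2$letters["a"], fixed = TRUE))
  expect_identical(unname(tk2$letters["a"]), unname(tk2$letters["b"]))
  expect_identical(nchar(unname(tk2$letters["c"])), 1L)
})

test_that("Tukey-adjusted p is never below the per-comparison pooled-t p", {
  set.seed(3)
  for (rep in 1:5) {
    tab <- list(a = rnorm(4, 0), b = rnorm(6, 0.8), c = rnorm(5, 1.6),
                d = rnorm(4, 0.2))
    df <- do.call(rbind, lapply(names(tab), function(g)
      data.frame(group = g, value = tab[[g]])))
    tk <- tukey_hsd(df)
    fit <- stats::aov(value ~ group, data = df)
    mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
    dfw <- summary(fit)[[1]]["Residuals", "Df"]
    ns <- vapply(tab, length, numeric(1))
    for (r in seq_len(nrow(tk$pairs))) {
      i <- tk$pairs$group_i[r]
      j <- tk$pairs$group_j[r]
      se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      p_unadj <- 2 * stats::pt(-abs(tk$pairs$diff[r]) / se, dfw)
      expect_gte(tk$pairs$p_adj[r] + 1e-12, p_unadj)
    }
  }
})

test_that("letter display is consistent with pairwise significance", {
  set.seed(4)
  for (rep in 1:8) {
    tab <- list(a = rnorm(4, 0), b = rnorm(5, rep / 2), c = rnorm(4, rep),
                d = rnorm(6, 0.3), e = rnorm(4, 2))
    tk <- tukey_hsd(tab)
    share <- function(x, y) {
      any(strsplit(x, "")[[1]] %in% strsplit(y, "")[[1]])
    }
    for (r in seq_len(nrow(tk$pairs))) {
      shared <- share(tk$letters[tk$pairs$group_i[r]],
                      tk$letters[tk$pairs$group_j[r]])
      if (tk$pairs$p_adj[r] > tk$alpha) {
        expect_true(shared)
      } else {
        expect_false(shared)
      }
    }
    expect_true(all(nchar(tk$letters) >= 1))
  }
})

test_that("group summaries report mean, SE and n with NA SE for singletons", {
  s <- summarize_groups(list(a = c(4, 4, 4), b = c(-2, -4, -6), c = 5))
  expect_equal(s$mean, c(4, -4, 5))
  expect_equal(s$se, c(0, 2 / sqrt(3), NA))
  expect_identical(s$n, c(3L, 3L, 1L))
  expect_equal(s$se[2], 1.1547, tolerance = 1e-4)
})

test_that("reports carry provenance, mark missing sections, and serialize deterministically", {
  empty <- build_report(seed = 5)
  expect_identical(empty$rsh$status, "not run")
  expect_identical(empty$dose_response$status, "not run")
  full <- build_report(ephys = list(x = 1), fits = list(y = 2),
                       mgv = list(z = 3), seed = 5,
                       config = default_config(seed = 5))
  expect_identical(full$rsh$status, "ok")
  expect_match(full$provenance$config_hash, "^[0-9a-f]+$")
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(full, p1)
  write_report(full, p2)
  expect_identical(readLines(p1), readLines(p2))
})
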