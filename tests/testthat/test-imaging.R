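test_that("segmentation of a noiseless disk on zero background is near-perfect", {
  p <- image_preset(membrane_to_interior_ratio = 1, noise_sd = 0,
                    mgv_cv_between = 0, background_level = 0)
  si <- simulate_calcium_image(p, seed = 1)
  mask <- segment_cell(si$image)
  iou <- sum(mask$mask & si$truth$mask) / sum(mask$mask | si$truth$mask)
  expect_gte(iou, 0.98)
})

test_that("segmentation of a membrane-ring cell still yields the filled disk", {
  si <- simulate_calcium_image(get_preset("control_calcium"), seed = 2)
  mask <- segment_cell(si$image)
  iou <- sum(mask$mask & si$truth$mask) / sum(mask$mask | si$truth$mask)
  expect_gte(iou, 0.95)
  expect_equal(mask$area_um2, mask$n_pixels * 0.25)
})

test_that("an empty image raises a no-cell error", {
  img <- as_image(matrix(0, 64, 64))
  expect_error(segment_cell(img), "no cell")
})

test_that("with two cells the larger one is segmented", {
  px <- matrix(0, 128, 128)
  cols <- matrix(rep(seq_len(128), each = 128), 128, 128)
  rows <- matrix(rep(seq_len(128), times = 128), 128, 128)
  big <- (cols - 40)^2 + (rows - 64)^2 <= 22^2
  small <- (cols - 100)^2 + (rows - 64)^2 <= 9^2
  px[big] <- 10
  px[small] <- 10
  mask <- segment_cell(as_image(px))
  expect_gt(sum(mask$mask & big) / sum(big), 0.95)
  expect_identical(sum(mask$mask & small), 0L)
})

test_that("MGV of a uniform image over a full mask is the constant", {
  px <- matrix(3.7, 32, 32)
  q <- compute_mgv(as_image(px), matrix(TRUE, 32, 32))
  expect_equal(q$mgv, 3.7)
  expect_error(compute_mgv(as_image(px), matrix(FALSE, 32, 32)), "empty mask")
})

test_that("MGV is invariant to background padding and linear in intensity", {
  si <- simulate_calcium_image(get_preset("control_calcium"), seed = 3)
  mask <- segment_cell(si$image)
  q <- compute_mgv(si$image, mask)
  pad <- 20
  n <- nrow(si$image$pixels)
  padded <- matrix(get_preset("control_calcium")$background_level,
                   n + 2 * pad, n + 2 * pad)
  padded[pad + seq_len(n), pad + seq_len(n)] <- si$image$pixels
  padded_mask <- matrix(FALSE, n + 2 * pad, n + 2 * pad)
  padded_mask[pad + seq_len(n), pad + seq_len(n)] <- mask$mask
  q_pad <- compute_mgv(as_image(padded), padded_mask)
  expect_equal(q_pad$mgv, q$mgv, tolerance = 1e-12)
  scaled <- as_image(2.5 * si$image$pixels)
  expect_equal(compute_mgv(scaled, mask)$mgv, 2.5 * q$mgv, tolerance = 1e-12)
})

test_that("radial profile bin means equal a brute-force per-pixel grouping", {
  si <- simulate_calcium_image(get_preset("menthol_calcium"), seed = 4)
  mask <- segment_cell(si$image)
  prof <- radial_profile(si$image, mask, n_bins = 12)
  # brute force: loop over mask pixels, assign to bins, average
  idx <- which(mask$mask, arr.ind = TRUE)
  cen <- mask$centroid
  r_um <- sqrt((idx[, 2] - cen[1])^2 + (idx[, 1] - cen[2])^2) * 0.5
  breaks <- seq(0, max(r_um) + 1e-9, length.out = 13)
  sums <- numeric(12)
  counts <- integer(12)
  vals <- si$image$pixels[mask$mask]
  for (k in seq_along(r_um)) {
    b <- min(12, max(1, findInterval(r_um[k], breaks, rightmost.closed = TRUE)))
    sums[b] <- sums[b] + vals[k]
    counts[b] <- counts[b] + 1L
  }
  got <- prof$mean_intensity
  want <- ifelse(counts > 0, sums / counts, NA_real_)
  expect_equal(got, want, tolerance = 1e-9)
  expect_error(radial_profile(si$image, mask, n_bins = 1), "n_bins")
})

test_that("a uniform disk has a flat profile and a ring preset peaks at the ring", {
  p_flat <- image_preset(membrane_to_interior_ratio = 1, noise_sd = 0,
                         mgv_cv_between = 0, center_jitter = 0)
  si_flat <- simulate_calcium_image(p_flat, seed = 1)
  prof_flat <- radial_profile(si_flat$image,
                              segment_cell(si_flat$image), n_bins = 10)
  inner <- prof_flat$mean_intensity[prof_flat$n_pixels > 20][1:8]
  expect_lt(max(inner) - min(inner), 0.05 * mean(inner))

  p_ring <- image_preset(noise_sd = 0, mgv_cv_between = 0, center_jitter = 0)
  si_ring <- simulate_calcium_image(p_ring, seed = 1)
  prof_ring <- radial_profile(si_ring$image,
                              segment_cell(si_ring$image), n_bins = 25)
  peak_um <- prof_ring$bin_center_um[which.max(prof_ring$mean_intensity)]
  ring_center_um <- 25 - 3 / 2
  expect_lt(abs(peak_um - ring_center_um), 1.5)
})
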