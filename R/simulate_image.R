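# Single-cell fluorescence image generator: disk cell with a brighter
# membrane ring on uniform background, scaled so the mask mean equals the
# per-image target MGV before noise.

#' Simulate a calcium-indicator fluorescence image
#'
#' @param preset An [image_preset()].
#' @param seed Integer seed.
#' @param label Treatment label.
#' @return List with `image` (class `fluorescence_image`: `pixels` matrix,
#'   `um_per_pixel`, `label`) and `truth` (class `image_truth`: logical
#'   `mask`, `true_mgv` for this image, `center` (px), `radius_px`,
#'   `ring_inner_px`).
#' @export
#' @examples
#' si <- simulate_calcium_image(image_preset(noise_sd = 0, mgv_cv_between = 0), seed = 1)
#' mean(si$image$pixels[si$truth$mask])
simulate_calcium_image <- function(preset, seed, label = "image") {
  stopifnot(inherits(preset, "image_preset"))
  n <- preset$image_size
  r_px <- preset$cell_radius / preset$um_per_pixel
  ring_px <- preset$membrane_ring_width / preset$um_per_pixel

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # per-image true MGV: mean-preserving lognormal around the cohort target
  mgv <- preset$target_mgv
  if (preset$mgv_cv_between > 0) {
    sdlog <- sqrt(log(1 + preset$mgv_cv_between^2))
    mgv <- mgv * stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }

  cx <- (n + 1) / 2 + stats::runif(1, -preset$center_jitter, preset$center_jitter)
  cy <- (n + 1) / 2 + stats::runif(1, -preset$center_jitter, preset$center_jitter)
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  r <- sqrt((xs - cx)^2 + (ys - cy)^2)

  disk <- r <= r_px
  ring <- disk & r > (r_px - ring_px)
  base <- matrix(0, n, n)
  base[disk] <- 1
  base[ring] <- preset$membrane_to_interior_ratio
  scale <- mgv / mean(base[disk])
  px <- matrix(preset$background_level, n, n)
  px[disk] <- base[disk] * scale
  if (preset$noise_sd > 0)
    px <- px + matrix(stats::rnorm(n * n, 0, preset$noise_sd), n, n)
  px <- pmax(px, 0)

  image <- structure(list(pixels = px, um_per_pixel = preset$um_per_pixel,
                          label = label),
                     class = "fluorescence_image")
  truth <- structure(list(mask = disk, true_mgv = mgv, center = c(cx, cy),
                          radius_px = r_px, ring_inner_px = r_px - ring_px),
                     class = "image_truth")
  list(image = image, truth = truth)
}

#' Simulate a cohort of fluorescence images
#'
#' @param preset An [image_preset()].
#' @param n Number of images.
#' @param seed Base seed; image i uses `seed + i - 1`.
#' @param label Treatment label.
#' @return List of [simulate_calcium_image()] results.
#' @export
simulate_image_cohort <- function(preset, n, seed, label = "image") {
  lapply(seq_len(n), function(i)
    simulate_calcium_image(preset, seed = seed + i - 1, label = label))
}

#' Write / read a fluorescence image as TIFF with a JSON sidecar
#'
#' Pixels are stored as 16-bit TIFF scaled by `intensity_scale` recorded in
#' the sidecar (`<path>.json`) together with the spatial calibration and, for
#' generated images, the true MGV.
#'
#' @param si Result of [simulate_calcium_image()], or a `fluorescence_image`.
#' @param path TIFF file path.
#' @return `read_image()` returns a list with `image` and (if present in the
#'   sidecar) `true_mgv`.
#' @export
write_image <- function(si, path) {
  image <- if (inherits(si, "fluorescence_image")) si else si$image
  scale <- max(image$pixels, 1e-12)
  tiff::writeTIFF(image$pixels / scale, path, bits.per.sample = 16)
  meta <- list(um_per_pixel = image$um_per_pixel, label = image$label,
               intensity_scale = scale)
  if (!inherits(si, "fluorescence_image") && !is.null(si$truth))
    meta$true_mgv <- si$truth$true_mgv
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing sidecar ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  px <- tiff::readTIFF(path) * meta$intensity_scale
  image <- structure(list(pixels = px, um_per_pixel = meta$um_per_pixel,
                          label = meta$label),
                     class = "fluorescence_image")
  list(image = image, true_mgv = meta$true_mgv)
}
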