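#' 3D image stack with voxel calibration
#'
#' @param intensity Non-negative 3D array ordered (z, y, x).
#' @param voxel_nm Voxel size per axis (z, y, x), nm.
#' @param channel Channel label.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(intensity, voxel_nm = c(30, 30, 30),
                        channel = "ch1") {
  stopifnot(length(dim(intensity)) == 3, all(intensity >= 0),
            length(voxel_nm) == 3, all(voxel_nm > 0))
  structure(list(intensity = intensity, voxel_nm = as.numeric(voxel_nm),
                 channel = channel),
            class = "image_stack")
}

#' Read a 3D image stack from a multi-page TIFF
#'
#' Pages are z slices; pixel values are rescaled back to integer counts
#' when the file stores them normalized.
#'
#' @param path Path to the TIFF file.
#' @param voxel_nm Voxel size (z, y, x), nm.
#' @param channel Channel label.
#' @return An `image_stack`.
#' @export
read_image_stack <- function(path, voxel_nm = c(30, 30, 30),
                             channel = "ch1") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  image_stack(arr, voxel_nm, channel)
}

#' Write a 3D image stack as a multi-page 16-bit TIFF
#' @param stack An `image_stack` (counts must fit 16 bits).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  d <- dim(stack$intensity)
  pages <- lapply(seq_len(d[1]), function(z)
    stack$intensity[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

conv_axis <- function(arr, k, axis) {
  r <- (length(k) - 1L) / 2L
  d <- dim(arr)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  # replicate-pad along the filtered axis
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
              m[rep(nrow(m), r), , drop = FALSE])
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
  b <- array(out, da)
  aperm(b, order(perm))
}

#' Separable 3D Gaussian blur
#' @param arr 3D array (z, y, x).
#' @param sigma Per-axis standard deviations in voxels (z, y, x).
#' @return Blurred array of the same dimension.
#' @export
gaussian_blur_3d <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3)
  for (ax in 1:3)
    if (sigma[ax] > 0) arr <- conv_axis(arr, gauss_kernel(sigma[ax]), ax)
  arr
}

laplacian_3d <- function(arr) {
  d <- dim(arr)
  out <- -6 * arr
  shift <- function(a, ax, by) {
    idx <- lapply(d, seq_len)
    idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    do.call(`[`, c(list(a), idx))
  }
  for (ax in 1:3) out <- out + shift(arr, ax, 1L) + shift(arr, ax, -1L)
  out
}

#' Detect the brightest spot with a Laplacian-of-Gaussian blob detector
#'
#' Scans a range of blob scales, takes the scale-normalized maximum of
#' `-sigma^2 * Laplacian(Gaussian(I))` (bright blobs give positive response)
#' and returns the maximizing voxel. Ties are broken deterministically by
#' the lowest (z, y, x).
#'
#' @param stack An `image_stack`.
#' @param scales Blob scales in voxels (isotropic), default `c(1, 1.5, 2)`.
#' @param noise_floor Minimal accepted response relative to the stack's
#'   robust noise level (`noise_floor * mad(I)`); below it the detector
#'   reports no spot.
#' @return List with `voxel` (z, y, x, 1-based), `scale`, `response`; or
#'   `NULL` when no spot exceeds the noise floor.
#' @export
detect_brightest_spot <- function(stack, scales = c(1, 1.5, 2),
                                  noise_floor = 8) {
  best <- NULL
  noise <- stats::mad(stack$intensity) + 1e-12
  for (s in scales) {
    resp <- -s^2 * laplacian_3d(gaussian_blur_3d(stack$intensity, s))
    mx <- max(resp)
    if (is.null(best) || mx > best$response) {
      w <- which(resp == mx, arr.ind = TRUE)
      w <- w[order(w[, 1], w[, 2], w[, 3]), , drop = FALSE][1, ]
      best <- list(voxel = unname(w), scale = s, response = mx)
    }
  }
  if (best$response < noise_floor * noise) return(NULL)
  best
}

#' Sub-voxel 3D Gaussian fit of a spot (Levenberg-Marquardt)
#'
#' Least-squares fit of a 3D Gaussian plus constant background over a local
#' window around the seed voxel, using the Levenberg-Marquardt algorithm.
#'
#' @param stack An `image_stack`.
#' @param seed_voxel Integer (z, y, x) seed coordinate (1-based), e.g. from
#'   [detect_brightest_spot()].
#' @param window_sigmas Half-width of the fit window in units of the
#'   initial width guess (default 3).
#' @param init_sigma_vox Initial per-axis width guess, voxels.
#' @return Object of class `spot_fit`: `center_nm` and `center_vox` (z, y,
#'   x), `amplitude`, `sigma_nm`, `background`, `residual` (RMS), `converged`,
#'   `voxel_nm`. Errors if the fit does not converge.
#' @export
fit_gaussian_3d <- function(stack, seed_voxel, window_sigmas = 3,
                            init_sigma_vox = c(2.5, 1.5, 1.5)) {
  d <- dim(stack$intensity)
  seed_voxel <- as.integer(round(seed_voxel))
  if (any(seed_voxel < 1L) || any(seed_voxel > d))
    stop("seed voxel outside stack bounds")
  r <- pmax(2L, as.integer(ceiling(window_sigmas * init_sigma_vox)))
  lo <- pmax(1L, seed_voxel - r); hi <- pmin(d, seed_voxel + r)
  sub <- stack$intensity[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  g <- expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
  I <- as.numeric(sub)

  bg0 <- stats::median(I)
  a0 <- max(I) - bg0
  p0 <- c(cz = seed_voxel[1], cy = seed_voxel[2], cx = seed_voxel[3],
          sz = init_sigma_vox[1], sy = init_sigma_vox[2],
          sx = init_sigma_vox[3], A = max(a0, 1e-6), bg = bg0)
  model <- function(p) {
    p[["bg"]] + p[["A"]] *
      exp(-((g$z - p[["cz"]])^2 / (2 * p[["sz"]]^2) +
            (g$y - p[["cy"]])^2 / (2 * p[["sy"]]^2) +
            (g$x - p[["cx"]])^2 / (2 * p[["sx"]]^2)))
  }
  fit <- minpack.lm::nls.lm(
    par = p0, fn = function(p) model(p) - I,
    lower = c(lo - 1, 0.3, 0.3, 0.3, 0, -Inf),
    upper = c(hi + 1, d, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200, maxfev = 5000))
  if (!fit$info %in% 1:4)
    stop("Gaussian fit did not converge (info = ", fit$info, "): ",
         fit$message)
  p <- fit$par
  center_vox <- c(p[["cz"]], p[["cy"]], p[["cx"]])
  if (any(center_vox < 0.5) || any(center_vox > d + 0.5))
    stop("fitted center outside stack bounds")
  structure(list(
    center_vox = center_vox,
    center_nm = (center_vox - 1) * stack$voxel_nm,
    amplitude = p[["A"]],
    sigma_nm = c(p[["sz"]], p[["sy"]], p[["sx"]]) * stack$voxel_nm,
    background = p[["bg"]],
    residual = sqrt(mean((model(p) - I)^2)),
    converged = TRUE,
    voxel_nm = stack$voxel_nm,
    channel = stack$channel), class = "spot_fit")
}

#' Distance between two fitted spots
#'
#' Euclidean distance between fitted sub-voxel centers in nm; in `"2D"` mode
#' the z coordinate is omitted before computing the distance.
#'
#' @param fit_a,fit_b `spot_fit` objects (typically one per color channel)
#'   with identical voxel calibration.
#' @param mode `"3D"` or `"2D"`.
#' @return Distance in nm.
#' @export
pair_distance <- function(fit_a, fit_b, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  if (max(abs(fit_a$voxel_nm - fit_b$voxel_nm)) > 1e-9)
    stop("voxel calibration mismatch between channels")
  d <- fit_a$center_nm - fit_b$center_nm
  if (mode == "2D") d <- d[2:3]
  sqrt(sum(d^2))
}

#' Localize a two-color spot pair in a pair of stacks
#'
#' Convenience wrapper: detect the brightest spot and Gaussian-fit it in
#' each channel, then report the 3D and projected 2D pair distances.
#'
#' @param stack_ch1,stack_ch2 `image_stack`s of the two channels.
#' @param ... Passed to [detect_brightest_spot()].
#' @return List with `fit_ch1`, `fit_ch2`, `distance_3d_nm`,
#'   `distance_2d_nm`; `NULL` if either channel has no detectable spot.
#' @export
localize_pair <- function(stack_ch1, stack_ch2, ...) {
  d1 <- detect_brightest_spot(stack_ch1, ...)
  d2 <- detect_brightest_spot(stack_ch2, ...)
  if (is.null(d1) || is.null(d2)) return(NULL)
  f1 <- fit_gaussian_3d(stack_ch1, d1$voxel)
  f2 <- fit_gaussian_3d(stack_ch2, d2$voxel)
  list(fit_ch1 = f1, fit_ch2 = f2,
       distance_3d_nm = pair_distance(f1, f2, "3D"),
       distance_2d_nm = pair_distance(f1, f2, "2D"))
}
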