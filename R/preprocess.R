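#' Estimate the cumulative axial motion profile of a volume
#'
#' Registers each pair of adjacent B-scans by maximizing the normalized
#' cross-correlation of axially shifted copies over an integer search range,
#' with optional parabolic subpixel refinement, and accumulates the pairwise
#' offsets into a cumulative displacement profile (first B-scan = 0).
#' Correlation is evaluated on the central 50% axial band so that the
#' background does not dominate the objective.
#'
#' @param volume An [oct_volume()] with at least 2 B-scans.
#' @param max_shift_px Maximum absolute pairwise shift searched, pixels.
#'   Must leave the central registration band inside the volume.
#' @param subpixel Parabolic refinement of the correlation peak.
#' @return Numeric cumulative displacement per B-scan, pixels.
#' @export
estimate_shifts <- function(volume, max_shift_px = 30L, subpixel = TRUE) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$intensity)
  if (d[1] < 2L) stop("need at least 2 B-scans")
  nz <- d[3]
  max_shift_px <- as.integer(max_shift_px)
  if (max_shift_px >= nz) stop("max_shift_px must be smaller than the axial depth")
  z0 <- floor(nz * 0.25) + 1L
  z1 <- floor(nz * 0.75)
  if (max_shift_px >= z0)
    stop("max_shift_px too large for the central registration band")
  band <- z0:z1
  shifts <- (-max_shift_px):max_shift_px
  offsets <- numeric(d[1] - 1L)
  for (i in 2:d[1]) {
    prev <- volume$intensity[i - 1L, , band]
    x <- as.vector(prev)
    sx <- stats::sd(x)
    cur <- volume$intensity[i, , ]
    if (sx == 0 || stats::sd(as.vector(cur[, band])) == 0) {
      warning("constant B-scan encountered; using zero offset")
      offsets[i - 1L] <- 0
      next
    }
    ncc <- vapply(shifts, function(s) {
      y <- as.vector(cur[, band + s])
      suppressWarnings(stats::cor(x, y))
    }, numeric(1))
    ncc[is.na(ncc)] <- -Inf
    k <- which.max(ncc)
    off <- shifts[k]
    if (subpixel && k > 1L && k < length(shifts)) {
      y1 <- ncc[k - 1L]; y2 <- ncc[k]; y3 <- ncc[k + 1L]
      den <- (y1 - 2 * y2 + y3)
      if (is.finite(den) && den < 0) off <- off + 0.5 * (y1 - y3) / den
    }
    offsets[i - 1L] <- off
  }
  cumsum(c(0, offsets))
}

#' Remove the smooth trend from a cumulative motion profile
#'
#' Fits a least-squares polynomial to the cumulative profile and returns the
#' residual (profile minus fit). The polynomial captures the natural retinal
#' curvature and the scanning angle along the slow axis, which must be
#' preserved; only the residual jitter is corrected.
#'
#' @param profile Cumulative displacement profile, pixels.
#' @param poly_order Polynomial order (default 2); must be smaller than the
#'   profile length.
#' @return Residual profile (the correction to subtract), pixels.
#' @export
detrend_shifts <- function(profile, poly_order = 2L) {
  n <- length(profile)
  if (poly_order >= n) stop("poly_order must be smaller than the profile length")
  x <- seq_len(n)
  X <- outer(x - mean(x), 0:poly_order, `^`)
  fit <- X %*% qr.solve(X, profile)
  as.numeric(profile - fit)
}

#' Apply a motion correction to a volume
#'
#' Shifts each B-scan axially by minus its residual displacement, with the
#' same interpolation contract as [apply_motion()]. Metadata is preserved.
#'
#' @param volume An [oct_volume()].
#' @param residual Residual profile from [detrend_shifts()].
#' @param seed Seed for background fill resampling.
#' @return Corrected [oct_volume()].
#' @export
apply_correction <- function(volume, residual, seed = 1L) {
  apply_motion(volume, -residual, seed = seed)
}

#' Motion-correct a volume end to end
#'
#' Convenience wrapper: [estimate_shifts()] then [detrend_shifts()] then
#' [apply_correction()].
#'
#' @inheritParams estimate_shifts
#' @inheritParams detrend_shifts
#' @return List with `volume` (corrected), `profile` (estimated cumulative)
#'   and `residual` (applied correction).
#' @export
motion_correct <- function(volume, max_shift_px = 30L, poly_order = 2L,
                           subpixel = TRUE) {
  prof <- estimate_shifts(volume, max_shift_px, subpixel = subpixel)
  resid <- detrend_shifts(prof, poly_order)
  list(volume = apply_correction(volume, resid),
       profile = prof, residual = resid)
}

#' Total variation of a volume
#'
#' Anisotropic 3D total variation (sum of absolute forward differences
#' along the three axes), the functional [bv_smooth()] penalizes.
#'
#' @param volume An [oct_volume()] or 3D array.
#' @return Scalar TV value.
#' @export
tv_norm <- function(volume) {
  a <- if (inherits(volume, "oct_volume")) volume$intensity else volume
  stopifnot(is.array(a), length(dim(a)) == 3L)
  tv_norm_3d(a)
}

#' 3D bounded-variation (total-variation) speckle smoothing
#'
#' Minimizes `||u - f||^2 + weight * TV(u)` over the volume with a
#' Chambolle-style dual projection solver (anisotropic 3D gradient), run to
#' `tol` (relative max voxel change per iteration) or `max_iter`. The output
#' is clipped to the input intensity range. Denoised volumes are intended
#' for visualization and manual labeling only; segmentation training and
#' inference operate on non-denoised volumes.
#'
#' @param volume An [oct_volume()].
#' @param weight Positive TV weight.
#' @param max_iter Maximum solver iterations.
#' @param tol Relative stopping tolerance.
#' @return Denoised [oct_volume()] (metadata gains `denoised = TRUE`).
#' @export
bv_smooth <- function(volume, weight, max_iter = 60L, tol = 1e-4) {
  stopifnot(inherits(volume, "oct_volume"))
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0)
    stop("weight must be a positive scalar")
  f <- volume$intensity
  u <- tv_denoise_3d(f, weight, as.integer(max_iter), tol)
  u <- pmin(pmax(u, min(f)), max(f))
  dim(u) <- dim(f)
  meta <- volume$meta
  meta$denoised <- TRUE
  meta$tv_weight <- weight
  oct_volume(u, volume$spacing_um, meta)
}

#' Signal-to-noise and contrast-to-noise ratio of a volume
#'
#' `SNR = 20 log10(mean_signal / sd_background)` (dB) and
#' `CNR = |mean_signal - mean_background| / sqrt((sd_signal^2 + sd_background^2)/2)`.
#'
#' @param volume An [oct_volume()] or 3D array.
#' @param signal_mask,background_mask Non-empty, disjoint logical arrays of
#'   the volume's dimensions.
#' @return List with elements `snr_db` and `cnr`.
#' @export
snr_cnr <- function(volume, signal_mask, background_mask) {
  a <- if (inherits(volume, "oct_volume")) volume$intensity else volume
  stopifnot(identical(dim(signal_mask), dim(a)),
            identical(dim(background_mask), dim(a)))
  if (!any(signal_mask) || !any(background_mask)) stop("masks must be non-empty")
  if (any(signal_mask & background_mask)) stop("masks must be disjoint")
  ms <- mean(a[signal_mask]); mb <- mean(a[background_mask])
  ss <- stats::sd(a[signal_mask]); sb <- stats::sd(a[background_mask])
  if (sb == 0) stop("background standard deviation is zero; SNR undefined")
  list(snr_db = 20 * log10(ms / sb),
       cnr = abs(ms - mb) / sqrt((ss^2 + sb^2) / 2))
}
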