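#' Detect the optic-nerve-head centre from boundary convergence
#'
#' The ONH appears as a pit in which the inner boundaries converge. The
#' centre is the weighted lateral centroid of the region where the
#' inner-retina separation (ILM to ELM boundary) drops below half its
#' median; if no such region exists, the geometric grid centre is returned
#' with a warning.
#'
#' @param stack A [surface_stack()] (any units).
#' @return Named numeric `c(y_um, x_um)` in centred lateral coordinates.
#' @export
detect_onh_center <- function(stack) {
  stopifnot(inherits(stack, "surface_stack"))
  H <- stack_heights_um(stack)
  sep <- H[, , 7] - H[, , 1]
  d <- dim(sep)
  sp <- stack$lateral_spacing_um
  yc <- (seq_len(d[1]) - 0.5) * sp[1] - d[1] * sp[1] / 2
  xc <- (seq_len(d[2]) - 0.5) * sp[2] - d[2] * sp[2] / 2
  thr <- 0.5 * stats::median(sep, na.rm = TRUE)
  pit <- !is.na(sep) & sep < thr
  if (!any(pit)) {
    warning("no ONH pit found; returning the geometric centre")
    return(c(y_um = 0, x_um = 0))
  }
  w <- (thr - sep)[pit]
  Y <- matrix(yc, d[1], d[2])[pit]
  X <- matrix(xc, d[1], d[2], byrow = TRUE)[pit]
  c(y_um = sum(w * Y) / sum(w), x_um = sum(w * X) / sum(w))
}

#' Build full / central / peripheral ROI masks around the ONH
#'
#' Annular regions centred at the optic nerve head, all excluding the ONH
#' disc: central is `r_onh < r <= r_mid`, peripheral `r_mid < r <= r_outer`,
#' full `r_onh < r <= r_outer`, so full is exactly the disjoint union of
#' central and peripheral. Membership uses the pixel-centre convention.
#'
#' @param dim_grid Integer length-2 grid dimensions (rows = slow axis).
#' @param spacing_um Lateral grid spacing (scalar or length-2), um.
#' @param center_um ONH centre `c(y_um, x_um)` in centred coordinates.
#' @param radii_um Named or positional radii `c(r_onh, r_mid, r_outer)`, um,
#'   strictly increasing (r_onh may be 0 for no exclusion disc).
#' @return Named list of three `roi_mask` objects: `full`, `central`,
#'   `peripheral`.
#' @export
make_masks <- function(dim_grid, spacing_um, center_um = c(0, 0),
                       radii_um = c(r_onh = 160, r_mid = 460, r_outer = 760)) {
  stopifnot(length(dim_grid) == 2L, length(radii_um) == 3L)
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) == 1L) spacing_um <- rep(spacing_um, 2L)
  r <- as.numeric(radii_um)
  if (!(r[1] < r[2] && r[2] < r[3]) || r[1] < 0)
    stop("radii must satisfy 0 <= r_onh < r_mid < r_outer")
  yc <- (seq_len(dim_grid[1]) - 0.5) * spacing_um[1] - dim_grid[1] * spacing_um[1] / 2
  xc <- (seq_len(dim_grid[2]) - 0.5) * spacing_um[2] - dim_grid[2] * spacing_um[2] / 2
  R2 <- outer((yc - center_um[1])^2, (xc - center_um[2])^2, `+`)
  Rl <- sqrt(R2)
  mk <- function(mask, label) {
    structure(list(mask = mask, region = label, center_um = center_um,
                   radii_um = r, spacing_um = spacing_um),
              class = "roi_mask")
  }
  central <- Rl > r[1] & Rl <= r[2]
  peripheral <- Rl > r[2] & Rl <= r[3]
  list(full = mk(central | peripheral, "full"),
       central = mk(central, "central"),
       peripheral = mk(peripheral, "peripheral"))
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s: %d px, radii (%g, %g, %g) um\n",
              x$region, sum(x$mask), x$radii_um[1], x$radii_um[2], x$radii_um[3]))
  invisible(x)
}

#' Mean thickness inside a region of interest
#'
#' Arithmetic mean of the valid thickness values inside the mask; invalid
#' (inpainting-flagged or NA) pixels are excluded.
#'
#' @param map A [thickness_map()] object.
#' @param mask An `roi_mask` (or logical matrix) on the same grid.
#' @return List with `mean_um` and `n_px` (pixels used).
#' @export
mean_thickness <- function(map, mask) {
  stopifnot(inherits(map, "thickness_map"))
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(map$values)))
  use <- m & map$valid
  if (!any(use)) stop("no valid pixels inside the mask")
  list(mean_um = mean(map$values[use]), n_px = sum(use))
}
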