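#' Convert a dense label volume to ordered boundary surfaces
#'
#' For each of the 11 boundaries, finds the per-(bscan, lateral) transition
#' depth: the first voxel of the lower class (boundary k is the top of layer
#' k; boundary 11 is the top of the choroid). A-scans in which a class is
#' missing (e.g. inside the optic nerve head, or due to segmentation
#' failures) are inpainted by an iterated 5x5 median fill and flagged
#' invalid. Ordering across boundaries is enforced by isotonic projection
#' (pool-adjacent-violators) at positions that violate it.
#'
#' Heights use the voxel-top-face convention: a boundary reported at height
#' h (0-based continuous pixels) means the lower class starts at voxel
#' floor(h) + 1.
#'
#' @param labels A [label_volume()].
#' @return A [surface_stack()] with heights in axial pixels.
#' @export
labels_to_surfaces <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  d <- dim(labels$classes)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  M <- matrix(labels$classes, ny * nx, nz)
  present <- sort(unique(as.vector(labels$classes)))
  missing_cls <- setdiff(1:11, present)
  if (length(missing_cls)) {
    nm <- names(layer_classes())[match(missing_cls, layer_classes())]
    stop("class(es) entirely absent from the volume: ", paste(nm, collapse = ", "))
  }
  heights <- array(NA_real_, c(ny, nx, 11L))
  valid <- array(TRUE, c(ny, nx, 11L))
  for (cls in 1:11) {
    B <- M == cls
    has <- rowSums(B) > 0L
    first <- max.col(B, ties.method = "first")
    h <- ifelse(has, first - 1, NA_real_)
    heights[, , cls] <- matrix(h, ny, nx)
    valid[, , cls] <- matrix(has, ny, nx)
  }
  # inpaint missing heights, then enforce ordering
  for (cls in 1:11) heights[, , cls] <- median_inpaint(heights[, , cls])
  heights <- enforce_ordering(heights)
  surface_stack(heights, lateral_spacing_um = labels$spacing_um[1:2],
                axial_spacing_um = labels$spacing_um[3], units = "px",
                valid = valid)
}

# Iterated 5x5 median fill of NA entries; non-NA entries are untouched.
median_inpaint <- function(m, max_pass = 50L) {
  if (!anyNA(m)) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  for (pass in seq_len(max_pass)) {
    nas <- which(is.na(m), arr.ind = TRUE)
    if (!nrow(nas)) break
    filled <- m
    done <- FALSE
    for (r in seq_len(nrow(nas))) {
      i <- nas[r, 1]; j <- nas[r, 2]
      wi <- max(1, i - 2):min(n1, i + 2)
      wj <- max(1, j - 2):min(n2, j + 2)
      v <- m[wi, wj]
      v <- v[!is.na(v)]
      if (length(v)) { filled[i, j] <- stats::median(v); done <- TRUE }
    }
    m <- filled
    if (!done) break  # isolated all-NA region larger than the window
  }
  m
}

# Project each A-scan's 11 boundary heights onto the ordered (nondecreasing)
# set via pool-adjacent-violators, only where violations occur.
enforce_ordering <- function(heights) {
  d <- dim(heights)
  H <- matrix(heights, d[1] * d[2], d[3])
  viol <- which(rowSums(H[, -1, drop = FALSE] < H[, -d[3], drop = FALSE],
                        na.rm = TRUE) > 0L)
  for (r in viol) {
    y <- H[r, ]
    ok <- !is.na(y)
    if (sum(ok) > 1L) {
      ir <- stats::isoreg(seq_len(d[3])[ok], y[ok])
      y[ok] <- ir$yf
    }
    H[r, ] <- y
  }
  array(H, d)
}

#' Resample boundary surfaces to an isotropic lateral grid
#'
#' Bilinearly upsamples each height map onto a lateral grid of `target_um`
#' spacing covering the same field of view, and converts heights to
#' micrometres using the axial voxel size. The validity mask is resampled
#' conservatively: an output position is valid only if all contributing
#' input positions were valid.
#'
#' @param stack A [surface_stack()].
#' @param target_um Target isotropic lateral spacing, um (default 1.6).
#' @return A [surface_stack()] in um on the new grid.
#' @export
resample_isotropic <- function(stack, target_um = 1.6) {
  stopifnot(inherits(stack, "surface_stack"))
  if (!is.numeric(target_um) || target_um <= 0) stop("target_um must be positive")
  d <- dim(stack$heights)
  sp <- stack$lateral_spacing_um
  ext <- c(d[1] * sp[1], d[2] * sp[2])
  n_out <- pmax(2L, as.integer(round(ext / target_um)))
  x1 <- (seq_len(d[1]) - 0.5) * sp[1]
  x2 <- (seq_len(d[2]) - 0.5) * sp[2]
  xo1 <- (seq_len(n_out[1]) - 0.5) * target_um
  xo2 <- (seq_len(n_out[2]) - 0.5) * target_um
  scale <- if (stack$units == "px") stack$axial_spacing_um else 1
  heights <- array(NA_real_, c(n_out, 11L))
  valid <- array(TRUE, c(n_out, 11L))
  for (k in 1:11) {
    heights[, , k] <- bilinear_grid(stack$heights[, , k] * scale, x1, x2, xo1, xo2)
    vin <- stack$valid[, , k] * 1
    valid[, , k] <- bilinear_grid(vin, x1, x2, xo1, xo2) > 1 - 1e-9
  }
  surface_stack(heights, lateral_spacing_um = target_um,
                axial_spacing_um = stack$axial_spacing_um, units = "um",
                valid = valid)
}

# Convert a stack's height units to micrometres in place.
stack_heights_um <- function(stack) {
  if (stack$units == "um") stack$heights else stack$heights * stack$axial_spacing_um
}

#' Nearest-neighbor shortest-distance thickness between two boundaries
#'
#' At each upper-surface point, the Euclidean distance (in 3D micrometre
#' space) to the nearest lower-surface point (k = 1), following the
#' shortest-distance construction used for cortical thickness. The search
#' is restricted to a lateral window, wide enough that the restriction
#' never binds at anatomical slopes. The symmetric variant averages the
#' upper-to-lower and lower-to-upper distances.
#'
#' @param stack An isotropically resampled [surface_stack()] (units um).
#' @param upper,lower Boundary indices in 1..11 (upper < lower) or boundary
#'   names from [boundary_names()].
#' @param symmetric Average both directions (default FALSE: upper-to-lower).
#' @param window_um Lateral search half-window, um.
#' @return A [thickness_map()] object in um.
#' @export
thickness_map <- function(stack, upper, lower, symmetric = FALSE,
                          window_um = 25) {
  stopifnot(inherits(stack, "surface_stack"))
  if (is.character(upper)) upper <- match(upper, boundary_names())
  if (is.character(lower)) lower <- match(lower, boundary_names())
  stopifnot(upper >= 1, lower <= 11, upper < lower)
  H <- stack_heights_um(stack)
  sp <- stack$lateral_spacing_um
  hu <- H[, , upper]; hl <- H[, , lower]
  vu <- stack$valid[, , upper]; vl <- stack$valid[, , lower]
  if (!any(vu) || !any(vl)) stop("no valid region on the requested boundaries")
  hu_na <- hu; hu_na[!vu] <- NA_real_
  hl_na <- hl; hl_na[!vl] <- NA_real_
  if (all(is.na(hu_na))) stop("upper boundary has no valid heights")
  dmap <- nn_surface_distance(hu_na, hl_na, sp[1], sp[2], window_um)
  if (symmetric) {
    dmap2 <- nn_surface_distance(hl_na, hu_na, sp[1], sp[2], window_um)
    dmap <- (dmap + dmap2) / 2
  }
  valid <- vu & vl & !is.na(dmap)
  dmap[!valid] <- NA_real_
  thickness_map_obj(dmap, sp, valid,
                    measure = sprintf("b%d-b%d", upper, lower))
}

#' Thickness map of a single retinal layer
#'
#' @param stack Isotropic [surface_stack()].
#' @param layer Layer index 1..10 or name from [layer_names()].
#' @param ... Passed to [thickness_map()].
#' @return A [thickness_map()] object.
#' @export
layer_thickness <- function(stack, layer, ...) {
  if (is.character(layer)) layer <- match(layer, layer_names())
  stopifnot(!is.na(layer), layer >= 1, layer <= 10)
  tm <- thickness_map(stack, layer, layer + 1L, ...)
  tm$measure <- layer_names()[layer]
  tm
}

#' Composite thickness over a contiguous span of layers
#'
#' Thickness between the outermost bounding surfaces of the span (not the
#' sum of per-layer maps); the per-layer-sum variant is available for
#' cross-checks. Named spans: `total` (ILM to BM/choroid), `inner` (ILM to
#' ONL), `outer` (ELM to BM).
#'
#' @param stack Isotropic [surface_stack()].
#' @param layer_set `"total"`, `"inner"`, `"outer"`, or an integer vector of
#'   contiguous layer indices.
#' @param mode `"span"` (default) or `"sum"`.
#' @param ... Passed to [thickness_map()].
#' @return A [thickness_map()] object.
#' @export
composite_thickness <- function(stack, layer_set, mode = c("span", "sum"), ...) {
  mode <- match.arg(mode)
  if (is.character(layer_set) && length(layer_set) == 1L &&
      layer_set %in% c("total", "inner", "outer")) {
    idx <- switch(layer_set, total = 1:10, inner = 1:6, outer = 7:10)
    nm <- layer_set
  } else {
    idx <- sort(as.integer(layer_set))
    nm <- paste0("layers_", idx[1], "-", idx[length(idx)])
  }
  if (any(diff(idx) != 1L)) stop("layer_set must be a contiguous span")
  if (idx[1] < 1L || idx[length(idx)] > 10L) stop("layer indices must be in 1..10")
  if (mode == "span") {
    tm <- thickness_map(stack, idx[1], idx[length(idx)] + 1L, ...)
    tm$measure <- nm
    return(tm)
  }
  maps <- lapply(idx, function(l) layer_thickness(stack, l, ...))
  vals <- Reduce(`+`, lapply(maps, function(m) {
    v <- m$values; v[!m$valid] <- NA_real_; v
  }))
  valid <- Reduce(`&`, lapply(maps, function(m) m$valid))
  vals[!valid] <- NA_real_
  thickness_map_obj(vals, stack$lateral_spacing_um, valid,
                    measure = paste0(nm, "_sum"))
}
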