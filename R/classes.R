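#' Retinal layer class map
#'
#' Integer codes used in every [label_volume()]: 0 is background (vitreous
#' above the retina and everything below the choroid), 1--10 the ten retinal
#' layers from the combined inner limiting membrane / retinal nerve fiber
#' layer down to Bruch's membrane, and 11 the choroid.
#'
#' @return Named integer vector mapping class names to codes.
#' @export
layer_classes <- function() {
  c(background = 0L,
    `ILM-RNFL` = 1L, GCL = 2L, IPL = 3L, INL = 4L, OPL = 5L,
    ONL = 6L, ELM = 7L, PRL = 8L, RPE = 9L, BM = 10L,
    choroid = 11L)
}

#' Names of the ten retinal layers
#' @return Character vector of length 10, innermost first.
#' @export
layer_names <- function() {
  names(layer_classes())[2:11]
}

#' Names of the eleven inter-layer boundaries
#'
#' Boundary k is the upper surface of layer k (k = 1..10); boundary 11 is the
#' BM/choroid interface.
#' @return Character vector of length 11.
#' @export
boundary_names <- function() {
  ln <- layer_names()
  c(paste0("top_", ln), "BM/choroid")
}

#' Construct an OCT intensity volume
#'
#' @param intensity 3D numeric array indexed (B-scan, lateral, axial).
#' @param spacing_um Numeric length-3 vector of voxel spacings in micrometres
#'   along the (B-scan/slow, lateral/fast, axial) directions.
#' @param meta Optional named list (subject, eye, day, ...). `eye` is one of
#'   `"injected"`, `"control"` when present.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(intensity, spacing_um, meta = list()) {
  stopifnot(is.array(intensity), length(dim(intensity)) == 3L)
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    stop("spacing_um must be 3 positive finite numbers")
  structure(list(intensity = intensity, spacing_um = spacing_um, meta = meta),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<oct_volume> %d B-scans x %d lateral x %d axial, spacing (%g, %g, %g) um\n",
              d[1], d[2], d[3], x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]))
  if (length(x$meta)) {
    m <- x$meta[intersect(c("subject", "eye", "day"), names(x$meta))]
    if (length(m)) cat("  meta:", paste(names(m), unlist(m), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Construct a dense label volume
#'
#' @param classes 3D integer array aligned with the parent [oct_volume()];
#'   values must lie in `layer_classes()`.
#' @param spacing_um Voxel spacing, as for [oct_volume()].
#' @param meta Optional metadata list.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(classes, spacing_um, meta = list()) {
  stopifnot(is.array(classes), length(dim(classes)) == 3L)
  storage.mode(classes) <- "integer"
  rng <- range(classes)
  if (rng[1] < 0L || rng[2] > 11L)
    stop("label classes must be in 0..11")
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(spacing_um <= 0))
    stop("spacing_um must be 3 positive numbers")
  structure(list(classes = classes, spacing_um = spacing_um, meta = meta),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$classes)
  cat(sprintf("<label_volume> %d x %d x %d, %d classes present\n",
              d[1], d[2], d[3], length(unique(as.vector(x$classes)))))
  invisible(x)
}

#' Construct a stack of ordered boundary surfaces
#'
#' Height maps z(bscan, lateral) for the 11 inter-layer boundaries, ordered
#' from the vitreous/ILM interface down to BM/choroid. Heights are either in
#' axial pixels (`units = "px"`, 0-based continuous voxel-top-face
#' convention) or micrometres (`units = "um"`).
#'
#' @param heights 3D numeric array (n_bscan, n_lateral, 11) or a list of 11
#'   matrices.
#' @param lateral_spacing_um Length-2 lateral grid spacing (slow, fast) in um.
#' @param axial_spacing_um Axial voxel size in um (needed to convert px
#'   heights to um).
#' @param units `"px"` or `"um"`.
#' @param valid Logical array matching `heights`; FALSE marks positions whose
#'   height was inpainted or is otherwise unreliable.
#' @return An object of class `surface_stack`.
#' @export
surface_stack <- function(heights, lateral_spacing_um, axial_spacing_um,
                          units = c("px", "um"), valid = NULL) {
  units <- match.arg(units)
  if (is.list(heights)) heights <- simplify2array(heights)
  stopifnot(is.array(heights), length(dim(heights)) == 3L)
  if (dim(heights)[3] != 11L) stop("surface_stack needs 11 boundaries")
  lateral_spacing_um <- as.numeric(lateral_spacing_um)
  if (length(lateral_spacing_um) == 1L) lateral_spacing_um <- rep(lateral_spacing_um, 2L)
  if (any(lateral_spacing_um <= 0)) stop("lateral spacing must be positive")
  if (is.null(valid)) valid <- array(TRUE, dim(heights))
  stopifnot(identical(dim(valid), dim(heights)))
  structure(list(heights = heights, lateral_spacing_um = lateral_spacing_um,
                 axial_spacing_um = as.numeric(axial_spacing_um),
                 units = units, valid = valid),
            class = "surface_stack")
}

#' @export
print.surface_stack <- function(x, ...) {
  d <- dim(x$heights)
  cat(sprintf("<surface_stack> 11 boundaries on %d x %d grid (%g x %g um), heights in %s\n",
              d[1], d[2], x$lateral_spacing_um[1], x$lateral_spacing_um[2], x$units))
  invisible(x)
}

#' Construct a 2D thickness map
#'
#' @param values Numeric matrix of thicknesses in micrometres.
#' @param spacing_um Lateral grid spacing (scalar or length-2), um.
#' @param valid Logical matrix; FALSE where the value is unreliable.
#' @param measure Layer or composite name this map describes.
#' @return An object of class `thickness_map`.
#' @export
thickness_map_obj <- function(values, spacing_um, valid = NULL, measure = NA_character_) {
  stopifnot(is.matrix(values))
  if (is.null(valid)) valid <- !is.na(values)
  stopifnot(identical(dim(valid), dim(values)))
  if (any(values[valid] < -1e-9, na.rm = TRUE))
    stop("thickness values must be non-negative where valid")
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) == 1L) spacing_um <- rep(spacing_um, 2L)
  structure(list(values = values, spacing_um = spacing_um, valid = valid,
                 measure = measure),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %s: %d x %d at %g um, mean %.2f um over %d valid px\n",
              x$measure, nrow(x$values), ncol(x$values), x$spacing_um[1],
              mean(x$values[x$valid]), sum(x$valid)))
  invisible(x)
}
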