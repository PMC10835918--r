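# Volume, surface, table and configuration I/O.
#
# No NIfTI or TIFF reader is available in the supported dependency set, so
# volumes are stored as minimal single-file NIfTI-1 (.nii / .nii.gz)
# written and parsed here: intensities as float64 (lossless round-trip),
# labels as int32, voxel spacing in pixdim (mm). Only the header fields the
# package writes are interpreted on read.

nifti_datatype <- function(x) if (is.integer(x)) c(8L, 32L) else c(64L, 64L)

#' Write a volume to a NIfTI-1 file
#'
#' Intensity volumes are stored as float64 (bit-lossless), label volumes as
#' int32. Voxel spacing is recorded in `pixdim` in millimetres. `.gz`
#' endings are compressed.
#'
#' @param x An [oct_volume()] or [label_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  a <- if (inherits(x, "oct_volume")) x$intensity else
    if (inherits(x, "label_volume")) x$classes else
      stop("x must be an oct_volume or label_volume")
  spacing_mm <- x$spacing_um / 1000
  d <- dim(a)
  dt <- nifti_datatype(a)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(348L, 4L)                               # sizeof_hdr
  writeBin(raw(36L), con)                    # unused through dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)          # dim[8]
  writeBin(raw(14L), con)                    # intent params/codes
  wi(dt[1], 2L)                              # datatype
  wi(dt[2], 2L)                              # bitpix
  wi(0L, 2L)                                 # slice_start
  wf(c(1, spacing_mm, 1, 1, 1, 1))           # pixdim[8]
  wf(352)                                    # vox_offset
  wf(1); wf(0)                               # scl_slope, scl_inter
  writeBin(raw(224L), con)                   # remaining descriptive fields
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4L), con)                     # extension flag
  if (is.integer(a)) wi(as.vector(a), 4L) else
    writeBin(as.vector(a), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a volume from a NIfTI-1 file
#'
#' Integer-typed files come back as [label_volume()], float-typed files as
#' [oct_volume()]. Voxel spacing is taken from `pixdim`; a file without
#' usable spacing requires the `spacing_um` override.
#'
#' @param path Input `.nii` / `.nii.gz` path.
#' @param spacing_um Optional spacing override (um).
#' @param meta Optional metadata list to attach.
#' @return An [oct_volume()] or [label_volume()].
#' @export
read_volume <- function(path, spacing_um = NULL, meta = list()) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(hdr_size, 348L)) stop("not a NIfTI-1 file: ", path)
  readBin(con, "raw", 36L)
  dims <- readBin(con, "integer", 8L, size = 2L, endian = "little")
  if (dims[1] != 3L) stop("expected a 3D volume")
  d <- dims[2:4]
  readBin(con, "raw", 14L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "integer", 1L, size = 2L, endian = "little")  # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = "little")  # slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = "little")
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  readBin(con, "raw", 348L - 112L)  # rest of header incl. magic
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  a <- switch(as.character(datatype),
              `8` = array(readBin(con, "integer", n, size = 4L, endian = "little"), d),
              `64` = array(readBin(con, "numeric", n, size = 8L, endian = "little"), d),
              `16` = array(readBin(con, "numeric", n, size = 4L, endian = "little"), d),
              stop("unsupported NIfTI datatype: ", datatype))
  sp_um <- spacing_um %||% (pixdim[2:4] * 1000)
  if (any(!is.finite(sp_um)) || any(sp_um <= 0))
    stop("no usable voxel spacing in file and no spacing_um override given")
  if (datatype == 8L) label_volume(a, sp_um, meta) else oct_volume(a, sp_um, meta)
}

#' Write boundary surfaces to a JSON + raw container
#'
#' Portable two-file container: `<path>.json` holds boundary order, grid
#' dimensions, spacings and units; `<path>.bin` holds the 11 height maps
#' then the 11 validity masks as little-endian float64.
#'
#' @param stack A [surface_stack()].
#' @param path Basename (without extension).
#' @return `path`, invisibly.
#' @export
write_surfaces <- function(stack, path) {
  stopifnot(inherits(stack, "surface_stack"))
  hdr <- list(boundaries = boundary_names(), dim = dim(stack$heights),
              lateral_spacing_um = stack$lateral_spacing_um,
              axial_spacing_um = stack$axial_spacing_um, units = stack$units)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(stack$heights), con, size = 8L, endian = "little")
  writeBin(as.numeric(stack$valid), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read boundary surfaces written by [write_surfaces()]
#' @param path Basename used at write time.
#' @return A [surface_stack()].
#' @export
read_surfaces <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(hdr$dim)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  n <- prod(d)
  h <- array(readBin(con, "numeric", n, size = 8L, endian = "little"), d)
  v <- array(readBin(con, "numeric", n, size = 8L, endian = "little") > 0.5, d)
  surface_stack(h, hdr$lateral_spacing_um, hdr$axial_spacing_um,
                units = hdr$units, valid = v)
}

#' Write / read a cohort manifest
#'
#' The manifest is a CSV with one row per (subject, eye, day) and the file
#' paths of the volume and optional labels/surfaces. (subject, eye, day)
#' must be unique; referenced volume files must exist at load.
#'
#' @param manifest Data frame with columns `subject`, `eye`, `day`,
#'   `volume_path` and optionally `label_path`, `surface_path`.
#' @param path CSV path.
#' @return `path` (write) or the validated data frame (read).
#' @export
write_manifest <- function(manifest, path) {
  need <- c("subject", "eye", "day", "volume_path")
  if (!all(need %in% names(manifest))) stop("manifest missing columns")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "eye", "day", "volume_path")
  if (!all(need %in% names(m))) stop("manifest missing columns: ",
                                     paste(setdiff(need, names(m)), collapse = ", "))
  key <- paste(m$subject, m$eye, m$day)
  if (anyDuplicated(key)) stop("(subject, eye, day) must be unique in the manifest")
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  m$volume_path <- resolve(m$volume_path)
  missing <- !file.exists(m$volume_path)
  if (any(missing)) stop("manifest references missing volume files: ",
                         paste(utils::head(m$volume_path[missing], 3), collapse = ", "))
  m
}

#' Default nested pipeline configuration
#'
#' One section per stage, every tunable in one place; round-trips
#' losslessly through JSON and rejects unknown keys on read.
#'
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function() {
  structure(list(
    seed = 1L,
    phantom = list(desk = TRUE, n_subjects = 9L, bio_sd = 0.03,
                   meas_sd = 0.01, motion_sd = 2, effects = "paper"),
    preprocess = list(max_shift_px = 20L, poly_order = 2L, subpixel = TRUE,
                      denoise = FALSE, tv_weight = 30, tv_max_iter = 40L,
                      tv_tol = 1e-4),
    segment = list(mode = "ground_truth", hidden = 24L, cascade = FALSE,
                   epochs_frozen = 6L, epochs_finetune = 10L),
    roi = list(r_onh_um = 160, r_mid_um = 460, r_outer_um = 760,
               detect_onh = TRUE),
    surfaces = list(target_um = 8, window_um = 24, symmetric = FALSE),
    stats = list(fdr_q = 0.1, family = "panel", alpha = 0.05)),
    class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' Reading validates every key against [pipeline_config()]: unknown keys
#' are rejected.
#'
#' @param config A `pipeline_config` (write).
#' @param path JSON path.
#' @return `path` (write) or the merged `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  template <- pipeline_config()
  merge_checked <- function(tpl, val, where) {
    unknown <- setdiff(names(val), names(tpl))
    if (length(unknown)) stop("unknown config key(s) in ", where, ": ",
                              paste(unknown, collapse = ", "))
    for (nm in names(val)) {
      tpl[[nm]] <- if (is.list(tpl[[nm]]) && is.list(val[[nm]]))
        merge_checked(tpl[[nm]], val[[nm]], paste0(where, "$", nm)) else val[[nm]]
    }
    tpl
  }
  structure(merge_checked(unclass(template), raw, "config"),
            class = "pipeline_config")
}

# Content hash of an arbitrary R object (used for stage caching).
hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}
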