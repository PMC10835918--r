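#' Phantom configuration for the synthetic layered retina
#'
#' Describes the acquisition geometry and the anatomy of the synthetic
#' curved ten-layer rodent retina used to exercise the whole pipeline:
#' baseline layer thicknesses, a quadratic retinal dome, an optic-nerve-head
#' (ONH) pit in which the boundaries converge, per-class mean backscatter,
#' multiplicative gamma speckle, and vessel shadows.
#'
#' The default geometry is the native acquisition grid: a 400 x 400 x 1024
#' voxel volume spanning 1.6 x 1.6 x 1.64 mm (4 um lateral, 1.6016 um axial
#' voxels). [phantom_config_desk()] gives a scaled-down volume with the same
#' lateral field of view and the same axial voxel pitch, suitable for tests.
#'
#' @param volume_shape Integer length-3: (n_bscans, width_px, depth_px).
#' @param fov_mm Numeric length-3 field of view (slow, fast, axial), mm.
#' @param layer_thicknesses_um Named numeric length-10 baseline thicknesses
#'   (innermost first) in micrometres.
#' @param choroid_um Choroid thickness rendered below BM (no thickness
#'   target is derived from it).
#' @param curvature_coeffs Named numeric quadratic dome coefficients
#'   (`x2`, `y2`, `xy` in 1/um; `x`, `y` dimensionless) applied to centred
#'   lateral coordinates in um; the result is an axial depth offset in um.
#' @param ilm_offset_um Background (vitreous) margin above the ILM at the
#'   dome apex, um.
#' @param onh_radius_um Radius of the ONH pit within which layer
#'   thicknesses taper to zero.
#' @param layer_reflectivity Named numeric length-12 mean backscatter per
#'   class (background, ten layers, choroid), arbitrary units.
#' @param speckle_shape Gamma shape parameter k of the unit-mean
#'   multiplicative speckle; `Inf` disables noise.
#' @param vessel_density Number of simulated vessel shadows per volume.
#' @param vessel_attenuation Multiplicative intensity factor under a vessel.
#' @param seed Default RNG seed carried by the config.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(volume_shape = c(400L, 400L, 1024L),
                           fov_mm = c(1.6, 1.6, 1.64),
                           layer_thicknesses_um = c(
                             `ILM-RNFL` = 12, GCL = 15, IPL = 45, INL = 30,
                             OPL = 15, ONL = 55, ELM = 5, PRL = 30,
                             RPE = 12, BM = 4),
                           choroid_um = 60,
                           curvature_coeffs = c(x2 = 4e-5, y2 = 4e-5,
                                                xy = 0, x = 0, y = 0),
                           ilm_offset_um = 60,
                           onh_radius_um = 150,
                           layer_reflectivity = c(
                             background = 4, `ILM-RNFL` = 95, GCL = 35,
                             IPL = 70, INL = 30, OPL = 65, ONL = 25,
                             ELM = 80, PRL = 55, RPE = 100, BM = 45,
                             choroid = 20),
                           speckle_shape = 16,
                           vessel_density = 6,
                           vessel_attenuation = 0.45,
                           seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape <= 0L))
    stop("volume_shape must be 3 positive integers")
  fov_mm <- as.numeric(fov_mm)
  if (length(fov_mm) != 3L || any(fov_mm <= 0))
    stop("fov_mm must be 3 positive numbers")
  if (length(layer_thicknesses_um) != 10L || any(layer_thicknesses_um <= 0))
    stop("layer_thicknesses_um must be 10 positive values")
  if (is.null(names(layer_thicknesses_um)))
    names(layer_thicknesses_um) <- layer_names()
  if (choroid_um <= 0) stop("choroid_um must be positive")
  if (length(layer_reflectivity) != 12L)
    stop("layer_reflectivity must have 12 values (background, 10 layers, choroid)")
  if (speckle_shape <= 0) stop("speckle_shape must be positive")
  cfg <- list(volume_shape = volume_shape, fov_mm = fov_mm,
              layer_thicknesses_um = layer_thicknesses_um,
              choroid_um = choroid_um,
              curvature_coeffs = curvature_coeffs,
              ilm_offset_um = ilm_offset_um,
              onh_radius_um = onh_radius_um,
              layer_reflectivity = layer_reflectivity,
              speckle_shape = speckle_shape,
              vessel_density = as.integer(vessel_density),
              vessel_attenuation = vessel_attenuation,
              seed = as.integer(seed))
  cfg$spacing_um <- spacing_from_fov(fov_mm, volume_shape)
  structure(cfg, class = "phantom_config")
}

#' Desk-scale phantom configuration
#'
#' Same 1.6 x 1.6 mm lateral field of view and 1.6 um axial voxel pitch as
#' the native geometry, but 64 x 64 B-scans/A-scans laterally and 256 axial
#' voxels, so that whole paired-eye cohorts render in seconds.
#'
#' @param ... Overrides passed on to [phantom_config()].
#' @return A `phantom_config`.
#' @export
phantom_config_desk <- function(volume_shape = c(64L, 64L, 288L),
                                fov_mm = c(1.6, 1.6, 0.4608), ...) {
  phantom_config(volume_shape = volume_shape, fov_mm = fov_mm, ...)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %d x %d x %d voxels over %g x %g x %g mm (spacing %g/%g/%g um)\n",
              x$volume_shape[1], x$volume_shape[2], x$volume_shape[3],
              x$fov_mm[1], x$fov_mm[2], x$fov_mm[3],
              x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]))
  cat("  layers (um):", paste(names(x$layer_thicknesses_um),
                              x$layer_thicknesses_um, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Longitudinal per-layer effect profile
#'
#' Fractional thickness multipliers applied to the injected eye at each
#' follow-up day; the control eye and both eyes at day 0 always carry
#' multiplier 1.
#'
#' @param multipliers Numeric 10 x 4 matrix (layers x days 0/3/7/28), all
#'   positive, with the day-0 column identically 1.
#' @return An object of class `effect_profile`.
#' @export
effect_profile <- function(multipliers) {
  multipliers <- as.matrix(multipliers)
  if (!all(dim(multipliers) == c(10L, 4L)))
    stop("multipliers must be a 10 x 4 matrix (layers x days)")
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  if (any(abs(multipliers[, 1] - 1) > 1e-12))
    stop("day-0 multipliers must all equal 1")
  rownames(multipliers) <- layer_names()
  colnames(multipliers) <- c("0", "3", "7", "28")
  structure(list(multipliers = multipliers, days = c(0L, 3L, 7L, 28L)),
            class = "effect_profile")
}

#' The packaged excitotoxic-injury effect profile
#'
#' Per-layer multipliers encoding the longitudinal pattern of unilateral
#' NMDA-induced excitotoxic injury: early IPL thinning (from day 3),
#' delayed INL thinning (from day 7), transient ILM-RNFL thickening at day 3
#' followed by thinning at day 28, slight early ELM/RPE/BM thinning with
#' later ELM/RPE normalization, and late PRL thickening. The layer-wise
#' values are calibrated, against the default baseline thicknesses of
#' [phantom_config()], so that the composite inner-retina (ILM-ONL)
#' thickness change is about -10.5% at day 7 and -15.8% at day 28, and the
#' composite outer-retina (ELM-BM) change is about -3.9% at day 7 and +5.5%
#' at day 28.
#'
#' @return An `effect_profile`.
#' @export
paper_effects <- function() {
  m <- rbind(
    `ILM-RNFL` = c(1, 1.12, 1.00, 0.85),
    GCL        = c(1, 1.05, 0.95, 0.85),
    IPL        = c(1, 0.90, 0.75, 0.69),
    INL        = c(1, 1.00, 0.85, 0.80),
    OPL        = c(1, 1.02, 1.00, 1.00),
    ONL        = c(1, 1.01, 0.97, 0.94),
    ELM        = c(1, 0.95, 0.92, 1.00),
    PRL        = c(1, 0.99, 0.987, 1.107),
    RPE        = c(1, 0.96, 0.94, 1.00),
    BM         = c(1, 0.90, 0.88, 0.90))
  effect_profile(m)
}

#' Null effect profile (no injected change)
#' @return An `effect_profile` with all multipliers 1.
#' @export
null_effects <- function() {
  effect_profile(matrix(1, 10, 4))
}

# ONH taper: fraction of baseline thickness retained at lateral radius r.
onh_taper <- function(r_um, onh_radius_um) {
  if (onh_radius_um <= 0) return(array(1, dim(r_um) %||% length(r_um)))
  pmin((r_um / onh_radius_um)^2, 1)
}

# Centred lateral coordinate vectors (um) of a config grid.
lateral_coords <- function(config) {
  sp <- config$spacing_um
  ny <- config$volume_shape[1]; nx <- config$volume_shape[2]
  list(y = (seq_len(ny) - 0.5) * sp[1] - config$fov_mm[1] * 500,
       x = (seq_len(nx) - 0.5) * sp[2] - config$fov_mm[2] * 500)
}

#' Build the ground-truth boundary geometry of a phantom
#'
#' Boundary heights are a quadratic dome plus cumulative layer thicknesses,
#' with the ONH pit tapering all layer thicknesses to zero at the pit
#' centre so the boundaries converge there.
#'
#' @param config A [phantom_config()].
#' @param thicknesses_um Optional override of the 10 baseline layer
#'   thicknesses (used by the cohort generator to inject effects).
#' @param onh_center_um Optional (y, x) pit centre in centred lateral
#'   coordinates, um. Default c(0, 0), i.e. the grid centre.
#' @return A [surface_stack()] with heights in um on the native lateral grid.
#' @export
make_geometry <- function(config, thicknesses_um = NULL, onh_center_um = c(0, 0)) {
  stopifnot(inherits(config, "phantom_config"))
  th <- thicknesses_um %||% config$layer_thicknesses_um
  if (length(th) != 10L || any(th <= 0)) stop("need 10 positive thicknesses")
  co <- lateral_coords(config)
  cc <- config$curvature_coeffs
  X <- matrix(co$x, length(co$y), length(co$x), byrow = TRUE)
  Y <- matrix(co$y, length(co$y), length(co$x))
  dome <- (cc["x2"] %||% 0) * X^2 + (cc["y2"] %||% 0) * Y^2 +
    (cc["xy"] %||% 0) * X * Y + (cc["x"] %||% 0) * X + (cc["y"] %||% 0) * Y
  dome[is.na(dome)] <- 0
  r <- sqrt((X - onh_center_um[2])^2 + (Y - onh_center_um[1])^2)
  taper <- onh_taper(r, config$onh_radius_um)
  heights <- array(0, c(dim(dome), 11L))
  b <- config$ilm_offset_um + dome
  heights[, , 1] <- b
  for (k in 1:10) {
    b <- b + th[k] * taper
    heights[, , k + 1] <- b
  }
  depth_um <- config$fov_mm[3] * 1000
  if (max(b) + config$choroid_um >= depth_um)
    stop("geometry overflow: cumulative thickness exceeds the axial field of view")
  surface_stack(heights, lateral_spacing_um = config$spacing_um[1:2],
                axial_spacing_um = config$spacing_um[3], units = "um")
}

#' Render an OCT intensity volume and its dense label volume
#'
#' Each voxel is assigned the class of the slab containing its centre
#' (boundaries sit on voxel top faces); intensity is the per-class mean
#' reflectivity times unit-mean multiplicative gamma speckle. Vessel
#' shadows attenuate everything beneath randomly placed RNFL-level discs.
#'
#' @param surfaces Ground-truth [surface_stack()] in um from
#'   [make_geometry()] on the lateral grid of `config`.
#' @param config The [phantom_config()].
#' @param seed RNG seed; `NULL` uses `config$seed`.
#' @return List with elements `volume` ([oct_volume()]) and `labels`
#'   ([label_volume()]).
#' @export
render_volume <- function(surfaces, config, seed = NULL) {
  stopifnot(inherits(surfaces, "surface_stack"), surfaces$units == "um")
  d <- dim(surfaces$heights)
  if (!all(d[1:2] == config$volume_shape[1:2]))
    stop("surfaces are not on the lateral grid of config")
  ny <- d[1]; nx <- d[2]; nz <- config$volume_shape[3]
  dz <- config$spacing_um[3]
  seed <- seed %||% config$seed
  refl <- as.numeric(config$layer_reflectivity)

  # interface depths in voxel units; interface 12 is the choroid bottom
  co <- lateral_coords(config)
  X <- matrix(co$x, ny, nx, byrow = TRUE); Y <- matrix(co$y, ny, nx)
  taper <- onh_taper(sqrt(X^2 + Y^2), config$onh_radius_um)
  b_px <- array(0, c(ny, nx, 12L))
  b_px[, , 1:11] <- surfaces$heights / dz
  b_px[, , 12] <- (surfaces$heights[, , 11] + config$choroid_um * taper) / dz
  cnt <- array(pmin(pmax(floor(b_px + 0.5), 0), nz), dim(b_px))
  storage.mode(cnt) <- "integer"

  labels <- array(0L, c(ny, nx, nz))
  Z <- matrix(seq_len(nz), nx, nz, byrow = TRUE)
  for (i in seq_len(ny)) {
    lab <- matrix(0L, nx, nz)
    for (m in 1:12) lab <- lab + (Z > cnt[i, , m])
    lab[lab == 12L] <- 0L
    labels[i, , ] <- lab
  }

  out <- with_seed(seed, {
    intens <- array(refl[labels + 1L], dim(labels))
    if (is.finite(config$speckle_shape)) {
      k <- config$speckle_shape
      intens <- intens * array(stats::rgamma(length(intens), shape = k, rate = k),
                               dim(intens))
    }
    # vessel shadows: attenuate all voxels beneath the RNFL at random discs
    nv <- config$vessel_density
    vessels <- NULL
    if (nv > 0) {
      half <- config$fov_mm[1:2] * 500
      vy <- stats::runif(nv, -half[1] * 0.9, half[1] * 0.9)
      vx <- stats::runif(nv, -half[2] * 0.9, half[2] * 0.9)
      vr <- stats::runif(nv, 12, 28)
      vessels <- cbind(y_um = vy, x_um = vx, r_um = vr)
      for (v in seq_len(nv)) {
        hit <- which((Y - vy[v])^2 + (X - vx[v])^2 <= vr[v]^2, arr.ind = TRUE)
        if (nrow(hit)) for (h in seq_len(nrow(hit))) {
          i <- hit[h, 1]; j <- hit[h, 2]
          z0 <- cnt[i, j, 2]  # below the RNFL
          if (z0 < nz) intens[i, j, (z0 + 1L):nz] <-
              intens[i, j, (z0 + 1L):nz] * config$vessel_attenuation
        }
      }
    }
    list(intens = intens, vessels = vessels)
  })

  meta <- list(vessels = out$vessels)
  list(volume = oct_volume(out$intens, config$spacing_um, meta),
       labels = label_volume(labels, config$spacing_um, meta))
}

#' Shift every B-scan of a volume axially by a motion profile
#'
#' Positive shifts move structures toward larger axial indices. Subvoxel
#' shifts use linear interpolation; integer shifts are applied exactly so
#' that applying the negated profile restores the original voxels outside
#' the fill margins. Out-of-range voxels are filled with values resampled
#' from the B-scan's top (vitreous) margin.
#'
#' @param volume An [oct_volume()].
#' @param profile Numeric vector of per-B-scan axial displacements, pixels;
#'   length must equal the number of B-scans.
#' @param seed Seed for the background fill resampling.
#' @return The shifted [oct_volume()].
#' @export
apply_motion <- function(volume, profile, seed = 1L) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$intensity)
  if (length(profile) != d[1])
    stop("profile length must equal the number of B-scans")
  if (any(abs(profile) >= d[3]))
    stop("shift magnitude must be smaller than the axial depth")
  nz <- d[3]
  out <- volume$intensity
  with_seed(seed, {
    for (i in seq_len(d[1])) {
      s <- profile[i]
      if (s == 0) next
      M <- volume$intensity[i, , ]
      bg <- as.vector(M[, seq_len(min(4L, nz))])
      fill_n <- function(n) sample(bg, n, replace = TRUE)
      if (abs(s - round(s)) < 1e-9) {
        si <- as.integer(round(s))
        N <- matrix(0, d[2], nz)
        if (si > 0) {
          N[, (si + 1L):nz] <- M[, 1:(nz - si)]
          N[, 1:si] <- matrix(fill_n(d[2] * si), d[2], si)
        } else {
          N[, 1:(nz + si)] <- M[, (1 - si):nz]
          N[, (nz + si + 1L):nz] <- matrix(fill_n(d[2] * (-si)), d[2], -si)
        }
      } else {
        pos <- seq_len(nz) - s
        lo <- floor(pos); fr <- pos - lo
        ok <- lo >= 1L & lo + 1 <= nz
        N <- matrix(0, d[2], nz)
        N[, ok] <- M[, lo[ok]] * rep(1 - fr[ok], each = d[2]) +
          M[, lo[ok] + 1L] * rep(fr[ok], each = d[2])
        nbad <- sum(!ok)
        if (nbad) N[, !ok] <- matrix(fill_n(d[2] * nbad), d[2], nbad)
      }
      out[i, , ] <- N
    }
  })
  oct_volume(out, volume$spacing_um, volume$meta)
}

#' Random-walk axial motion profile
#'
#' @param n_bscans Number of B-scans.
#' @param sd Per-step standard deviation in pixels.
#' @param seed RNG seed.
#' @param integer Round each cumulative displacement to whole pixels.
#' @return Numeric vector of cumulative displacements (first B-scan 0).
#' @export
random_walk_profile <- function(n_bscans, sd = 2, seed = 1L, integer = FALSE) {
  p <- with_seed(seed, cumsum(c(0, stats::rnorm(n_bscans - 1L, 0, sd))))
  if (integer) p <- round(p)
  p
}

# Effective per-layer thicknesses for every (subject, eye, day) record of a
# cohort: baseline x stable per-subject biological variation x injected
# effect multiplier x per-visit measurement-scale variation.
cohort_thickness_model <- function(config, effects, n_subjects, seed,
                                   bio_sd = 0.03, meas_sd = 0.01) {
  stopifnot(inherits(effects, "effect_profile"), n_subjects >= 1)
  base <- config$layer_thicknesses_um
  days <- effects$days
  recs <- list()
  with_seed(seed, {
    for (s in seq_len(n_subjects)) {
      subj_var <- exp(stats::rnorm(10, 0, bio_sd))
      for (eye in c("injected", "control")) {
        for (di in seq_along(days)) {
          m <- if (eye == "injected") effects$multipliers[, di] else rep(1, 10)
          meas_var <- exp(stats::rnorm(10, 0, meas_sd))
          th <- base * subj_var * m * meas_var
          recs[[length(recs) + 1L]] <- list(
            subject = s, eye = eye, day = days[di],
            thickness_um = stats::setNames(th, layer_names()))
        }
      }
    }
  })
  recs
}

#' Sample per-record ground-truth layer thicknesses for a cohort
#'
#' The statistical layer of the cohort generator: effective per-layer
#' thicknesses for every (subject, eye, day) without building any volume.
#' [generate_cohort()] uses exactly these values to build its geometries, so
#' the fast path and the volumetric path agree by construction.
#'
#' @inheritParams generate_cohort
#' @return A long data.frame (subject, eye, day, layer, thickness_um).
#' @export
sample_cohort_thickness <- function(config, effects, n_subjects, seed = config$seed,
                                    bio_sd = 0.03, meas_sd = 0.01) {
  recs <- cohort_thickness_model(config, effects, n_subjects, seed, bio_sd, meas_sd)
  do.call(rbind, lapply(recs, function(r)
    data.frame(subject = r$subject, eye = r$eye, day = r$day,
               layer = layer_names(), thickness_um = unname(r$thickness_um),
               row.names = NULL)))
}

#' Generate a longitudinal paired-eye phantom cohort
#'
#' Per subject, paired eyes at days 0/3/7/28. Injected-eye layer thicknesses
#' are scaled by the effect multipliers; both eyes share a stable lognormal
#' per-subject biological variation and receive an independent lognormal
#' per-visit variation. Ground truth (labels, surfaces, motion profile,
#' effective thicknesses) is retained for every record.
#'
#' @param config A [phantom_config()].
#' @param effects An [effect_profile()].
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Cohort RNG seed.
#' @param bio_sd Lognormal sigma of the stable per-subject, per-layer
#'   biological variation.
#' @param meas_sd Lognormal sigma of the per-visit variation.
#' @param motion_sd Per-step sd (pixels) of the random-walk axial motion
#'   applied to rendered volumes; 0 disables motion.
#' @param render `"full"` renders intensity volumes (with motion applied),
#'   `"labels"` builds only labels and surfaces, `"none"` keeps just the
#'   thickness ground truth.
#' @return An object of class `phantom_cohort`: a list with `records` (one
#'   list per (subject, eye, day)) and the generating `config`, `effects`
#'   and parameters.
#' @export
generate_cohort <- function(config, effects, n_subjects, seed = config$seed,
                            bio_sd = 0.03, meas_sd = 0.01, motion_sd = 2,
                            render = c("full", "labels", "none")) {
  render <- match.arg(render)
  recs <- cohort_thickness_model(config, effects, n_subjects, seed, bio_sd, meas_sd)
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    rseed <- child_seed(seed, i)
    if (render != "none") {
      surf <- make_geometry(config, thicknesses_um = r$thickness_um)
      recs[[i]]$surfaces <- surf
      if (render == "full") {
        rv <- render_volume(surf, config, seed = rseed)
        rv$volume$meta <- c(rv$volume$meta,
                            list(subject = r$subject, eye = r$eye, day = r$day))
        rv$labels$meta <- rv$volume$meta
        prof <- if (motion_sd > 0)
          random_walk_profile(config$volume_shape[1], motion_sd,
                              seed = child_seed(rseed, 1L)) else
          rep(0, config$volume_shape[1])
        recs[[i]]$motion <- prof
        recs[[i]]$volume <- if (motion_sd > 0)
          apply_motion(rv$volume, prof, seed = child_seed(rseed, 2L)) else rv$volume
        recs[[i]]$labels <- rv$labels
      } else {
        lv <- render_labels_only(surf, config)
        lv$meta <- list(subject = r$subject, eye = r$eye, day = r$day)
        recs[[i]]$labels <- lv
        recs[[i]]$motion <- rep(0, config$volume_shape[1])
      }
    }
  }
  structure(list(records = recs, config = config, effects = effects,
                 n_subjects = n_subjects, seed = seed,
                 bio_sd = bio_sd, meas_sd = meas_sd, motion_sd = motion_sd,
                 render = render),
            class = "phantom_cohort")
}

# Label volume from geometry without intensity rendering (no RNG needed).
render_labels_only <- function(surfaces, config) {
  d <- dim(surfaces$heights)
  ny <- d[1]; nx <- d[2]; nz <- config$volume_shape[3]
  dz <- config$spacing_um[3]
  co <- lateral_coords(config)
  X <- matrix(co$x, ny, nx, byrow = TRUE); Y <- matrix(co$y, ny, nx)
  taper <- onh_taper(sqrt(X^2 + Y^2), config$onh_radius_um)
  b_px <- array(0, c(ny, nx, 12L))
  b_px[, , 1:11] <- surfaces$heights / dz
  b_px[, , 12] <- (surfaces$heights[, , 11] + config$choroid_um * taper) / dz
  cnt <- array(pmin(pmax(floor(b_px + 0.5), 0), nz), dim(b_px))
  labels <- array(0L, c(ny, nx, nz))
  Z <- matrix(seq_len(nz), nx, nz, byrow = TRUE)
  for (i in seq_len(ny)) {
    lab <- matrix(0L, nx, nz)
    for (m in 1:12) lab <- lab + (Z > cnt[i, , m])
    lab[lab == 12L] <- 0L
    labels[i, , ] <- lab
  }
  label_volume(labels, config$spacing_um)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects x 2 eyes x 4 days = %d records (render=%s)\n",
              x$n_subjects, length(x$records), x$render))
  invisible(x)
}
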