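# Shared fixtures, built in code and memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Flat, noiseless, pit-free phantom: exact-construction tests.
flat_config <- function(speckle_shape = Inf, ...) {
  phantom_config_desk(volume_shape = c(12L, 32L, 288L),
                      fov_mm = c(0.3, 0.8, 0.4608),
                      curvature_coeffs = c(x2 = 0, y2 = 0),
                      onh_radius_um = 0, vessel_density = 0L,
                      speckle_shape = speckle_shape, ...)
}

# Small curved phantom with a pit, moderate speckle: realistic-path tests.
small_config <- function(...) {
  phantom_config_desk(volume_shape = c(24L, 48L, 288L), ...)
}

# Noiseless paper-spacing phantom (4 um lateral, 1.6 um axial) with a small
# pit, for the 1.6 um-target parameter-recovery path.
recovery_config <- function() {
  phantom_config_desk(volume_shape = c(60L, 60L, 288L),
                      fov_mm = c(0.24, 0.24, 0.4608),
                      curvature_coeffs = c(x2 = 4e-5, y2 = 4e-5),
                      onh_radius_um = 30, vessel_density = 0L,
                      speckle_shape = Inf)
}

rendered_small <- function() fixture("rendered_small", function() {
  cfg <- small_config()
  surf <- make_geometry(cfg)
  c(render_volume(surf, cfg, seed = 42), list(surfaces = surf, config = cfg))
})

# Segmentation training fixtures: 16-B-scan desk phantoms.
seg_target_config <- function(...) phantom_config_desk(volume_shape = c(16L, 64L, 288L), ...)

seg_source_config <- function() {
  seg_target_config(
    layer_thicknesses_um = c(`ILM-RNFL` = 15, GCL = 18, IPL = 38, INL = 26,
                             OPL = 18, ONL = 48, ELM = 6, PRL = 34, RPE = 14, BM = 5),
    layer_reflectivity = c(background = 6, `ILM-RNFL` = 70, GCL = 45, IPL = 90,
                           INL = 20, OPL = 50, ONL = 35, ELM = 95, PRL = 40,
                           RPE = 85, BM = 60, choroid = 15))
}

seg_sets <- function() fixture("seg_sets", function() {
  list(train = phantom_labeled_set(seg_target_config(), 1, seed = 200),
       val = phantom_labeled_set(seg_target_config(), 2, seed = 201)[2])
})

trained_model <- function() fixture("trained_model", function() {
  cfg <- seg_config(seed = 7)
  s <- seg_sets()
  m <- init_seg_model(cfg, c(64L, 288L))
  m <- train_frozen_stage(m, s$train, s$val, cfg)
  train_finetune_stage(m, s$train, s$val, cfg)
})

# Brute-force all-pairs nearest-neighbor oracle for surface distances.
bruteforce_nn <- function(upper, lower, sy, sx) {
  n1 <- nrow(upper); n2 <- ncol(upper)
  pts <- cbind(rep(seq_len(n1), n2) * sy,
               rep(seq_len(n2), each = n1) * sx,
               as.vector(lower))
  out <- matrix(NA_real_, n1, n2)
  for (j in seq_len(n2)) for (i in seq_len(n1)) {
    d2 <- (pts[, 1] - i * sy)^2 + (pts[, 2] - j * sx)^2 + (pts[, 3] - upper[i, j])^2
    out[i, j] <- sqrt(min(d2, na.rm = TRUE))
  }
  out
}

# Brute-force BH step-up oracle: literal definition.
bruteforce_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}
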