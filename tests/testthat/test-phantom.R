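test_that("geometry: layer separations, ordering and the paper lateral grid", {
  cfg <- flat_config()
  surf <- make_geometry(cfg)
  h <- surf$heights
  # flat config: IPL upper/lower differ by exactly its thickness everywhere
  expect_equal(h[, , 4] - h[, , 3],
               matrix(45, dim(h)[1], dim(h)[2]), tolerance = 1e-12)
  # ordering by construction for an arbitrary curved/pitted config
  cfg2 <- small_config()
  h2 <- make_geometry(cfg2)$heights
  for (k in 1:10) expect_true(all(h2[, , k + 1] >= h2[, , k]))
  # native acquisition geometry: 400x400 lateral grid, 4 / 1.6016 um voxels
  cfgp <- phantom_config()
  expect_equal(dim(make_geometry(cfgp)$heights)[1:2], c(400L, 400L))
  expect_equal(cfgp$spacing_um[1:2], c(4, 4))
  expect_equal(cfgp$spacing_um[3], 1640 / 1024, tolerance = 1e-12)
  # overflow guard
  expect_error(make_geometry(phantom_config_desk(ilm_offset_um = 400)),
               "overflow")
})

test_that("rendered volumes: class set, zero-noise limit, determinism, histogram", {
  r <- rendered_small()
  expect_setequal(unique(as.vector(r$labels$classes)), 0:11)
  # zero-noise limit: intensities equal class means exactly
  cfg0 <- flat_config()
  s0 <- make_geometry(cfg0)
  r0 <- render_volume(s0, cfg0, seed = 1)
  refl <- cfg0$layer_reflectivity
  expect_equal(r0$volume$intensity,
               array(as.numeric(refl[r0$labels$classes + 1L]),
                     dim(r0$labels$classes)))
  # determinism: same seed, bit-identical
  cfg <- r$config
  r2 <- render_volume(r$surfaces, cfg, seed = 42)
  expect_identical(r$volume$intensity, r2$volume$intensity)
  expect_identical(r$labels$classes, r2$labels$classes)
  # class histogram consistent with volume fractions (one axial voxel per
  # boundary of slack, pit region excluded analytically via taper integral)
  lab0 <- r0$labels$classes
  n_ascan <- prod(dim(lab0)[1:2])
  for (k in 1:10) {
    expected_vox <- cfg0$layer_thicknesses_um[k] / cfg0$spacing_um[3]
    got <- sum(lab0 == k) / n_ascan
    expect_lt(abs(got - expected_vox), 1.0)
  }
})

test_that("ground-truth thickness equals boundary differences exactly", {
  r <- rendered_small()
  h <- r$surfaces$heights
  th <- r$config$layer_thicknesses_um
  co <- (seq_len(dim(h)[1]) - 0.5) * r$config$spacing_um[1] - r$config$fov_mm[1] * 500
  cx <- (seq_len(dim(h)[2]) - 0.5) * r$config$spacing_um[2] - r$config$fov_mm[2] * 500
  rr <- sqrt(outer(co^2, cx^2, `+`))
  taper <- pmin((rr / r$config$onh_radius_um)^2, 1)
  for (k in 1:10)
    expect_equal(h[, , k + 1] - h[, , k], th[k] * taper, tolerance = 1e-9)
})

test_that("apply_motion: identity, exact integer inverse, recoverable offsets", {
  r <- rendered_small()
  v <- r$volume
  expect_identical(apply_motion(v, rep(0, dim(v$intensity)[1]))$intensity,
                   v$intensity)
  prof <- round(random_walk_profile(dim(v$intensity)[1], 3, seed = 5))
  fwd <- apply_motion(v, prof, seed = 2)
  back <- apply_motion(fwd, -prof, seed = 2)
  # restored outside the fill margins
  margin <- max(abs(prof)) + 1
  nz <- dim(v$intensity)[3]
  keep <- (margin + 1):(nz - margin)
  expect_equal(back$intensity[, , keep], v$intensity[, , keep])
  expect_error(apply_motion(v, rep(nz, dim(v$intensity)[1])), "magnitude")
  expect_error(apply_motion(v, rep(0, 3)), "length")
})

test_that("apply_motion offsets match an exhaustive-shift cross-correlation oracle", {
  # flat (curvature-free) phantom: adjacent B-scans differ only by motion
  cfg <- flat_config(speckle_shape = 16)
  v <- render_volume(make_geometry(cfg), cfg, seed = 21)$volume
  prof <- random_walk_profile(dim(v$intensity)[1], 3, seed = 31)
  moved <- apply_motion(v, prof, seed = 3)
  nz <- dim(v$intensity)[3]
  band <- (nz %/% 4):(3 * nz %/% 4)
  # oracle: per-pair exhaustive integer-shift search of the NCC peak
  for (i in c(2, 5, 9, 12)) {
    prev <- moved$intensity[i - 1, , band]
    cur <- moved$intensity[i, , ]
    peak <- which.max(vapply(-20:20, function(s)
      stats::cor(as.vector(prev), as.vector(cur[, band + s])), numeric(1)))
    expect_lt(abs((-20:20)[peak] - (prof[i] - prof[i - 1])), 1 + 1e-9)
  }
})

test_that("effect profiles validate and cohorts have the paired-eye structure", {
  expect_error(effect_profile(matrix(2, 10, 4)), "day-0")
  expect_error(effect_profile(matrix(-1, 10, 4)), "positive")
  eff <- paper_effects()
  expect_equal(dim(eff$multipliers), c(10L, 4L))
  expect_true(all(eff$multipliers[, 1] == 1))
  # day-28 ILM-RNFL multiplier < 1: injected thinner than control at day 28
  expect_lt(eff$multipliers["ILM-RNFL", "28"], 1)

  cfg <- phantom_config_desk(volume_shape = c(8L, 16L, 288L))
  coh <- generate_cohort(cfg, eff, 9, seed = 3, render = "none")
  expect_length(coh$records, 72L)  # 9 subjects x 2 eyes x 4 days
  df <- sample_cohort_thickness(cfg, eff, 9, seed = 3)
  ilm28 <- df[df$layer == "ILM-RNFL" & df$day == 28, ]
  expect_lt(mean(ilm28$thickness_um[ilm28$eye == "injected"]),
            mean(ilm28$thickness_um[ilm28$eye == "control"]))
  # all-1.0 effects, zero variance: eyes identical
  df0 <- sample_cohort_thickness(cfg, null_effects(), 3, seed = 4,
                                 bio_sd = 0, meas_sd = 0)
  inj <- df0[df0$eye == "injected", ]
  ctl <- df0[df0$eye == "control", ]
  expect_equal(inj$thickness_um, ctl$thickness_um)
  # cohort generation is reproducible bit-exactly under a fixed seed
  coh2 <- generate_cohort(cfg, eff, 2, seed = 11, render = "full", motion_sd = 2)
  coh3 <- generate_cohort(cfg, eff, 2, seed = 11, render = "full", motion_sd = 2)
  expect_identical(coh2$records[[5]]$volume$intensity,
                   coh3$records[[5]]$volume$intensity)
  expect_identical(coh2$records[[5]]$motion, coh3$records[[5]]$motion)
})
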