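test_that("augment: identity draws, range limits, flip frequency, label alignment", {
  r <- rendered_small()
  img <- r$volume$intensity[3, , ]
  lab <- r$labels$classes[3, , ]
  id <- list(t_lat = 0, t_ax = 0, angle_deg = 0, zoom = 1, flip = FALSE)
  out <- augment(img, lab, params = id)
  expect_identical(out$bscan, img)
  expect_identical(out$labels, lab)
  # maximum translation draw (20, 20) is allowed; draws are within ranges
  out20 <- augment(img, lab, params = list(t_lat = 20, t_ax = 20, angle_deg = 0,
                                           zoom = 1, flip = FALSE))
  expect_identical(dim(out20$bscan), dim(img))
  # shifted content: label column moved by exactly 20 where in range
  expect_identical(out20$labels[25, 40], lab[5, 20])
  set.seed(10)
  draws <- replicate(3000, augment(matrix(0, 2, 2), matrix(0L, 2, 2))$params,
                     simplify = FALSE)
  tl <- vapply(draws, `[[`, numeric(1), "t_lat")
  ta <- vapply(draws, `[[`, numeric(1), "t_ax")
  an <- vapply(draws, `[[`, numeric(1), "angle_deg")
  zo <- vapply(draws, `[[`, numeric(1), "zoom")
  fl <- vapply(draws, `[[`, logical(1), "flip")
  expect_true(all(abs(tl) <= 20) && all(abs(ta) <= 20))
  expect_true(all(abs(an) <= 30))
  expect_true(all(zo >= 0.75 & zo <= 1.25))
  # empirical lateral-flip frequency 0.5 +/- 0.02 over 10^4 draws
  set.seed(11)
  fl2 <- replicate(10000, augment(matrix(0, 2, 2), matrix(0L, 2, 2))$params$flip)
  expect_lt(abs(mean(fl2) - 0.5), 0.02)
  # labels follow the image under a generic transform (same spatial map)
  gen <- augment(img, lab, params = list(t_lat = 5, t_ax = -8, angle_deg = 10,
                                         zoom = 1.1, flip = TRUE))
  expect_identical(dim(gen$labels), dim(lab))
  expect_true(all(gen$labels %in% 0:11))
})

test_that("freeze contract is bit-exact and unfreeze changes parameters", {
  cfg <- seg_config(seed = 7, epochs_frozen = 2L, epochs_finetune = 2L)
  s <- seg_sets()
  m0 <- init_seg_model(cfg, c(64L, 288L))
  snap <- m0$params
  m1 <- train_frozen_stage(m0, s$train, s$val, cfg)
  expect_identical(m1$params$W1, snap$W1)
  expect_identical(m1$params$b1, snap$b1)
  expect_identical(m1$params$W2, snap$W2)
  expect_identical(m1$params$b2, snap$b2)
  expect_false(identical(m1$params$W3, snap$W3))
  # best-checkpoint contract: validation loss <= at initialization
  expect_lte(m1$val_loss, m1$train_log$val_loss[1])
  m2 <- train_finetune_stage(m1, s$train, s$val, cfg)
  expect_false(identical(m2$params$W1, m1$params$W1))
  # train/val sharing a volume is refused
  expect_error(train_frozen_stage(m0, s$train, s$train, cfg), "share")
})

test_that("training is deterministic under fixed seeds", {
  cfg <- seg_config(seed = 5, epochs_frozen = 2L, epochs_finetune = 2L)
  s <- seg_sets()
  run <- function() {
    m <- init_seg_model(cfg, c(64L, 288L))
    m <- train_frozen_stage(m, s$train, s$val, cfg)
    train_finetune_stage(m, s$train, s$val, cfg)
  }
  a <- run(); b <- run()
  expect_identical(a$params, b$params)
  expect_identical(a$val_loss, b$val_loss)
})

test_that("frozen-stage segmentation beats a label-shuffled baseline", {
  cfg <- seg_config(seed = 7, epochs_frozen = 4L)
  s <- seg_sets()
  m <- train_frozen_stage(init_seg_model(cfg, c(64L, 288L)), s$train, s$val, cfg)
  ev <- s$val[[1]]
  pred <- predict_volume(m, ev$volume)
  d_model <- mean_retinal_dice(pred, ev$labels)
  shuf <- ev$labels
  set.seed(1)
  shuf$classes <- array(sample(as.vector(ev$labels$classes)),
                        dim(ev$labels$classes))
  d_shuf <- mean_retinal_dice(shuf, ev$labels)
  expect_gt(d_model, d_shuf)
})

test_that("finetune does not degrade held-out Dice; prediction is deterministic", {
  cfg <- seg_config(seed = 7)
  s <- seg_sets()
  m1 <- train_frozen_stage(init_seg_model(cfg, c(64L, 288L)), s$train, s$val, cfg)
  m2 <- train_finetune_stage(m1, s$train, s$val, cfg)
  ev <- phantom_labeled_set(seg_target_config(), 1, seed = 333)[[1]]
  d1 <- mean_retinal_dice(predict_volume(m1, ev$volume), ev$labels)
  d2 <- mean_retinal_dice(predict_volume(m2, ev$volume), ev$labels)
  expect_gte(d2, d1 - 0.005)
  p1 <- predict_volume(m2, ev$volume)
  p2 <- predict_volume(m2, ev$volume)
  expect_identical(p1$classes, p2$classes)
  # geometry mismatch and denoised input are refused
  bad <- oct_volume(array(1, c(2, 32, 64)), c(25, 25, 1.6))
  expect_error(predict_volume(m2, bad), "geometry")
  den <- ev$volume; den$meta$denoised <- TRUE
  expect_error(predict_volume(m2, den), "denoised")
})

test_that("pseudo-label round expands the set and preserves held-out Dice", {
  m <- trained_model()
  cfg <- m$config
  s <- seg_sets()
  unl <- lapply(phantom_labeled_set(seg_target_config(), 5, seed = 400),
                function(r) r$volume)
  ev <- phantom_labeled_set(seg_target_config(), 1, seed = 500)[[1]]
  d_before <- mean_retinal_dice(predict_volume(m, ev$volume), ev$labels)
  # 1 labeled + 5 unlabeled -> expanded set of 6; with the paper's counts,
  # 2 + 5 would give 7
  pr <- pseudo_label_round(m, unl, s$train, s$val, cfg)
  expect_length(pr$expanded_set, length(s$train) + 5L)
  d_after <- mean_retinal_dice(predict_volume(pr$model, ev$volume), ev$labels)
  expect_gte(d_after, d_before - 0.005)
  # pseudo-labels pass the ordering check after enforcement
  st <- labels_to_surfaces(pr$expanded_set[[2]]$labels)
  for (k in 1:10)
    expect_true(all(st$heights[, , k + 1] >= st$heights[, , k] - 1e-9))
  # empty unlabeled set: warning and no-op
  expect_warning(nothing <- pseudo_label_round(m, list(), s$train, s$val, cfg),
                 "skipped")
  expect_identical(nothing$model$params, m$params)
})

test_that("cascade option trains a second stage without losing accuracy", {
  cfg <- seg_config(seed = 7, epochs_frozen = 2L, epochs_finetune = 4L,
                    cascade = TRUE)
  s <- seg_sets()
  m <- init_seg_model(cfg, c(64L, 288L))
  m <- train_frozen_stage(m, s$train, s$val, cfg)
  base <- train_finetune_stage(m, s$train, s$val, seg_config(seed = 7,
    epochs_frozen = 2L, epochs_finetune = 4L))
  casc <- train_finetune_stage(m, s$train, s$val, cfg)
  expect_false(is.null(casc$stage2))
  expect_true("cascade" %in% casc$history)
  ev <- s$val[[1]]
  d_base <- mean_retinal_dice(predict_volume(base, ev$volume), ev$labels)
  d_casc <- mean_retinal_dice(predict_volume(casc, ev$volume), ev$labels)
  expect_gte(d_casc, d_base - 0.05)
  # cascade prediction is deterministic too
  expect_identical(predict_volume(casc, ev$volume)$classes,
                   predict_volume(casc, ev$volume)$classes)
})

test_that("dice: exact overlaps and guards", {
  mk <- function(a) label_volume(array(as.integer(a), c(1, 2, 4)), c(1, 1, 1))
  a <- mk(c(1, 1, 0, 0, 2, 2, 0, 0))
  expect_equal(unname(dice(a, a)[c("ILM-RNFL", "GCL")]), c(1, 1))
  b <- mk(c(0, 0, 1, 1, 0, 0, 2, 2))
  expect_equal(unname(dice(a, b)["ILM-RNFL"]), 0)
  # half-overlapping equal-size masks -> 0.5
  cc <- mk(c(0, 1, 1, 0, 2, 2, 0, 0))
  expect_equal(unname(dice(a, cc)["ILM-RNFL"]), 0.5)
  # empty-vs-empty class scores 1
  expect_equal(unname(dice(a, a)["RPE"]), 1)
  expect_error(dice(a, label_volume(array(0L, c(1, 2, 2)), c(1, 1, 1))),
               "identical")
})

test_that("vessel shadows do not break outer-layer surface ordering", {
  cfg <- seg_target_config(vessel_density = 10L)
  rec <- phantom_labeled_set(cfg, 1, seed = 600)[[1]]
  m <- trained_model()
  pred <- predict_volume(m, rec$volume)
  st <- labels_to_surfaces(pred)
  for (k in 1:10)
    expect_true(all(st$heights[, , k + 1] >= st$heights[, , k] - 1e-9))
})
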