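#' Segmentation model configuration
#'
#' Controls the reduced trainable B-scan segmentation model: a fixed
#' multiscale feature extractor feeding a small dense network whose final
#' layer is the pixel-wise classification head. The transfer-learning
#' schedule (freeze the feature layers, train the head, then unfreeze and
#' finetune, then a pseudo-labeling round) mirrors the protocol used with
#' full encoder-decoder architectures, at a scale trainable on one CPU in
#' seconds to minutes.
#'
#' @param hidden Width of the two hidden (feature) layers.
#' @param lr_frozen,lr_finetune Adam learning rates of the two stages.
#' @param epochs_frozen,epochs_finetune Epochs per stage.
#' @param bscans_per_epoch B-scans sampled (with augmentation) per epoch.
#' @param px_per_class Stratified pixel sample per class per B-scan.
#' @param val_px_per_class Per-class pixels in the fixed validation design.
#' @param batch_size Minibatch size.
#' @param augment Apply random affine augmentation during training.
#' @param cascade Train a second-stage network on features augmented with
#'   the first stage's smoothed class probabilities.
#' @param seed RNG seed controlling initialization, sampling and
#'   augmentation; fixed seeds give bit-reproducible training.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(hidden = 24L, lr_frozen = 0.02, lr_finetune = 0.008,
                       epochs_frozen = 6L, epochs_finetune = 16L,
                       bscans_per_epoch = 8L, px_per_class = 250L,
                       val_px_per_class = 200L, batch_size = 1024L,
                       augment = TRUE, cascade = FALSE, seed = 1L) {
  stopifnot(hidden > 0, lr_frozen > 0, lr_finetune > 0,
            epochs_frozen >= 1, epochs_finetune >= 1)
  structure(list(hidden = as.integer(hidden), lr_frozen = lr_frozen,
                 lr_finetune = lr_finetune,
                 epochs_frozen = as.integer(epochs_frozen),
                 epochs_finetune = as.integer(epochs_finetune),
                 bscans_per_epoch = as.integer(bscans_per_epoch),
                 px_per_class = as.integer(px_per_class),
                 val_px_per_class = as.integer(val_px_per_class),
                 batch_size = as.integer(batch_size),
                 augment = isTRUE(augment), cascade = isTRUE(cascade),
                 seed = as.integer(seed)),
            class = "seg_config")
}

#' Initialize a fresh segmentation model
#'
#' @param config A [seg_config()].
#' @param geometry Integer `c(width_px, depth_px)` of the B-scans the model
#'   will be trained on; inference on other geometries is refused.
#' @return An object of class `seg_model`.
#' @export
init_seg_model <- function(config, geometry) {
  stopifnot(inherits(config, "seg_config"), length(geometry) == 2L)
  structure(list(params = init_params(n_base_features(), config$hidden, 12L,
                                      config$seed),
                 config = config, geometry = as.integer(geometry),
                 n_classes = 12L, feat_ctx = NULL, stage2 = NULL,
                 history = character()),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> hidden=%d, geometry %d x %d, stages: %s\n",
              x$config$hidden, x$geometry[1], x$geometry[2],
              if (length(x$history)) paste(x$history, collapse = " -> ") else "untrained"))
  invisible(x)
}

#' Random affine augmentation of a B-scan / label pair
#'
#' Applies one identical spatial transform to the image (bilinear
#' interpolation) and the labels (nearest neighbor): lateral flip with
#' probability 0.5, rotation of up to 30 degrees (random sign), zoom of up
#' to 25%, and translations of up to 20 pixels along both the axial and
#' lateral directions (random signs). There is never an axial flip.
#' Out-of-range pixels get intensity 0 / label 0.
#'
#' @param bscan Numeric matrix (lateral x axial).
#' @param labels Integer matrix of the same dimensions.
#' @param params Optional list `(t_lat, t_ax, angle_deg, zoom, flip)`
#'   overriding the random draws (identity: all 0, zoom 1, flip FALSE).
#' @return List `bscan`, `labels`, `params`.
#' @export
augment <- function(bscan, labels, params = NULL) {
  stopifnot(is.matrix(bscan), identical(dim(bscan), dim(labels)))
  if (is.null(params)) {
    params <- list(
      t_lat = sample(c(-1, 1), 1L) * stats::runif(1, 0, 20),
      t_ax = sample(c(-1, 1), 1L) * stats::runif(1, 0, 20),
      angle_deg = sample(c(-1, 1), 1L) * stats::runif(1, 0, 30),
      zoom = stats::runif(1, 0.75, 1.25),
      flip = stats::runif(1) < 0.5)
  }
  n1 <- nrow(bscan); n2 <- ncol(bscan)
  identityish <- params$t_lat == 0 && params$t_ax == 0 &&
    params$angle_deg == 0 && params$zoom == 1 && !isTRUE(params$flip)
  if (identityish)
    return(list(bscan = bscan, labels = labels, params = params))
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
  th <- params$angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  D1 <- matrix(seq_len(n1), n1, n2) - c1
  D2 <- matrix(seq_len(n2), n1, n2, byrow = TRUE) - c2
  # inverse map: undo translation, rotation, zoom, then flip in source
  U1 <- D1 - params$t_lat
  U2 <- D2 - params$t_ax
  S1 <- (ct * U1 + st * U2) / params$zoom + c1
  S2 <- (-st * U1 + ct * U2) / params$zoom + c2
  if (isTRUE(params$flip)) S1 <- (n1 + 1) - S1
  out_img <- bilinear_sample(bscan, S1, S2, fill = 0)
  out_lab <- nearest_sample(labels, S1, S2, fill = 0L)
  list(bscan = out_img, labels = out_lab, params = params)
}

# Bilinear gather at real-valued coordinates; outside -> fill.
bilinear_sample <- function(M, S1, S2, fill = 0) {
  n1 <- nrow(M); n2 <- ncol(M)
  lo1 <- floor(S1); lo2 <- floor(S2)
  f1 <- S1 - lo1; f2 <- S2 - lo2
  ok <- lo1 >= 1 & lo1 + 1 <= n1 & lo2 >= 1 & lo2 + 1 <= n2
  edge <- S1 >= 1 & S1 <= n1 & S2 >= 1 & S2 <= n2 & !ok
  out <- matrix(fill, n1, n2)
  g <- function(i, j) M[cbind(pmin(pmax(i, 1), n1), pmin(pmax(j, 1), n2))]
  sel <- ok | edge
  out[sel] <- g(lo1[sel], lo2[sel]) * (1 - f1[sel]) * (1 - f2[sel]) +
    g(lo1[sel] + 1, lo2[sel]) * f1[sel] * (1 - f2[sel]) +
    g(lo1[sel], lo2[sel] + 1) * (1 - f1[sel]) * f2[sel] +
    g(lo1[sel] + 1, lo2[sel] + 1) * f1[sel] * f2[sel]
  out
}

nearest_sample <- function(M, S1, S2, fill = 0L) {
  n1 <- nrow(M); n2 <- ncol(M)
  i <- round(S1); j <- round(S2)
  ok <- i >= 1 & i <= n1 & j >= 1 & j <= n2
  out <- matrix(fill, n1, n2)
  out[ok] <- M[cbind(i[ok], j[ok])]
  out
}

check_distinct_sets <- function(labeled_train, labeled_val) {
  id_of <- function(r, i) r$id %||% sprintf("vol%d@%s", i,
                                            paste(dim(r$volume$intensity), collapse = "x"))
  tr <- vapply(seq_along(labeled_train),
               function(i) id_of(labeled_train[[i]], i), character(1))
  va <- vapply(seq_along(labeled_val),
               function(i) id_of(labeled_val[[i]], i + 1000L), character(1))
  shared <- intersect(tr, va)
  if (length(shared) ||
      any(vapply(labeled_train, function(a) any(vapply(labeled_val, function(b)
        identical(a$volume$intensity, b$volume$intensity), logical(1))), logical(1))))
    stop("training and validation sets must not share a volume")
}

#' Transfer-learning stage 1: train only the classification head
#'
#' All parameter tensors except the final pixel-wise classification layer
#' are preserved and frozen (bit-identical after the stage, which is
#' testable); only the head adapts to the new domain. Returns the model at
#' the best validation loss, which is never worse than at initialization.
#'
#' @param model A [init_seg_model()] model, fresh or pretrained on a
#'   source domain.
#' @param labeled_train,labeled_val Disjoint lists of records
#'   `list(volume = oct_volume, labels = label_volume, id = ...)`; at least
#'   one volume each, and they must not share a volume.
#' @param config A [seg_config()].
#' @return The updated `seg_model`.
#' @export
train_frozen_stage <- function(model, labeled_train, labeled_val, config = model$config) {
  stopifnot(inherits(model, "seg_model"), length(labeled_train) >= 1,
            length(labeled_val) >= 1)
  check_distinct_sets(labeled_train, labeled_val)
  model <- train_stage(model, labeled_train, labeled_val, config,
                       trainable = "head", lr = config$lr_frozen,
                       epochs = config$epochs_frozen,
                       seed = child_seed(config$seed, 1L))
  model$history <- c(model$history, "frozen")
  model
}

#' Transfer-learning stage 2: unfreeze and finetune all parameters
#'
#' All parameter tensors become trainable (augmentation active); returns
#' the best-validation checkpoint. With `config$cascade = TRUE` a second
#' network is subsequently trained on features augmented with the first
#' stage's smoothed class probabilities.
#'
#' @inheritParams train_frozen_stage
#' @return The updated `seg_model`.
#' @export
train_finetune_stage <- function(model, labeled_train, labeled_val, config = model$config) {
  stopifnot(inherits(model, "seg_model"))
  check_distinct_sets(labeled_train, labeled_val)
  model <- train_stage(model, labeled_train, labeled_val, config,
                       trainable = "all", lr = config$lr_finetune,
                       epochs = config$epochs_finetune,
                       seed = child_seed(config$seed, 2L))
  model$history <- c(model$history, "finetune")
  if (isTRUE(config$cascade)) {
    s2 <- structure(list(params = init_params(n_base_features() + 12L,
                                              config$hidden, 12L,
                                              child_seed(config$seed, 5L)),
                         config = config, geometry = model$geometry,
                         n_classes = 12L,
                         feat_ctx = list(params = model$params),
                         stage2 = NULL, history = character()),
                    class = "seg_model")
    s2 <- train_stage(s2, labeled_train, labeled_val, config,
                      trainable = "all", lr = config$lr_finetune,
                      epochs = config$epochs_finetune,
                      seed = child_seed(config$seed, 6L))
    model$stage2 <- s2
    model$history <- c(model$history, "cascade")
  }
  model
}

#' Pseudo-labeling round
#'
#' The trained model segments the unlabeled volumes; its predictions become
#' pseudo-ground-truth, the expanded set (manual + pseudo labels, equally
#' weighted) is assembled, and a second full finetune round is run on it.
#'
#' @param model A trained `seg_model`.
#' @param unlabeled_volumes List of [oct_volume()]s (typically baseline
#'   scans). Empty list: warning and no-op.
#' @param labeled_train,labeled_val The manually labeled records used
#'   before.
#' @param config A [seg_config()].
#' @return List with `expanded_set` (labeled + pseudo-labeled records) and
#'   `model` (after the second training round).
#' @export
pseudo_label_round <- function(model, unlabeled_volumes, labeled_train,
                               labeled_val, config = model$config) {
  stopifnot(inherits(model, "seg_model"))
  if (length(unlabeled_volumes) == 0L) {
    warning("no unlabeled volumes; pseudo-labeling round skipped")
    return(list(expanded_set = labeled_train, model = model))
  }
  pseudo <- lapply(seq_along(unlabeled_volumes), function(i) {
    v <- unlabeled_volumes[[i]]
    list(volume = v, labels = predict_volume(model, v),
         id = sprintf("pseudo%d", i))
  })
  expanded <- c(labeled_train, pseudo)
  # second round resumes from an already-converged model: half learning rate
  config$lr_finetune <- config$lr_finetune / 2
  model <- train_finetune_stage(model, expanded, labeled_val, config)
  model$history[length(model$history)] <- "pseudo-label"
  list(expanded_set = expanded, model = model)
}

#' Predict a dense label volume
#'
#' Per-B-scan 2D inference: feature extraction, forward pass, argmax over
#' class scores, reassembled into a [label_volume()]. Deterministic given a
#' model.
#'
#' @param model A trained `seg_model`.
#' @param volume An [oct_volume()] (motion-corrected, non-denoised) whose
#'   B-scan geometry matches the training geometry.
#' @return A [label_volume()].
#' @export
predict_volume <- function(model, volume) {
  stopifnot(inherits(model, "seg_model"), inherits(volume, "oct_volume"))
  d <- dim(volume$intensity)
  if (!all(d[2:3] == model$geometry))
    stop(sprintf("B-scan geometry %dx%d does not match training geometry %dx%d",
                 d[2], d[3], model$geometry[1], model$geometry[2]))
  if (isTRUE(volume$meta$denoised))
    stop("refusing to segment a denoised volume; inference runs on raw intensities")
  head_model <- model$stage2 %||% model
  out <- array(0L, d)
  for (i in seq_len(d[1])) {
    X <- model_features(head_model, volume$intensity[i, , ])
    P <- net_forward(head_model$params, X)
    out[i, , ] <- matrix(max.col(P, ties.method = "first") - 1L, d[2], d[3])
  }
  label_volume(out, volume$spacing_um, volume$meta)
}

#' Per-class Dice overlap between two label volumes
#'
#' `2|A n B| / (|A| + |B|)` for every class in the map; a class empty in
#' both volumes scores 1.
#'
#' @param pred,truth Aligned [label_volume()]s.
#' @param classes Integer classes to score (default all 12).
#' @return Named numeric vector of Dice scores in `[0, 1]`.
#' @export
dice <- function(pred, truth, classes = 0:11) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  if (!identical(dim(pred$classes), dim(truth$classes)))
    stop("label volumes must have identical dimensions")
  p <- as.vector(pred$classes); t <- as.vector(truth$classes)
  out <- vapply(classes, function(cl) {
    a <- p == cl; b <- t == cl
    na <- sum(a); nb <- sum(b)
    if (na + nb == 0L) return(1.0)
    2 * sum(a & b) / (na + nb)
  }, numeric(1))
  names(out) <- names(layer_classes())[match(classes, layer_classes())]
  out
}

#' Mean Dice over the ten retinal layer classes
#' @inheritParams dice
#' @return Scalar mean Dice over classes 1..10.
#' @export
mean_retinal_dice <- function(pred, truth) {
  mean(dice(pred, truth, classes = 1:10))
}

#' Build labeled phantom volumes for training experiments
#'
#' Renders `n` motion-free phantom volumes with ground-truth labels under a
#' config, for use as (pre)training or validation sets.
#'
#' @param config A [phantom_config()].
#' @param n Number of volumes.
#' @param seed Base seed; volume i uses a derived child seed.
#' @return List of records `list(volume, labels, id)`.
#' @export
phantom_labeled_set <- function(config, n, seed = config$seed) {
  lapply(seq_len(n), function(i) {
    surf <- make_geometry(config)
    rv <- render_volume(surf, config, seed = child_seed(seed, i))
    list(volume = rv$volume, labels = rv$labels, id = sprintf("phantom-%d-%d", seed, i))
  })
}
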