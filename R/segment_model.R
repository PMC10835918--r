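# Internal machinery of the reduced segmentation model: fixed multiscale
# feature extraction followed by a trainable per-pixel dense network whose
# last layer is the pixel-wise classification head. The fixed extractor
# plus the hidden dense layers play the role of the feature-extraction
# stages of a full encoder-decoder; the head is the "last segmentation
# layer" that the freeze/finetune schedule manipulates.

# 2D box mean with half-width r via integral image (edge-replicated counts).
box_mean <- function(M, r) {
  if (r <= 0) return(M)
  n1 <- nrow(M); n2 <- ncol(M)
  P <- matrix(0, n1 + 1L, n2 + 1L)
  P[-1L, -1L] <- apply(apply(M, 2L, cumsum), 1L, cumsum) |> t()
  i0 <- pmax(seq_len(n1) - r, 1L); i1 <- pmin(seq_len(n1) + r, n1)
  j0 <- pmax(seq_len(n2) - r, 1L); j1 <- pmin(seq_len(n2) + r, n2)
  S <- P[i1 + 1L, j1 + 1L, drop = FALSE] - P[i0, j1 + 1L, drop = FALSE] -
    P[i1 + 1L, j0, drop = FALSE] + P[i0, j0, drop = FALSE]
  cnt <- outer(i1 - i0 + 1L, j1 - j0 + 1L)
  S / cnt
}

# Per-pixel feature matrix of one B-scan (lateral x axial), N x F.
bscan_features <- function(M) {
  n1 <- nrow(M); n2 <- ncol(M)
  s <- mean(M); if (s <= 0) s <- 1
  Mn <- M / s
  b1 <- box_mean(Mn, 1L)
  b3 <- box_mean(Mn, 3L)
  b7 <- box_mean(Mn, 7L)
  gz <- cbind(b1[, 2L, drop = FALSE] - b1[, 1L, drop = FALSE],
              (b1[, -(1:2), drop = FALSE] - b1[, 1:(n2 - 2L), drop = FALSE]) / 2,
              b1[, n2, drop = FALSE] - b1[, n2 - 1L, drop = FALSE])
  z <- matrix(seq_len(n2) / n2, n1, n2, byrow = TRUE)
  zmax <- max.col(b7, ties.method = "first")
  zrel <- (matrix(seq_len(n2), n1, n2, byrow = TRUE) - zmax) / n2
  cbind(raw = as.vector(Mn), s1 = as.vector(b1), s3 = as.vector(b3),
        s7 = as.vector(b7), gz = as.vector(gz), agz = abs(as.vector(gz)),
        z = as.vector(z), zrel = as.vector(zrel))
}

n_base_features <- function() 8L

relu <- function(x) x * (x > 0)

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

init_params <- function(n_in, hidden, n_class, seed) {
  with_seed(seed, {
    he <- function(n1, n2) matrix(stats::rnorm(n1 * n2, 0, sqrt(2 / n1)), n1, n2)
    list(W1 = he(n_in, hidden), b1 = numeric(hidden),
         W2 = he(hidden, hidden), b2 = numeric(hidden),
         W3 = he(hidden, n_class), b3 = numeric(n_class))
  })
}

net_forward <- function(params, X, keep = FALSE) {
  A1 <- relu(sweep(X %*% params$W1, 2L, params$b1, `+`))
  A2 <- relu(sweep(A1 %*% params$W2, 2L, params$b2, `+`))
  P <- softmax_rows(sweep(A2 %*% params$W3, 2L, params$b3, `+`))
  if (keep) list(P = P, A1 = A1, A2 = A2) else P
}

# Cross-entropy loss; y is an integer class vector in 0..(C-1).
net_loss <- function(params, X, y) {
  P <- net_forward(params, X)
  -mean(log(pmax(P[cbind(seq_len(nrow(P)), y + 1L)], 1e-12)))
}

# Gradients of mean cross-entropy wrt all parameters.
net_grad <- function(params, X, y) {
  n <- nrow(X)
  fw <- net_forward(params, X, keep = TRUE)
  D3 <- fw$P
  D3[cbind(seq_len(n), y + 1L)] <- D3[cbind(seq_len(n), y + 1L)] - 1
  D3 <- D3 / n
  gW3 <- crossprod(fw$A2, D3); gb3 <- colSums(D3)
  D2 <- (D3 %*% t(params$W3)) * (fw$A2 > 0)
  gW2 <- crossprod(fw$A1, D2); gb2 <- colSums(D2)
  D1 <- (D2 %*% t(params$W2)) * (fw$A1 > 0)
  gW1 <- crossprod(X, D1); gb1 <- colSums(D1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t, which_params,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in which_params) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Stratified pixel sample: up to per_class pixels of each class present.
stratified_sample <- function(y, per_class) {
  idx <- split(seq_along(y), y)
  unlist(lapply(idx, function(v)
    if (length(v) <= per_class) v else sample(v, per_class)), use.names = FALSE)
}

# Assemble a (X, y) design from a set of labeled volumes: sample B-scans,
# optionally augment, extract features, stratified-sample pixels.
sample_design <- function(labeled_set, n_bscans, per_class, config,
                          do_augment = TRUE, model = NULL) {
  Xs <- list(); ys <- list()
  vols <- sample(rep(seq_along(labeled_set), length.out = n_bscans))
  for (v in vols) {
    rec <- labeled_set[[v]]
    nb <- dim(rec$volume$intensity)[1]
    b <- sample.int(nb, 1L)
    img <- rec$volume$intensity[b, , ]
    lab <- rec$labels$classes[b, , ]
    if (do_augment && isTRUE(config$augment)) {
      ag <- augment(img, lab)
      img <- ag$bscan; lab <- ag$labels
    }
    Xf <- model_features(model, img, config)
    keep <- stratified_sample(as.vector(lab), per_class)
    Xs[[length(Xs) + 1L]] <- Xf[keep, , drop = FALSE]
    ys[[length(ys) + 1L]] <- as.vector(lab)[keep]
  }
  list(X = do.call(rbind, Xs), y = unlist(ys))
}

# Features for one B-scan. When the model carries a cascade feature
# context (`feat_ctx`: a frozen first-stage network), its smoothed class
# probabilities are appended as auxiliary anatomical channels.
model_features <- function(model, img, config = NULL) {
  X <- bscan_features(img)
  ctx <- model$feat_ctx
  if (!is.null(ctx)) {
    P <- net_forward(ctx$params, X)
    n1 <- nrow(img); n2 <- ncol(img)
    aux <- vapply(seq_len(ncol(P)), function(k)
      as.vector(box_mean(matrix(P[, k], n1, n2), 2L)), numeric(length(img)))
    X <- cbind(X, aux)
  }
  X
}

# Fixed validation design built once per training stage (no augmentation).
validation_design <- function(labeled_val, config, model = NULL, seed = 99L) {
  with_seed(seed, {
    Xs <- list(); ys <- list()
    for (rec in labeled_val) {
      nb <- dim(rec$volume$intensity)[1]
      for (b in unique(round(seq(1L, nb, length.out = min(4L, nb))))) {
        img <- rec$volume$intensity[b, , ]
        lab <- rec$labels$classes[b, , ]
        Xf <- model_features(model, img, config)
        keep <- stratified_sample(as.vector(lab), config$val_px_per_class)
        Xs[[length(Xs) + 1L]] <- Xf[keep, , drop = FALSE]
        ys[[length(ys) + 1L]] <- as.vector(lab)[keep]
      }
    }
    list(X = do.call(rbind, Xs), y = unlist(ys))
  })
}

# Core training loop shared by the frozen and finetune stages.
# `trainable` is "head" (W3/b3 only) or "all". Returns the model at the
# best validation loss (including the initial state as epoch 0).
train_stage <- function(model, labeled_train, labeled_val, config,
                        trainable, lr, epochs, seed) {
  which_params <- if (trainable == "head") c("W3", "b3") else
    c("W1", "b1", "W2", "b2", "W3", "b3")
  val <- validation_design(labeled_val, config, model = model)
  params <- model$params
  best <- list(loss = net_loss(params, val$X, val$y), params = params)
  state <- adam_init(params)
  t_step <- 0L
  log <- data.frame(epoch = 0L, val_loss = best$loss)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      des <- sample_design(labeled_train, config$bscans_per_epoch,
                           config$px_per_class, config, model = model)
      ord <- sample.int(length(des$y))
      nb <- ceiling(length(ord) / config$batch_size)
      for (bi in seq_len(nb)) {
        sel <- ord[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, length(ord))]
        g <- net_grad(params, des$X[sel, , drop = FALSE], des$y[sel])
        t_step <- t_step + 1L
        st <- adam_step(params, g, state, lr, t_step, which_params)
        params <- st$params; state <- st$state
      }
      vl <- net_loss(params, val$X, val$y)
      log <- rbind(log, data.frame(epoch = ep, val_loss = vl))
      if (vl < best$loss) best <- list(loss = vl, params = params)
    }
  })
  model$params <- best$params
  model$val_loss <- best$loss
  model$train_log <- log
  model
}
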