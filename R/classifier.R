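# Image classifier: frozen convolutional trunk + trainable linear head.
#
# The audit's contribution is the masking/evaluation logic, not the backbone,
# so the backbone here is a deliberately small stand-in for a large frozen
# CNN: a fixed multi-channel convolutional trunk (smoothed, blob-detecting
# and gradient-magnitude channels) followed by grid-wise mean/max pooling
# gives a per-image embedding, and only the per-class logistic head is
# trained (Adam, mini-batches, validation-based early stopping). Any backbone
# exposing embeddings + a probabilistic head can stand behind the same model
# handle.

#' Training configuration
#'
#' Defaults mirror a frozen-backbone fine-tuning protocol: batch size 32, up
#' to 250 epochs, early stopping after 10 epochs without a validation-loss
#' improvement of at least 1e-3, augmentation by random rotation (+/- 45
#' degrees), horizontal flip (p = 0.5) and brightness scaling (0.7-1.1).
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param loss `"cross_entropy"` or `"weighted_cross_entropy"` (weights =
#'   inverse class frequency of the training folds).
#' @param max_epochs Epoch cap.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param early_stop_delta Minimum validation-loss improvement that counts.
#' @param rotation_deg Augmentation rotation range (+/- degrees).
#' @param hflip_prob Horizontal-flip probability.
#' @param brightness_range Length-2 multiplicative brightness range.
#' @param erase_prob Probability that an augmented replica receives random
#'   erasing (1-2 black rectangles); black is the padding/masking value, so
#'   this teaches the head that black patches mean absence of signal, which
#'   in turn makes occlusion-based attribution probes in-distribution.
#' @param weight_decay L2 penalty on the head weights.
#' @param hidden_units Width of the head's single hidden ReLU layer; the
#'   nonlinearity lets the head express "artifact present anywhere"
#'   (a soft OR over pooling cells), which a purely linear head cannot.
#' @param mask_dilate_aug Maximum radius (pixels) of the random ROI-mask
#'   dilation applied to augmented replicas before masking; models
#'   segmentation-boundary variability so the head does not latch onto the
#'   exact visible-area footprint. 0 (the default) disables it; dilation
#'   sweep analyses should train with a range covering the swept factors.
#' @param n_augment Stochastic augmented replicas per training image
#'   (augmentation is realised as deterministic dataset expansion, applied to
#'   the raw image before masking so masked-out regions stay exactly black).
#' @param grid Pooling grid side; the embedding has
#'   `6 * grid^2 * 3` dimensions.
#' @param seed Integer seed for head initialisation and batching.
#' @return Object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-3, batch_size = 32L,
                            loss = c("cross_entropy", "weighted_cross_entropy"),
                            max_epochs = 250L, early_stop_patience = 10L,
                            early_stop_delta = 1e-3,
                            rotation_deg = 45, hflip_prob = 0.5,
                            brightness_range = c(0.7, 1.1), erase_prob = 0.5,
                            weight_decay = 1e-3, mask_dilate_aug = 0L,
                            hidden_units = 32L,
                            n_augment = 2L, grid = 4L, seed = 1L) {
  loss <- match.arg(loss)
  if (early_stop_patience < 1) stopf("`early_stop_patience` must be >= 1")
  if (length(brightness_range) != 2 || brightness_range[1] >= brightness_range[2]) {
    stopf("`brightness_range` must be (low, high) with low < high")
  }
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 loss = loss, max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_delta = early_stop_delta,
                 rotation_deg = rotation_deg, hflip_prob = hflip_prob,
                 brightness_range = brightness_range, erase_prob = erase_prob,
                 weight_decay = weight_decay,
                 mask_dilate_aug = as.integer(mask_dilate_aug),
                 hidden_units = as.integer(hidden_units),
                 n_augment = as.integer(n_augment), grid = as.integer(grid),
                 seed = as.integer(seed)),
            class = "training_config")
}

# ---- frozen trunk -----------------------------------------------------------

.trunk_cache <- new.env(parent = emptyenv())

# Banded row-normalized Gaussian smoothing matrix (separable blur by
# G %*% X %*% t(G)); cached per (size, sigma).
gauss_mat <- function(S, sigma) {
  key <- sprintf("g_%d_%g", S, sigma)
  if (!is.null(.trunk_cache[[key]])) return(.trunk_cache[[key]])
  half <- ceiling(3 * sigma)
  idx <- seq_len(S)
  G <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    ifelse(d <= half, exp(-d^2 / (2 * sigma^2)), 0)
  })
  G <- G / rowSums(G)
  .trunk_cache[[key]] <- G
  G
}

# Trunk channels for one image: visibility (nonzero pixels; black doubles as
# padding/masking, so this is the visible-area covariate), raw, Gaussian
# blur, difference of Gaussians (blob detector), gradient magnitude, and
# local high-pass energy (texture).
trunk_channels <- function(image) {
  S <- nrow(image)
  G1 <- gauss_mat(S, 1); G2 <- gauss_mat(S, 2); G3 <- gauss_mat(S, 3)
  b1 <- G1 %*% image %*% t(G1)
  b2 <- G2 %*% image %*% t(G2)
  b3 <- G3 %*% image %*% t(G3)
  gr <- rbind(b1[2:S, ] - b1[1:(S - 1), ], 0)
  gc <- cbind(b1[, 2:S] - b1[, 1:(S - 1)], 0)
  hf <- image - b1
  list(vis = (image > 0) * 1, raw = image, blur = b2, dog = b1 - b3,
       grad = sqrt(gr^2 + gc^2), hf_energy = hf^2)
}

# Mean, upper-quantile (0.95) and max pooling over a grid x grid partition.
# The quantile is stable under changes of the visible-pixel count, unlike the
# max, which keeps occlusion/dilation effects from masquerading as texture.
pool_grid <- function(x, grid) {
  S <- nrow(x)
  cuts <- findInterval(seq_len(S) - 1L, seq(0, S, length.out = grid + 1L),
                       rightmost.closed = TRUE)
  out <- numeric(3 * grid^2)
  rs <- split(seq_len(S), cuts)
  k <- 0L
  for (b in seq_len(grid)) {
    for (a in seq_len(grid)) {
      cell <- x[rs[[a]], rs[[b]]]
      k <- k + 1L
      iq <- ceiling(0.95 * length(cell))
      srt <- sort.int(cell, partial = iq)
      out[k] <- mean(cell)
      out[grid^2 + k] <- srt[iq]
      out[2 * grid^2 + k] <- srt[length(cell)]
    }
  }
  out
}

#' Embed one image with the frozen trunk
#'
#' Pooled channel statistics plus per-cell visible-pixel-normalised ratios
#' (mean intensity and mean high-pass energy per visible pixel), which are
#' invariant to how much of a cell is masked out or padded.
#'
#' @param image Working-size image matrix on \[0, 1\].
#' @param grid Pooling grid side (default 4).
#' @return Numeric feature vector of length `6 * grid^2 * 3 + 2 * grid^2`.
#' @export
featurize_image <- function(image, grid = 4L) {
  ch <- trunk_channels(image)
  pooled <- lapply(ch, pool_grid, grid = grid)
  g2 <- grid^2
  vis_mean <- pooled$vis[seq_len(g2)]
  raw_mean <- pooled$raw[seq_len(g2)]
  hf_mean <- pooled$hf_energy[seq_len(g2)]
  denom <- pmax(vis_mean, 0.02)
  ratios <- c(raw_mean / denom, hf_mean / denom)
  c(unlist(pooled, use.names = FALSE), ratios)
}

embedding_dim_for <- function(grid) as.integer(6 * grid^2 * 3 + 2 * grid^2)

# ---- folds ------------------------------------------------------------------

#' Label-stratified K-fold assignment
#'
#' Strata are the distinct label vectors; indices within each stratum are
#' shuffled and dealt round-robin, so fold sizes and per-class positive
#' counts are balanced up to rounding. Deterministic given the seed.
#'
#' @param labels Binary vector, or matrix with one column per class.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `0..k-1`.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  if (is.matrix(labels)) {
    strata <- apply(labels, 1, paste, collapse = "/")
    n <- nrow(labels)
  } else {
    strata <- as.character(labels)
    n <- length(labels)
  }
  if (k < 2) stopf("`k` must be >= 2")
  if (n < k) stopf("need at least `k` records")
  folds <- integer(n)
  with_seed(seed, {
    start <- 0L
    for (s in unique(strata)) {
      idx <- which(strata == s)
      if (length(idx) < k) {
        warnf("stratum '%s' has fewer than %d records; assignment degrades to unstratified for it", s, k)
      }
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- (start + seq_along(idx) - 1L) %% k
      start <- (start + length(idx)) %% k
    }
  })
  folds
}

# ---- augmentation and feature sets -----------------------------------------

augment_image <- function(image, mask, rotation_deg, hflip_prob, brightness_range,
                          mask_dilate_aug = 0L, erase_prob = 0, geometry = TRUE) {
  if (mask_dilate_aug > 0) {
    f <- sample.int(mask_dilate_aug + 1L, 1L) - 1L
    if (f > 0) mask <- dilate_mask(mask, f)
  }
  if (geometry) {
    ang <- runif(1, -rotation_deg, rotation_deg)
    if (ang != 0) {
      image <- as.matrix(EBImage::rotate(image, ang, output.dim = dim(image), bg.col = 0))
      mask <- binarize_mask(as.matrix(EBImage::rotate(mask * 1.0, ang,
                                                      output.dim = dim(mask), bg.col = 0)))
    }
    if (runif(1) < hflip_prob) {
      image <- image[, rev(seq_len(ncol(image)))]
      mask <- mask[, rev(seq_len(ncol(mask)))]
    }
    image <- clip01(image * runif(1, brightness_range[1], brightness_range[2]))
  }
  if (runif(1) < erase_prob) {
    S_r <- nrow(image); S_c <- ncol(image)
    for (k in seq_len(sample.int(2L, 1L))) {
      h <- sample(round(0.06 * S_r):round(0.25 * S_r), 1L)
      w <- sample(round(0.06 * S_c):round(0.25 * S_c), 1L)
      r0 <- sample.int(S_r - h, 1L); c0 <- sample.int(S_c - w, 1L)
      image[r0:(r0 + h), c0:(c0 + w)] <- 0
    }
  }
  list(image = image, mask = mask)
}

labels_matrix <- function(records) {
  cls <- names(records[[1]]$labels)
  y <- matrix(unlist(lapply(records, function(r) as.numeric(r$labels))),
              nrow = length(records), ncol = length(cls), byrow = TRUE)
  colnames(y) <- cls
  y
}

#' Precompute trunk features for all records under one masking strategy
#'
#' Because the trunk is frozen, features depend only on (record, replica,
#' strategy) and can be shared across the K fold models. Augmented replicas
#' (augment-then-mask) are generated from deterministic per-record streams.
#'
#' @param records List of records (image, mask, labels, fold).
#' @param strategy One of [masking_strategies()].
#' @param config A [training_config()].
#' @param augment Whether to also compute `config$n_augment` augmented
#'   replicas per record (training-time only).
#' @return Object of class `feature_set`: `X` (originals), `X_aug`,
#'   `aug_index` (record index per augmented row), `y`, `folds`, `grid`,
#'   `strategy`, `input_size`.
#' @export
featurize_records <- function(records, strategy, config = training_config(),
                              augment = FALSE) {
  check_strategy(strategy)
  n <- length(records)
  S <- nrow(records[[1]]$image)
  d <- embedding_dim_for(config$grid)
  X <- matrix(0, n, d)
  for (i in seq_len(n)) {
    r <- records[[i]]
    X[i, ] <- featurize_image(apply_strategy(r$image, r$mask, strategy), config$grid)
  }
  X_aug <- NULL; aug_index <- integer(0)
  if (augment && config$n_augment > 0) {
    X_aug <- matrix(0, n * config$n_augment, d)
    aug_index <- integer(n * config$n_augment)
    row <- 0L
    for (i in seq_len(n)) {
      r <- records[[i]]
      for (j in seq_len(config$n_augment)) {
        row <- row + 1L
        # mask-boundary jitter is decoupled from the photometric/geometric
        # augmentations: all but the last replica vary only the mask
        # boundary, the last applies rotation/flip/brightness alone
        dil_only <- config$mask_dilate_aug > 0L && j < config$n_augment
        a <- with_seed(child_seed(config$seed, i, 100L + j), {
          augment_image(r$image, r$mask, config$rotation_deg,
                        config$hflip_prob, config$brightness_range,
                        mask_dilate_aug = if (dil_only || config$n_augment == 1L)
                          config$mask_dilate_aug else 0L,
                        erase_prob = config$erase_prob,
                        geometry = !dil_only)
        })
        X_aug[row, ] <- featurize_image(apply_strategy(a$image, a$mask, strategy),
                                        config$grid)
        aug_index[row] <- i
      }
    }
  }
  structure(list(X = X, X_aug = X_aug, aug_index = aug_index,
                 y = labels_matrix(records),
                 folds = vapply(records, `[[`, numeric(1), "fold"),
                 grid = config$grid, strategy = strategy, input_size = S),
            class = "feature_set")
}

# ---- head training ----------------------------------------------------------

bce_loss <- function(P, Y, W = NULL) {
  eps <- 1e-9
  L <- -(Y * log(P + eps) + (1 - Y) * log(1 - P + eps))
  if (!is.null(W)) L <- L * W
  mean(L)
}

#' Train an image classifier for one fold under one masking strategy
#'
#' Trains the per-class logistic head on trunk features of strategy-masked
#' (and augmented) images from all folds except `fold`, which is held out for
#' validation-based early stopping. Optimisation is mini-batch Adam; training
#' stops when the validation loss has not improved by `early_stop_delta` for
#' `early_stop_patience` consecutive epochs, and the best-epoch weights are
#' restored.
#'
#' @param records List of records with `image`, `mask`, `labels`, `fold`.
#' @param strategy One of [masking_strategies()].
#' @param fold Held-out fold id.
#' @param config A [training_config()].
#' @param features Optional precomputed [featurize_records()] result for this
#'   strategy (with `augment = TRUE`); computed on the fly if missing.
#' @return Object of class `maskaudit_model` with elements `W`, `b`, `center`,
#'   `scale`, `class_names`, `embedding_dim`, `input_size`, `strategy`,
#'   `fold`, `best_epoch`, `val_history`.
#' @export
train_image_classifier <- function(records, strategy, fold,
                                   config = training_config(), features = NULL) {
  if (is.null(features)) {
    features <- featurize_records(records, strategy, config, augment = TRUE)
  }
  fs <- features
  y <- fs$y
  if (any(apply(y, 2, function(c) length(unique(c)) < 2))) {
    stopf("training labels contain a single class; cannot train")
  }
  tr_orig <- which(fs$folds != fold)
  va <- which(fs$folds == fold)
  if (!length(va)) stopf("fold %s has no validation records", fold)
  Xtr <- fs$X[tr_orig, , drop = FALSE]
  Ytr <- y[tr_orig, , drop = FALSE]
  if (!is.null(fs$X_aug)) {
    keep <- fs$aug_index %in% tr_orig
    Xtr <- rbind(Xtr, fs$X_aug[keep, , drop = FALSE])
    Ytr <- rbind(Ytr, y[fs$aug_index[keep], , drop = FALSE])
  }
  Xva <- fs$X[va, , drop = FALSE]
  Yva <- y[va, , drop = FALSE]

  center <- colMeans(Xtr)
  scl <- pmax(apply(Xtr, 2, sd), 0.01)
  Xtr <- sweep(sweep(Xtr, 2, center), 2, scl, "/")
  Xva <- sweep(sweep(Xva, 2, center), 2, scl, "/")

  C <- ncol(Ytr); d <- ncol(Xtr); n <- nrow(Xtr)
  Wt <- NULL
  if (config$loss == "weighted_cross_entropy") {
    Wt <- matrix(1, n, C)
    for (c in seq_len(C)) {
      p <- mean(Ytr[, c])
      Wt[, c] <- ifelse(Ytr[, c] == 1, 1 / (2 * max(p, 1e-6)), 1 / (2 * max(1 - p, 1e-6)))
    }
  }

  H <- config$hidden_units
  par <- with_seed(child_seed(config$seed, fold, 7L), list(
    W1 = matrix(rnorm(d * H, sd = sqrt(2 / d)), d, H), b1 = rep(0, H),
    W2 = matrix(rnorm(H * C, sd = sqrt(1 / H)), H, C), b2 = rep(0, C)))
  mom <- lapply(par, function(p) p * 0)
  vel <- lapply(par, function(p) p * 0)
  bt1 <- 0.9; bt2 <- 0.999; eps <- 1e-8; t <- 0
  lr <- config$learning_rate; l2 <- config$weight_decay

  forward <- function(p, X) {
    A <- pmax(X %*% p$W1 + matrix(p$b1, nrow(X), H, byrow = TRUE), 0)
    P <- stats::plogis(A %*% p$W2 + matrix(p$b2, nrow(X), C, byrow = TRUE))
    list(A = A, P = P)
  }

  best <- list(loss = Inf, par = par, epoch = 0L)
  wait <- 0L
  val_history <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(child_seed(config$seed, fold, 1000L + epoch), sample.int(n))
    for (s in seq(1, n, by = config$batch_size)) {
      rows <- ord[s:min(s + config$batch_size - 1, n)]
      Xb <- Xtr[rows, , drop = FALSE]
      Yb <- Ytr[rows, , drop = FALSE]
      fw <- forward(par, Xb)
      G2 <- (fw$P - Yb)
      if (!is.null(Wt)) G2 <- G2 * Wt[rows, , drop = FALSE]
      nb <- nrow(Xb)
      grads <- list(
        W1 = NULL, b1 = NULL,
        W2 = crossprod(fw$A, G2) / nb + l2 * par$W2,
        b2 = colMeans(G2))
      GA <- (G2 %*% t(par$W2)) * (fw$A > 0)
      grads$W1 <- crossprod(Xb, GA) / nb + l2 * par$W1
      grads$b1 <- colMeans(GA)
      t <- t + 1
      for (nm in names(par)) {
        mom[[nm]] <- bt1 * mom[[nm]] + (1 - bt1) * grads[[nm]]
        vel[[nm]] <- bt2 * vel[[nm]] + (1 - bt2) * grads[[nm]]^2
        par[[nm]] <- par[[nm]] -
          lr * (mom[[nm]] / (1 - bt1^t)) / (sqrt(vel[[nm]] / (1 - bt2^t)) + eps)
      }
    }
    vloss <- bce_loss(forward(par, Xva)$P, Yva)
    val_history <- c(val_history, vloss)
    if (vloss < best$loss - config$early_stop_delta) {
      best <- list(loss = vloss, par = par, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }

  structure(list(head = best$par, center = center, scale = scl,
                 class_names = colnames(y), embedding_dim = d,
                 input_size = fs$input_size, grid = fs$grid,
                 strategy = fs$strategy, fold = fold,
                 best_epoch = best$epoch, val_history = val_history,
                 config_hash = config_hash(unclass(config))),
            class = "maskaudit_model")
}

#' @export
print.maskaudit_model <- function(x, ...) {
  cat(sprintf("<maskaudit_model> strategy %s, fold %d, embedding dim %d, best epoch %d/%d\n",
              x$strategy, x$fold, x$embedding_dim, x$best_epoch, length(x$val_history)))
  invisible(x)
}

as_image_list <- function(images) {
  if (is.matrix(images)) list(images)
  else if (is.list(images)) images
  else stopf("`images` must be a matrix or a list of matrices")
}

#' Per-class predicted probabilities
#'
#' @param model A `maskaudit_model`.
#' @param images A working-size image matrix or list of matrices (already
#'   masked as intended by the caller).
#' @return Matrix `(n_images, n_classes)` of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, images) {
  E <- extract_embeddings(model, images)
  predict_from_embedding(model, E)
}

#' Trunk embeddings of images
#'
#' The pooled representation feeding the classification head.
#'
#' @inheritParams predict_proba
#' @return Matrix `(n_images, embedding_dim)`.
#' @export
extract_embeddings <- function(model, images) {
  images <- as_image_list(images)
  for (im in images) {
    if (!all(dim(im) == model$input_size)) {
      stopf("image size %dx%d does not match model input size %d",
            nrow(im), ncol(im), model$input_size)
    }
  }
  E <- t(vapply(images, featurize_image, numeric(model$embedding_dim),
                grid = model$grid))
  E
}

#' Apply the stored head to an embedding matrix
#'
#' `predict_proba(model, imgs)` equals
#' `predict_from_embedding(model, extract_embeddings(model, imgs))` exactly.
#'
#' @param model A `maskaudit_model`.
#' @param E Embedding matrix `(n, embedding_dim)`.
#' @return Probability matrix `(n, n_classes)`.
#' @export
predict_from_embedding <- function(model, E) {
  if (ncol(E) != model$embedding_dim) stopf("embedding dimension mismatch")
  h <- model$head
  Z <- sweep(sweep(E, 2, model$center), 2, model$scale, "/")
  A <- pmax(Z %*% h$W1 + matrix(h$b1, nrow(E), length(h$b1), byrow = TRUE), 0)
  P <- stats::plogis(A %*% h$W2 + matrix(h$b2, nrow(E), length(h$b2), byrow = TRUE))
  colnames(P) <- model$class_names
  P
}

#' Save / load a model checkpoint with a JSON sidecar
#'
#' @param model A `maskaudit_model`.
#' @param path File path (JSON).
#' @return `path` invisibly; `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  obj <- unclass(model)
  obj$head <- lapply(obj$head, function(p) {
    if (is.matrix(p)) list(dim = dim(p), x = as.vector(p)) else list(dim = NULL, x = p)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$head <- lapply(obj$head, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$x, p$dim[1], p$dim[2]) else p$x
  })
  obj$class_names <- as.character(obj$class_names)
  structure(obj, class = "maskaudit_model")
}

# ---- tabular baseline -------------------------------------------------------

#' Logistic-regression baseline on tabular metadata
#'
#' Fits one logistic regression per fold on (`sex`, `birth_year`,
#' `projection`), using the same folds as the image models, after dropping
#' rows in which any feature is missing. Such a baseline quantifies how much
#' of the image models' performance is attainable from metadata alone.
#'
#' @param metadata Data frame with columns `sex`, `birth_year`, `projection`.
#' @param labels Binary vector or matrix (one column per class).
#' @param folds Integer fold ids aligned with `metadata` rows.
#' @return List with `fold_auc` (K x C matrix), `mean_auc` (per class),
#'   `models`, and `n_used`.
#' @export
train_tabular_baseline <- function(metadata, labels, folds) {
  need <- c("sex", "birth_year", "projection")
  if (!all(need %in% names(metadata))) {
    stopf("metadata must have columns: %s", paste(need, collapse = ", "))
  }
  if (!is.matrix(labels)) labels <- matrix(labels, ncol = 1, dimnames = list(NULL, "class"))
  complete <- stats::complete.cases(metadata[, need])
  if (!any(complete)) stopf("all rows dropped: every record has a missing feature")
  md <- metadata[complete, need, drop = FALSE]
  md$projection <- factor(md$projection)
  y <- labels[complete, , drop = FALSE]
  f <- folds[complete]

  preds <- c("sex", "birth_year", if (nlevels(md$projection) > 1) "projection")
  fml <- stats::as.formula(paste(".y ~", paste(preds, collapse = " + ")))
  ks <- sort(unique(f))
  C <- ncol(y)
  fold_auc <- matrix(NA_real_, length(ks), C,
                     dimnames = list(paste0("fold", ks), colnames(y)))
  models <- list()
  for (ki in seq_along(ks)) {
    k <- ks[ki]
    tr <- f != k; va <- f == k
    models[[ki]] <- list()
    for (c in seq_len(C)) {
      dat <- md[tr, , drop = FALSE]
      dat$.y <- y[tr, c]
      fit <- suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial()))
      p <- suppressWarnings(stats::predict(fit, newdata = md[va, , drop = FALSE],
                                           type = "response"))
      yv <- y[va, c]
      fold_auc[ki, c] <- if (length(unique(yv)) < 2) NA_real_ else auc(p, yv)
      models[[ki]][[colnames(y)[c]]] <- fit
    }
  }
  list(fold_auc = fold_auc, mean_auc = colMeans(fold_auc, na.rm = TRUE),
       models = models, n_used = sum(complete))
}
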