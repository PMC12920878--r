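# Representation proximity between full and masked images: paired cosine
# similarity tables and a 2-D stochastic neighbour projection.
#
# Standing caveat, printed with every similarity table: conclusions drawn
# from embedding similarity or 2-D projections are limited and should be
# considered carefully — the similarity ordering between masked variants can
# disagree with the AUC ordering.

SIMILARITY_CAVEAT <- paste(
  "Note: embedding-similarity and 2-D projection conclusions are limited and",
  "should be considered carefully; similarity ordering can disagree with AUC",
  "ordering.")

#' Cosine similarity between two vectors
#'
#' @param u,v Equal-length numeric vectors.
#' @return `dot(u, v) / (||u|| ||v||)`, or `NA` (with a warning) when either
#'   vector is zero.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stopf("`u` and `v` must have the same length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warnf("zero vector: cosine similarity undefined")
    return(NA_real_)
  }
  sum(u * v) / (nu * nv)
}

#' Paired cosine-similarity table between full and masked embeddings
#'
#' For each masking strategy (other than `FULL`) and each class (plus a
#' pooled `"All"` column), computes the mean and SD over images of the cosine
#' similarity between the embedding of the full image and the embedding of
#' its masked variant, paired per image, under a model trained on full
#' images.
#'
#' @param model A `maskaudit_model` trained on `FULL` images.
#' @param records Records with images and masks (typically the held-out
#'   fold).
#' @param strategies Strategies to compare against `FULL` (default the other
#'   four).
#' @return Object of class `similarity_table`: long data frame with columns
#'   `strategy`, `class`, `mean_cosine`, `sd_cosine`, `n`.
#' @export
similarity_table <- function(model, records,
                             strategies = setdiff(masking_strategies(), "FULL")) {
  E_full <- extract_embeddings(model, lapply(records, `[[`, "image"))
  y <- labels_matrix(records)
  groups <- c(All = list(seq_along(records)),
              stats::setNames(lapply(colnames(y), function(cl) which(y[, cl] == 1)),
                              colnames(y)))
  rows <- list()
  for (st in strategies) {
    imgs <- lapply(records, function(r) apply_strategy(r$image, r$mask, st))
    E_m <- extract_embeddings(model, imgs)
    sims <- vapply(seq_along(records), function(i) {
      suppressWarnings(cosine_similarity(E_full[i, ], E_m[i, ]))
    }, numeric(1))
    for (g in names(groups)) {
      idx <- groups[[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = st, class = g,
        mean_cosine = if (length(idx)) mean(sims[idx], na.rm = TRUE) else NA_real_,
        sd_cosine = if (length(idx) > 1) sd(sims[idx], na.rm = TRUE) else NA_real_,
        n = length(idx))
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("similarity_table", "data.frame"))
}

#' @export
print.similarity_table <- function(x, ...) {
  print.data.frame(x, ...)
  cat(SIMILARITY_CAVEAT, "\n")
  invisible(x)
}

# ---- 2-D stochastic neighbour projection ------------------------------------

# Per-point conditional affinities whose perplexity matches the target, via
# binary search on the Gaussian bandwidth.
tsne_affinities <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in seq_len(50)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0 } else {
        H <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    P[i, -i] <- if (sum(w) == 0) 1 / (n - 1) else w / sum(w)
  }
  P
}

#' Project embeddings to 2-D with t-SNE
#'
#' Exact (O(n^2)) t-distributed stochastic neighbour embedding with
#' deterministic PCA initialisation, early exaggeration, and momentum
#' gradient descent. Points exceeding `max_points` are subsampled, stratified
#' by `labels`.
#'
#' @param embeddings Numeric matrix (n x d), n >= 10.
#' @param labels Optional tags (e.g. masking strategy) per row, used for
#'   stratified subsampling and returned alongside the coordinates.
#' @param seed Integer seed (subsampling; the optimisation itself is
#'   deterministic given the PCA initialisation).
#' @param perplexity t-SNE perplexity (default 30, reduced automatically for
#'   small n down to a floor of 2).
#' @param max_iter Gradient-descent iterations.
#' @param max_points Subsample cap (default 2000).
#' @return Data frame with columns `x`, `y`, and `label`.
#' @export
project_2d <- function(embeddings, labels = NULL, seed = 1L, perplexity = 30,
                       max_iter = 400L, max_points = 2000L) {
  n <- nrow(embeddings)
  if (n < 10) stopf("need at least 10 embeddings for a 2-D projection")
  if (is.null(labels)) labels <- rep("all", n)
  if (n > max_points) {
    idx <- with_seed(seed, {
      unlist(lapply(split(seq_len(n), labels), function(ix) {
        sample(ix, max(1L, round(length(ix) * max_points / n)))
      }), use.names = FALSE)
    })
    embeddings <- embeddings[idx, , drop = FALSE]
    labels <- labels[idx]
    n <- nrow(embeddings)
  }
  # identical rows are embedded once and share coordinates (coincident by
  # construction; pairwise affinities are undefined at zero distance)
  key <- apply(embeddings, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  map <- match(key, key[first])
  uX <- embeddings[first, , drop = FALSE]
  nu <- nrow(uX)
  if (3 * perplexity >= nu) {
    perplexity <- max(2, floor((nu - 1) / 3))
    if (3 * perplexity >= nu) {
      stopf("too few points for any admissible perplexity; provide at least 10 distinct points")
    }
  }

  X <- scale(uX, center = TRUE, scale = FALSE)
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsne_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * nu)
  P <- pmax(P, 1e-12)

  # deterministic PCA initialisation
  pc <- stats::prcomp(X, rank. = 2)
  Y <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  if (ncol(Y) < 2) Y <- cbind(Y, 0)
  Y <- Y / max(stats::sd(Y[, 1]), 1e-12) * 1e-4

  mom <- 0.5; gain <- matrix(1, nu, 2); dY <- matrix(0, nu, 2)
  eta <- 200
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 100) 12 else 1
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gain <- ifelse(sign(grad) != sign(dY), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    dY <- mom * dY - eta * gain * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == 100) mom <- 0.8
  }
  Y <- Y[map, , drop = FALSE]
  data.frame(x = Y[, 1], y = Y[, 2], label = labels, stringsAsFactors = FALSE)
}
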