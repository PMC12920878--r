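# AUC, the DeLong test for correlated AUCs, the fold-wise significance rule,
# the cross-masking AUC matrix, and dilation sweep curves.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive outranks a random negative, with half
#' credit for ties; computed from midranks, which equals the exhaustive
#' pairwise count exactly.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (both classes present).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("`scores` and `labels` lengths differ")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present to compute an AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components via midranks: per-positive placements V10 and
# per-negative placements V01, plus the AUC.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  n1 <- length(pos); n0 <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r_pos) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' Variance of a single AUC (DeLong estimator)
#'
#' @inheritParams auc
#' @return Estimated variance of the AUC.
#' @export
auc_variance <- function(scores, labels) {
  labels <- as.integer(labels)
  pl <- delong_placements(scores, labels)
  var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the same samples. The
#' covariance of the two AUCs is estimated from the structural components
#' (midrank placements, so ties are handled exactly), and
#' \eqn{z = (A_a - A_b)/\sqrt{\mathrm{var}(A_a - A_b)}} is referred to the
#' standard normal, two-sided. When the variance of the difference is zero,
#' `p = 1` if the AUCs are equal and `p = 0` (with a warning) otherwise.
#'
#' @param scores_a,scores_b Score vectors on the same samples.
#' @param labels Binary labels (both classes present).
#' @return List with `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) stopf("score vectors must have the same length")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  n1 <- length(pa$v10); n0 <- length(pa$v01)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(d) < 1e-12) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1))
    }
    warnf("zero variance of the AUC difference with unequal AUCs; p set to 0")
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = sign(d) * Inf, p = 0))
  }
  z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * pnorm(-abs(z)))
}

#' One-sided label-permutation p-value for an AUC above chance
#'
#' Tests whether an AUC is significantly above a label-permuted null:
#' `p = (1 + #\{AUC_perm >= AUC_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams auc
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return List with `auc` and `p`.
#' @export
permutation_auc_pvalue <- function(scores, labels, n_perm = 200L, seed = 1L) {
  obs <- auc(scores, labels)
  labels <- as.integer(labels)
  ge <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      auc(scores, sample(labels)) >= obs
    }, logical(1)))
  })
  list(auc = obs, p = (1 + ge) / (n_perm + 1))
}

#' Fold-wise significance rule
#'
#' A comparison is significant when the p-value is strictly below `alpha` in
#' at least `min_folds` folds.
#'
#' @param p_values One p-value per fold.
#' @param alpha Significance level (default 0.05).
#' @param min_folds Minimum number of significant folds (default 3).
#' @return Logical flag.
#' @export
aggregate_significance <- function(p_values, alpha = 0.05, min_folds = 3L) {
  if (!length(p_values)) stopf("`p_values` must be nonempty")
  sum(p_values < alpha) >= min_folds
}

# ---- cross-masking matrix ---------------------------------------------------

#' Cross-masking AUC matrix
#'
#' Evaluates every (train strategy, fold) model on every masked variant of
#' the test records: a train-strategy x eval-strategy x class grid of mean
#' and SD AUC over the K fold models. Cells whose evaluation subset contains
#' a single class are recorded as missing (`NA`), not 0.5.
#'
#' @param models Named list (one entry per train strategy) of lists of fold
#'   models.
#' @param records Test records with masks.
#' @param strategies Strategies to span (default all five); every listed
#'   train strategy must have a model list.
#' @return Object of class `auc_matrix`: a long data frame with columns
#'   `train_strategy`, `eval_strategy`, `class`, `mean_auc`, `sd_auc`, plus
#'   attribute `fold_auc` (4-d array strategy x strategy x class x fold).
#' @export
cross_masking_evaluation <- function(models, records, strategies = masking_strategies()) {
  missing_models <- setdiff(strategies, names(models))
  if (length(missing_models)) {
    stopf("no trained models for strategy: %s", paste(missing_models, collapse = ", "))
  }
  y <- labels_matrix(records)
  classes <- colnames(y)
  n_folds <- max(lengths(models[strategies]))
  fold_auc <- array(NA_real_, c(length(strategies), length(strategies), length(classes), n_folds),
                    dimnames = list(strategies, strategies, classes, NULL))
  for (es in strategies) {
    imgs <- lapply(records, function(r) apply_strategy(r$image, r$mask, es))
    # embeddings shared across train strategies for this eval variant
    E <- extract_embeddings(models[[strategies[1]]][[1]], imgs)
    for (ts in strategies) {
      if (!length(models[[ts]])) stopf("no trained models for strategy: %s", ts)
      for (fi in seq_along(models[[ts]])) {
        P <- predict_from_embedding(models[[ts]][[fi]], E)
        for (ci in seq_along(classes)) {
          yv <- y[, ci]
          fold_auc[ts, es, ci, fi] <-
            if (length(unique(yv)) < 2) NA_real_ else auc(P[, ci], yv)
        }
      }
    }
  }
  long <- expand.grid(train_strategy = strategies, eval_strategy = strategies,
                      class = classes, stringsAsFactors = FALSE)
  long$mean_auc <- mapply(function(ts, es, cl) mean(fold_auc[ts, es, cl, ], na.rm = TRUE),
                          long$train_strategy, long$eval_strategy, long$class)
  long$sd_auc <- mapply(function(ts, es, cl) sd(fold_auc[ts, es, cl, ], na.rm = TRUE),
                        long$train_strategy, long$eval_strategy, long$class)
  long$mean_auc[is.nan(long$mean_auc)] <- NA_real_
  structure(long, fold_auc = fold_auc, class = c("auc_matrix", "data.frame"))
}

#' Extract one cell of an `auc_matrix`
#'
#' @param m An `auc_matrix`.
#' @param train_strategy,eval_strategy,class Cell coordinates.
#' @return Row of the long table (mean and SD AUC).
#' @export
auc_cell <- function(m, train_strategy, eval_strategy, class = NULL) {
  if (is.null(class)) class <- unique(m$class)[1]
  m[m$train_strategy == train_strategy & m$eval_strategy == eval_strategy &
      m$class == class, , drop = FALSE]
}

# ---- dilation sweeps --------------------------------------------------------

#' Dilation sweep of the AUC
#'
#' For each dilation factor, the masks of the selected record subset
#' (`all`, `positives_only`, or `negatives_only`) are dilated before applying
#' the base strategy (`ONLY_ROI` or `NO_ROI`), and the resulting set is
#' scored by each fold model. Sweeping a model trained on `FULL` images
#' probes how much area around the ROI it needs; sweeping positives only on
#' an `ONLY_ROI` model exposes ROI-size confounds.
#'
#' @param models List of fold models (all trained on the same strategy).
#' @param records Records with masks.
#' @param base `"ONLY_ROI"` or `"NO_ROI"`.
#' @param factors Strictly increasing nonnegative dilation radii.
#' @param subset `"all"`, `"positives_only"`, or `"negatives_only"` (which
#'   records' masks get dilated).
#' @param class_name Class whose label defines the subset (default first).
#' @return Object of class `dilation_curve`: data frame with `factor`,
#'   `subset`, `mean_auc`, `sd_auc`, plus attribute `fold_auc`.
#' @export
dilation_sweep <- function(models, records, base = c("ONLY_ROI", "NO_ROI"),
                           factors = c(0, 5, 10, 25, 50),
                           subset = c("all", "positives_only", "negatives_only"),
                           class_name = NULL) {
  base <- match.arg(base)
  subset <- match.arg(subset)
  if (is.unsorted(factors, strictly = TRUE)) stopf("`factors` must be strictly increasing")
  y <- labels_matrix(records)
  if (is.null(class_name)) class_name <- colnames(y)[1]
  yv <- y[, class_name]
  dil_rows <- switch(subset,
    all = seq_along(records),
    positives_only = which(yv == 1),
    negatives_only = which(yv == 0))
  if (!length(dil_rows)) stopf("selected subset is empty")

  fold_auc <- matrix(NA_real_, length(factors), length(models))
  for (qi in seq_along(factors)) {
    f <- factors[qi]
    imgs <- lapply(seq_along(records), function(i) {
      m <- records[[i]]$mask
      if (f > 0 && i %in% dil_rows) m <- dilate_mask(m, f)
      apply_strategy(records[[i]]$image, m, base)
    })
    E <- extract_embeddings(models[[1]], imgs)
    for (fi in seq_along(models)) {
      P <- predict_from_embedding(models[[fi]], E)
      fold_auc[qi, fi] <- auc(P[, class_name], yv)
    }
  }
  out <- data.frame(factor = factors, subset = subset,
                    mean_auc = rowMeans(fold_auc),
                    sd_auc = apply(fold_auc, 1, sd))
  structure(out, fold_auc = fold_auc, class = c("dilation_curve", "data.frame"))
}
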