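# Independent brute-force oracles used to check the fast implementations.

# O(n^2) pairwise AUC: mean over (positive, negative) pairs of
# [s_p > s_n] + 0.5 [s_p == s_n].
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Exhaustive bounding-box scan.
bbox_scan_oracle <- function(mask) {
  rmin <- Inf; rmax <- -Inf; cmin <- Inf; cmax <- -Inf
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] != 0) {
      rmin <- min(rmin, r); rmax <- max(rmax, r)
      cmin <- min(cmin, c); cmax <- max(cmax, c)
    }
  }
  c(rmin - 1, cmin - 1, rmax - 1, cmax - 1)
}

# Brute-force Euclidean dilation: pixel is on iff within `r` of any on-pixel.
dilate_bruteforce_oracle <- function(mask, r) {
  on <- which(mask != 0, arr.ind = TRUE)
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    d2 <- (on[, 1] - i)^2 + (on[, 2] - j)^2
    if (any(d2 <= r^2)) out[i, j] <- 1L
  }
  out
}

# Paired-bootstrap two-sided p-value for the difference of two AUCs computed
# on the same samples (independent cross-check of the DeLong test).
paired_bootstrap_auc_test <- function(scores_a, scores_b, labels, B = 200, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  d_obs <- auc(scores_a, labels) - auc(scores_b, labels)
  ds <- replicate(B, {
    idx <- sample.int(n, replace = TRUE)
    while (length(unique(labels[idx])) < 2) idx <- sample.int(n, replace = TRUE)
    auc(scores_a[idx], labels[idx]) - auc(scores_b[idx], labels[idx])
  })
  se <- sd(ds)
  if (se == 0) return(if (abs(d_obs) < 1e-12) 1 else 0)
  2 * pnorm(-abs(d_obs / se))
}

# Toy coalition "models" for Shapley checks: each takes a working image and
# returns a per-class output vector, computed from per-segment mean
# intensities (occluded pixels are 0, so occlusion lowers segment means).
toy_linear_model <- function(segmap, weights) {
  force(segmap); force(weights)
  function(image) {
    means <- vapply(seq_along(weights) - 1L, function(l) mean(image[segmap == l]),
                    numeric(1))
    sum(weights * means)
  }
}

toy_interaction_model <- function(segmap) {
  force(segmap)
  function(image) {
    m <- vapply(0:(max(segmap)), function(l) mean(image[segmap == l]), numeric(1))
    # interactions of all orders (exp of the total) plus a three-way product:
    # antithetic permutation pairs average out pairwise interactions exactly,
    # so higher-order terms are needed for a nondegenerate estimator variance
    c(exp(sum(m) / 2) + 3 * m[1] * m[2] * m[3] - 2 * sqrt(abs(m[length(m)])))
  }
}
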