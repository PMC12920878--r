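# Superpixel Shapley attribution with occlusion, plus an exact enumeration
# oracle and an in-ROI attribution-share summary.
#
# The image is partitioned into M superpixels; the "game" value of a
# coalition S is the model output on the image with all segments outside S
# occluded to black (0, the masking/padding value). Shapley values fairly
# split f(image) - f(all-occluded) across segments.

#' Partition an image into grid superpixels
#'
#' Default regular grid: `ceiling(sqrt(M))` cells per side; when the grid has
#' more cells than `n_segments`, surplus cells are merged cyclically so that
#' labels `0..M-1` are all nonempty and the segments partition the image.
#' Content-based segmentations can be substituted: any integer label matrix
#' with labels `0..M-1` is accepted downstream.
#'
#' @param image Image matrix (only its shape is used).
#' @param n_segments Number of superpixels M (1 to the pixel count).
#' @return Integer label matrix (class `superpixel_map`) with labels
#'   `0..M-1`.
#' @export
make_superpixels <- function(image, n_segments) {
  S_r <- nrow(image); S_c <- ncol(image)
  if (n_segments < 1 || n_segments > S_r * S_c) {
    stopf("`n_segments` must lie in [1, %d]", S_r * S_c)
  }
  side <- ceiling(sqrt(n_segments))
  ri <- findInterval(seq_len(S_r) - 1L, seq(0, S_r, length.out = side + 1L),
                     rightmost.closed = TRUE) - 1L
  ci <- findInterval(seq_len(S_c) - 1L, seq(0, S_c, length.out = side + 1L),
                     rightmost.closed = TRUE) - 1L
  lab <- outer(ri, ci, function(a, b) a * side + b)
  lab <- lab %% n_segments
  structure(lab, class = c("superpixel_map", class(lab)))
}

# Accept either a maskaudit_model or a plain function(image) -> numeric
# vector of per-class outputs.
as_predictor <- function(model) {
  if (inherits(model, "maskaudit_model")) {
    function(image) as.numeric(predict_proba(model, image))
  } else if (is.function(model)) {
    function(image) as.numeric(model(image))
  } else stopf("`model` must be a maskaudit_model or a function(image) -> numeric")
}

# Coalition value oracle with caching. Coalitions are logical vectors of
# length M (TRUE = segment kept, others occluded to 0).
make_value_fn <- function(predict_fn, image, segmap, M) {
  cache <- new.env(parent = emptyenv())
  calls <- new.env(parent = emptyenv()); calls$n <- 0L
  seg_idx <- lapply(seq_len(M) - 1L, function(l) which(segmap == l))
  v <- function(keep) {
    key <- rawToChar(as.raw(48L + as.integer(keep)))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    img <- image
    for (l in which(!keep)) img[seg_idx[[l]]] <- 0
    out <- predict_fn(img)
    calls$n <- calls$n + 1L
    cache[[key]] <- out
    out
  }
  list(v = v, calls = calls)
}

attribution_result <- function(values, class_names, n_evaluations, exact) {
  structure(list(values = values, class_names = class_names,
                 n_evaluations = n_evaluations, baseline_kind = "occlusion",
                 exact = exact),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> %d segments x %d classes, %d model evaluations (%s)\n",
              nrow(x$values), ncol(x$values), x$n_evaluations,
              if (x$exact) "exact" else "Monte-Carlo"))
  invisible(x)
}

#' Monte-Carlo Shapley occlusion attribution
#'
#' Estimates per-segment Shapley values under the occlusion game within a
#' budget of `n_evals` model calls. When the budget covers exhaustive
#' enumeration (`2^M <= n_evals`) every coalition is evaluated and the exact
#' weighted-marginal formula is applied; otherwise segment permutations are
#' sampled in antithetic pairs (a permutation and its reverse), coalition
#' values are cached, and the estimate is the average marginal contribution,
#' with any residual spread uniformly so that efficiency
#' (values sum to `f(x) - f(all-occluded)`) holds exactly.
#'
#' @param model A `maskaudit_model`, or a function `(image) -> numeric`.
#' @param image Image matrix at the model's working size.
#' @param segmap A [make_superpixels()] map (labels `0..M-1`).
#' @param n_evals Budget of model evaluations (>= M + 2).
#' @param class_index Optional class column(s) to keep (default all).
#' @param seed Integer seed.
#' @return An `attribution_result` with `values` (M x C matrix).
#' @export
shapley_occlusion <- function(model, image, segmap, n_evals = 1000L,
                              class_index = NULL, seed = 1L) {
  M <- max(segmap) + 1L
  if (n_evals < M + 2) stopf("`n_evals` must be at least M + 2 = %d", M + 2)
  predict_fn <- as_predictor(model)
  vf <- make_value_fn(predict_fn, image, segmap, M)
  v <- vf$v

  if (2^M <= n_evals) {
    phi <- shapley_exact_marginal(v, M)
    exact <- TRUE
  } else {
    f_full <- v(rep(TRUE, M))
    f_none <- v(rep(FALSE, M))
    C <- length(f_full)
    phi <- matrix(0, M, C)
    n_perm <- 0L
    with_seed(seed, {
      repeat {
        # one antithetic pair costs at most 2 * (M - 1) fresh evaluations
        if (vf$calls$n + 2L * (M - 1L) > n_evals) break
        perm <- sample.int(M)
        for (p in list(perm, rev(perm))) {
          keep <- rep(FALSE, M)
          prev <- f_none
          for (j in p) {
            keep[j] <- TRUE
            cur <- if (all(keep)) f_full else v(keep)
            phi[j, ] <- phi[j, ] + (cur - prev)
            prev <- cur
          }
          n_perm <- n_perm + 1L
        }
      }
    })
    if (n_perm == 0L) stopf("budget too small to process one permutation pair")
    phi <- phi / n_perm
    # exact efficiency: spread the (tiny) residual uniformly
    resid <- (f_full - f_none) - colSums(phi)
    phi <- phi + matrix(resid, M, ncol(phi), byrow = TRUE) / M
    exact <- FALSE
  }
  cn <- if (inherits(model, "maskaudit_model")) model$class_names else paste0("class", seq_len(ncol(phi)))
  res <- attribution_result(phi, cn, vf$calls$n, exact = exact)
  if (!is.null(class_index)) {
    res$values <- res$values[, class_index, drop = FALSE]
    res$class_names <- res$class_names[class_index]
  }
  res
}

# Exact Shapley via the weighted-marginal formula over all 2^M coalitions:
# phi_i = sum_{S not containing i} |S|!(M-|S|-1)!/M! * (v(S+i) - v(S)).
shapley_exact_marginal <- function(v, M) {
  n_sub <- 2^M
  vals <- vector("list", n_sub)
  keeps <- matrix(FALSE, n_sub, M)
  for (s in seq_len(n_sub) - 1L) {
    keep <- as.logical(bitwAnd(s, 2^(seq_len(M) - 1L)) > 0)
    keeps[s + 1L, ] <- keep
    vals[[s + 1L]] <- v(keep)
  }
  C <- length(vals[[1]])
  lw <- lgamma(seq_len(M)) + lgamma(M - seq_len(M) + 1) - lgamma(M + 1)  # |S| = k-1
  phi <- matrix(0, M, C)
  sizes <- rowSums(keeps)
  for (i in seq_len(M)) {
    without <- which(!keeps[, i])
    for (s in without) {
      w <- exp(lw[sizes[s] + 1L])
      s_with <- s + 2^(i - 1L)
      phi[i, ] <- phi[i, ] + w * (vals[[s_with]] - vals[[s]])
    }
  }
  phi
}

#' Exact Shapley values by full coalition enumeration (oracle)
#'
#' Independent oracle for [shapley_occlusion()]: evaluates every coalition,
#' computes Harsanyi dividends with a fast Möbius transform, and distributes
#' each dividend equally among its coalition's members. Refuses M > 15.
#'
#' @inheritParams shapley_occlusion
#' @return An `attribution_result` with exact `values`.
#' @export
exact_shapley <- function(model, image, segmap, class_index = NULL) {
  M <- max(segmap) + 1L
  if (M > 15) stopf("exact enumeration refused for M > 15 segments (budget guard)")
  predict_fn <- as_predictor(model)
  vf <- make_value_fn(predict_fn, image, segmap, M)
  n_sub <- 2^M
  V <- matrix(0, n_sub, 0)
  first <- vf$v(rep(FALSE, M))
  C <- length(first)
  V <- matrix(0, n_sub, C)
  V[1, ] <- first
  for (s in seq_len(n_sub - 1L)) {
    keep <- as.logical(bitwAnd(s, 2^(seq_len(M) - 1L)) > 0)
    V[s + 1L, ] <- vf$v(keep)
  }
  # fast Möbius transform: a(S) = sum_{T subset S} (-1)^{|S|-|T|} v(T)
  A <- V
  for (i in seq_len(M)) {
    bit <- 2^(i - 1L)
    has <- which(bitwAnd(seq_len(n_sub) - 1L, bit) > 0)
    A[has, ] <- A[has, ] - A[has - bit, ]
  }
  sizes <- vapply(seq_len(n_sub) - 1L, function(s) sum(bitwAnd(s, 2^(seq_len(M) - 1L)) > 0), numeric(1))
  phi <- matrix(0, M, C)
  for (i in seq_len(M)) {
    bit <- 2^(i - 1L)
    has <- which(bitwAnd(seq_len(n_sub) - 1L, bit) > 0)
    phi[i, ] <- colSums(A[has, , drop = FALSE] / sizes[has])
  }
  cn <- if (inherits(model, "maskaudit_model")) model$class_names else paste0("class", seq_len(C))
  res <- attribution_result(phi, cn, vf$calls$n, exact = TRUE)
  if (!is.null(class_index)) {
    res$values <- res$values[, class_index, drop = FALSE]
    res$class_names <- res$class_names[class_index]
  }
  res
}

#' Fraction of positive attribution mass inside the ROI
#'
#' A segment counts as "in ROI" when the majority of its pixels lie inside
#' the ROI mask. The share is the positive attribution mass on in-ROI
#' segments divided by the total positive mass. Models leaning on planted
#' shortcuts outside the ROI drive this share below 0.5.
#'
#' @param result An `attribution_result`.
#' @param segmap The superpixel map used to compute it.
#' @param mask Binary ROI mask on the same grid.
#' @param class_index Class column to summarise (default 1).
#' @return Share in \[0, 1\], or `NA` (with a warning) when there is no
#'   positive mass.
#' @export
roi_attribution_share <- function(result, segmap, mask, class_index = 1L) {
  if (!all(dim(segmap) == dim(mask))) stopf("segmap and mask must share a grid")
  vals <- result$values[, class_index]
  M <- length(vals)
  in_roi <- vapply(seq_len(M) - 1L, function(l) {
    px <- segmap == l
    mean(mask[px]) > 0.5
  }, logical(1))
  pos <- pmax(vals, 0)
  total <- sum(pos)
  if (total <= 0) {
    warnf("no positive attribution mass; share undefined")
    return(NA_real_)
  }
  sum(pos[in_roi]) / total
}

#' Export an attribution map as a per-segment table and optional PNG overlay
#'
#' The overlay renders positive values in red and negative values in blue
#' over the grayscale image.
#'
#' @param result An `attribution_result`.
#' @param segmap Superpixel map.
#' @param image Image matrix.
#' @param csv_path,png_path Optional output paths.
#' @param class_index Class column to render.
#' @return Data frame with `segment` and `value`, invisibly.
#' @export
export_attribution <- function(result, segmap, image, csv_path = NULL,
                               png_path = NULL, class_index = 1L) {
  vals <- result$values[, class_index]
  tab <- data.frame(segment = seq_along(vals) - 1L, value = vals)
  if (!is.null(csv_path)) write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    vmap <- matrix(vals[segmap + 1L], nrow(segmap), ncol(segmap))
    amax <- max(abs(vmap), 1e-12)
    pos <- pmax(vmap, 0) / amax; neg <- pmax(-vmap, 0) / amax
    rgb <- array(0, c(nrow(image), ncol(image), 3))
    base <- clip01(image)
    rgb[, , 1] <- clip01(base + 0.7 * pos)
    rgb[, , 2] <- base * (1 - 0.5 * (pos + neg))
    rgb[, , 3] <- clip01(base + 0.7 * neg)
    png::writePNG(rgb, png_path)
  }
  invisible(tab)
}
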