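# Masking strategies, preprocessing, dilation, and record filtering.
#
# The audit trains one model per dataset "variant": the full image, the image
# with the ROI removed (precise mask or its bounding box), or the image with
# everything but the ROI removed. Masked pixels take the value 0, identical to
# the black padding introduced by preprocessing, so removed regions are
# indistinguishable from padding.

#' The five masking strategies
#'
#' Returns the names of the five dataset variants used throughout the audit:
#' `FULL` (identity), `NO_ROI` (zero out the precise ROI mask), `NO_ROI_BB`
#' (zero out the filled bounding box of the mask), `ONLY_ROI` (keep only the
#' precise mask), and `ONLY_ROI_BB` (keep only the filled bounding box).
#'
#' @return Character vector of length five.
#' @export
masking_strategies <- function() {
  c("FULL", "NO_ROI", "NO_ROI_BB", "ONLY_ROI", "ONLY_ROI_BB")
}

check_strategy <- function(strategy) {
  if (!is.character(strategy) || length(strategy) != 1 ||
      !strategy %in% masking_strategies()) {
    stopf("`strategy` must be one of: %s",
          paste(masking_strategies(), collapse = ", "))
  }
  strategy
}

#' Binarize a mask array
#'
#' Masks read from 8-bit files are thresholded at > 127; masks already on
#' \[0, 1\] are thresholded at > 0.5. Exact 0/1 arrays pass through unchanged.
#'
#' @param mask Numeric matrix.
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize_mask <- function(mask) {
  if (!is.matrix(mask)) stopf("`mask` must be a matrix")
  if (is_binary(mask)) {
    storage.mode(mask) <- "integer"
    return(mask)
  }
  thr <- if (max(mask) > 1) 127 else 0.5
  out <- (mask > thr) * 1L
  dim(out) <- dim(mask)
  out
}

#' Preprocess an image (and its mask) to the working resolution
#'
#' Scales intensities to \[0, 1\] (dividing by 255 when the input looks 8-bit),
#' resizes so the longer side equals `size` while preserving the aspect ratio,
#' and centres the result in a `size` x `size` frame with black (0) padding.
#' The mask receives the identical geometric transform with nearest-neighbour
#' interpolation so it stays binary.
#'
#' @param image Numeric matrix (grayscale image).
#' @param mask Optional binary matrix of the same shape.
#' @param size Working side length in pixels (default 128; use 512 to mirror
#'   full-resolution runs).
#' @return If `mask` is `NULL`, the preprocessed image matrix; otherwise a
#'   list with elements `image` and `mask`.
#' @export
preprocess_image <- function(image, mask = NULL, size = 128L) {
  if (!is.matrix(image) || length(image) == 0) stopf("`image` must be a nonempty matrix")
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(image))) stopf("mask shape must equal image shape")
    mask <- binarize_mask(mask)
  }
  if (max(image) > 1) image <- image / 255
  image <- clip01(image)

  h <- nrow(image); w <- ncol(image)
  if (h == size && w == size) {
    out <- image
    out_mask <- mask
  } else {
    s <- size / max(h, w)
    nh <- max(1L, as.integer(round(h * s)))
    nw <- max(1L, as.integer(round(w * s)))
    img_r <- as.matrix(EBImage::resize(image, w = nh, h = nw))
    out <- matrix(0, size, size)
    r0 <- (size - nh) %/% 2L
    c0 <- (size - nw) %/% 2L
    out[r0 + seq_len(nh), c0 + seq_len(nw)] <- img_r
    out_mask <- NULL
    if (!is.null(mask)) {
      msk_r <- as.matrix(EBImage::resize(mask, w = nh, h = nw, filter = "none"))
      out_mask <- matrix(0L, size, size)
      out_mask[r0 + seq_len(nh), c0 + seq_len(nw)] <- binarize_mask(msk_r)
    }
  }
  if (is.null(mask)) out else list(image = out, mask = out_mask)
}

#' Tightest bounding box of a binary mask
#'
#' @param mask Binary matrix with at least one nonzero pixel.
#' @return Object of class `bounding_box`: a list with 0-based inclusive
#'   corners `row_min`, `col_min`, `row_max`, `col_max`.
#' @export
compute_bounding_box <- function(mask) {
  mask <- binarize_mask(mask)
  nz <- which(mask != 0L, arr.ind = TRUE)
  if (nrow(nz) == 0) stopf("degenerate mask: no nonzero pixel, record should be excluded")
  structure(list(
    row_min = min(nz[, 1]) - 1L, col_min = min(nz[, 2]) - 1L,
    row_max = max(nz[, 1]) - 1L, col_max = max(nz[, 2]) - 1L
  ), class = "bounding_box")
}

# Filled bounding-box mask; empty mask yields an empty box mask.
bb_mask <- function(mask) {
  mask <- binarize_mask(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask != 0L)) return(out)
  bb <- compute_bounding_box(mask)
  out[(bb$row_min + 1L):(bb$row_max + 1L), (bb$col_min + 1L):(bb$col_max + 1L)] <- 1L
  out
}

#' Apply a masking strategy to an image
#'
#' `FULL` returns the image unchanged; `ONLY_ROI` zeroes pixels outside the
#' mask; `NO_ROI` zeroes pixels inside it; the `_BB` variants substitute the
#' filled bounding box for the precise mask. Zeroed pixels take the value 0
#' ("black"), the same value as padding, applied on the \[0, 1\] scale before
#' any model-specific standardisation.
#'
#' @param image Preprocessed image matrix.
#' @param mask Binary mask matrix of the same shape.
#' @param strategy One of [masking_strategies()].
#' @return Masked image matrix.
#' @export
apply_strategy <- function(image, mask, strategy) {
  check_strategy(strategy)
  if (strategy == "FULL") return(image)
  if (!all(dim(mask) == dim(image))) stopf("mask shape must equal image shape")
  m <- binarize_mask(mask)
  if (strategy %in% c("NO_ROI_BB", "ONLY_ROI_BB")) m <- bb_mask(m)
  switch(strategy,
    ONLY_ROI    = ,
    ONLY_ROI_BB = image * m,
    NO_ROI      = ,
    NO_ROI_BB   = image * (1L - m)
  )
}

#' Dilate a binary mask by a Euclidean disk
#'
#' Morphological dilation with the structuring element
#' \eqn{\{p : \lVert p \rVert_2 \le \mathrm{factor}\}}; the "dilation factor"
#' is the disk radius in pixels at the working resolution. Implemented via an
#' exact Euclidean distance transform, so the result equals the brute-force
#' definition pixel for pixel.
#'
#' @param mask Binary matrix.
#' @param factor Nonnegative radius in pixels; 0 is the identity.
#' @return Binary matrix, a superset of `mask`.
#' @export
dilate_mask <- function(mask, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || is.na(factor) || factor < 0) {
    stopf("`factor` must be a single nonnegative number")
  }
  mask <- binarize_mask(mask)
  if (factor == 0 || !any(mask == 0L) || !any(mask == 1L)) return(mask)
  d <- as.matrix(EBImage::distmap(1L - mask, metric = "euclidean"))
  out <- (mask == 1L | d <= factor) * 1L
  dim(out) <- dim(mask)
  out
}

#' Filter records on mask availability and mask quality
#'
#' Keeps records that carry a non-degenerate mask and whose `mask_quality`
#' (a stand-in for an automated segmentation-quality score such as Dice RCA)
#' is strictly above the threshold. Removal counts are reported via
#' `message()`.
#'
#' @param records List of image records (see [generate_dataset()]).
#' @param quality_threshold Strict lower bound on `mask_quality` (default 0.7).
#' @return Filtered list of records, with attribute `removed` holding counts.
#' @export
filter_records <- function(records, quality_threshold = 0.7) {
  has_mask <- vapply(records, function(r) !is.null(r$mask) && any(r$mask != 0), logical(1))
  qual <- vapply(records, function(r) {
    q <- r$mask_quality
    if (is.null(q) || is.na(q)) NA_real_ else as.numeric(q)
  }, numeric(1))
  keep <- has_mask & !is.na(qual) & qual > quality_threshold
  removed <- c(no_mask = sum(!has_mask),
               low_quality = sum(has_mask & (is.na(qual) | qual <= quality_threshold)))
  message(sprintf("filter_records: removed %d without usable mask, %d with quality <= %g; kept %d/%d",
                  removed[["no_mask"]], removed[["low_quality"]],
                  quality_threshold, sum(keep), length(records)))
  structure(records[keep], removed = removed)
}

#' Apply the chest X-ray metadata filters to manifest-style tables
#'
#' Reproduces the record-filtering pipeline for a PadChest-dialect metadata
#' table joined to a per-image mask-quality table: drop lateral views
#' (`Projection == "L"`), drop rows whose label field is null/empty, drop rows
#' whose label list contains (as a substring) any of `"suboptimal study"`,
#' `"exclude"` or `"unchanged"`, join to the mask table on `ImageID`, and keep
#' rows whose quality score is strictly above `quality_threshold` (rows with
#' no mask entry are dropped).
#'
#' @param metadata_table Data frame with columns `ImageID`, `Projection`,
#'   `Labels`.
#' @param mask_table Data frame with columns `ImageID` and a quality column
#'   (default name `"Dice RCA (Mean)"`).
#' @param quality_threshold Strict lower bound on the quality score.
#' @param quality_column Name of the quality column in `mask_table`.
#' @return List with `table` (surviving rows), `n_kept`, and `counts`
#'   (rows removed at each stage).
#' @export
padchest_filter <- function(metadata_table, mask_table, quality_threshold = 0.7,
                            quality_column = "Dice RCA (Mean)") {
  for (col in c("ImageID", "Projection", "Labels")) {
    if (!col %in% names(metadata_table)) stopf("metadata_table is missing required column `%s`", col)
  }
  if (!"ImageID" %in% names(mask_table)) stopf("mask_table is missing required column `ImageID`")
  if (!quality_column %in% names(mask_table)) {
    stopf("mask_table is missing required column `%s`", quality_column)
  }
  counts <- c(start = nrow(metadata_table))
  tab <- metadata_table[is.na(metadata_table$Projection) | metadata_table$Projection != "L", , drop = FALSE]
  counts["lateral"] <- counts[["start"]] - nrow(tab)

  lab <- tab$Labels
  null_lab <- is.na(lab) | trimws(as.character(lab)) %in% c("", "[]", "NULL")
  tab <- tab[!null_lab, , drop = FALSE]
  counts["null_label"] <- sum(null_lab)

  excl <- c("suboptimal study", "exclude", "unchanged")
  bad <- Reduce(`|`, lapply(excl, function(p) grepl(p, tab$Labels, fixed = TRUE)))
  tab <- tab[!bad, , drop = FALSE]
  counts["excluded_label"] <- sum(bad)

  merged <- merge(tab, mask_table[, c("ImageID", quality_column)], by = "ImageID")
  counts["no_mask"] <- nrow(tab) - nrow(merged)
  q <- merged[[quality_column]]
  keep <- !is.na(q) & q > quality_threshold
  counts["low_quality"] <- sum(!keep)
  merged <- merged[keep, , drop = FALSE]

  message(sprintf("padchest_filter: %d -> %d rows (lateral %d, null label %d, excluded label %d, no mask %d, low quality %d)",
                  counts[["start"]], nrow(merged), counts[["lateral"]], counts[["null_label"]],
                  counts[["excluded_label"]], counts[["no_mask"]], counts[["low_quality"]]))
  list(table = merged, n_kept = nrow(merged), counts = counts)
}
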