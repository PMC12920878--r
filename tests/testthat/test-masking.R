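# Preprocessing, the five masking strategies, dilation, and record filtering.

random_mask <- function(S, p = 0.2, seed) {
  set.seed(seed)
  matrix(rbinom(S * S, 1, p), S, S)
}

test_that("preprocessing preserves aspect ratio and centres with black padding", {
  # square input at the working size: geometry untouched, intensities scaled
  img8 <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  out <- preprocess_image(img8, size = 64)
  expect_equal(out, img8 / 255)

  # 2:1 input: content fills half the width, centred black columns elsewhere
  wide <- matrix(runif(1024 * 512, min = 0.2, max = 1), 1024, 512)
  out <- preprocess_image(wide, size = 512)
  expect_equal(dim(out), c(512, 512))
  expect_true(all(out[, 1:128] == 0))
  expect_true(all(out[, 385:512] == 0))
  expect_true(all(out[, 129:384] > 0))

  # mask transformed alongside stays binary
  msk <- random_mask(96, seed = 1)
  res <- preprocess_image(matrix(runif(96 * 48), 96, 48),
                          mask = msk[, 1:48], size = 64)
  expect_true(all(res$mask %in% c(0L, 1L)))
  expect_equal(dim(res$mask), c(64, 64))

  expect_error(preprocess_image(matrix(numeric(0), 0, 0)), "nonempty")
})

test_that("bounding boxes are tight and match the exhaustive scan", {
  bb <- compute_bounding_box(matrix(1, 4, 4))
  expect_equal(unlist(bb[c("row_min", "col_min", "row_max", "col_max")]),
               c(row_min = 0, col_min = 0, row_max = 3, col_max = 3))

  m <- matrix(0, 8, 8); m[3, 6] <- 1
  bb <- compute_bounding_box(m)
  expect_equal(c(bb$row_min, bb$col_min, bb$row_max, bb$col_max), c(2, 5, 2, 5))

  for (s in 1:50) {
    m <- random_mask(12, p = 0.08, seed = s)
    if (!any(m == 1)) next
    bb <- compute_bounding_box(m)
    expect_equal(c(bb$row_min, bb$col_min, bb$row_max, bb$col_max),
                 unname(bbox_scan_oracle(m)))
  }

  expect_error(compute_bounding_box(matrix(0, 4, 4)), "degenerate")
})

test_that("masking strategies partition the image and satisfy BB dominance", {
  expect_length(masking_strategies(), 5)
  for (s in 1:20) {
    set.seed(s)
    img <- matrix(runif(32 * 32), 32, 32)
    msk <- random_mask(32, p = 0.3, seed = 100 + s)
    if (!any(msk == 1)) next
    expect_identical(apply_strategy(img, msk, "FULL"), img)
    # partition identity, precise and bounding-box variants
    expect_equal(apply_strategy(img, msk, "ONLY_ROI") +
                 apply_strategy(img, msk, "NO_ROI"), img)
    expect_equal(apply_strategy(img, msk, "ONLY_ROI_BB") +
                 apply_strategy(img, msk, "NO_ROI_BB"), img)
    # BB dominance
    only <- apply_strategy(img, msk, "ONLY_ROI")
    only_bb <- apply_strategy(img, msk, "ONLY_ROI_BB")
    expect_true(all(only_bb[only > 0] > 0))
    no_bb <- apply_strategy(img, msk, "NO_ROI_BB")
    no <- apply_strategy(img, msk, "NO_ROI")
    expect_true(all(no[no_bb > 0] > 0))
    # idempotence (the mask of an already-masked image removes nothing new)
    expect_equal(apply_strategy(only, msk, "ONLY_ROI"), only)
    expect_equal(apply_strategy(no, msk, "NO_ROI"), no)
  }

  img <- matrix(runif(16 * 16), 16, 16)
  expect_true(all(apply_strategy(img, matrix(0, 16, 16), "ONLY_ROI") == 0))
  expect_error(apply_strategy(img, matrix(0, 8, 8), "NO_ROI"), "shape")
  expect_error(apply_strategy(img, matrix(0, 16, 16), "HALF_ROI"), "strategy")
})

test_that("dilation matches the Euclidean-disk definition and is monotone", {
  m <- matrix(0, 21, 21); m[11, 11] <- 1
  for (r in c(0, 3, 5.5)) {
    expect_identical(dilate_mask(m, r), dilate_bruteforce_oracle(m, r))
  }
  expect_identical(dilate_mask(m, 0), binarize_mask(m))
  ones <- matrix(1L, 9, 9)
  expect_identical(dilate_mask(ones, 50), ones)
  expect_error(dilate_mask(m, -1), "nonnegative")

  msk <- random_mask(40, p = 0.05, seed = 2)
  prev <- dilate_mask(msk, 0)
  for (f in c(5, 25, 50)) {
    cur <- dilate_mask(msk, f)
    expect_true(all(cur[prev == 1] == 1))  # superset ordering
    prev <- cur
  }
})

test_that("quality filtering is strict at the threshold", {
  rec <- function(q) list(image = matrix(1, 4, 4), mask = matrix(1L, 4, 4),
                          mask_quality = q)
  records <- list(rec(0.69), rec(0.70), rec(0.71),
                  list(image = matrix(1, 4, 4), mask = NULL, mask_quality = 0.9))
  kept <- quiet(filter_records(records))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$mask_quality, 0.71)
  expect_equal(unname(attr(kept, "removed")), c(1, 2))
})

test_that("chest-metadata filtering applies the projection, label and quality rules", {
  meta <- data.frame(
    ImageID = paste0("im", 1:7),
    Projection = c("L", "PA", "AP", "PA", "PA", "AP", "PA"),
    Labels = c("[pneumonia]", NA, "[pneumonia, unchanged]", "[exclude]",
               "[suboptimal study]", "[effusion]", "[normal]"),
    stringsAsFactors = FALSE)
  masks <- data.frame(ImageID = paste0("im", c(2:6, 7)),
                      check.names = FALSE)
  masks[["Dice RCA (Mean)"]] <- c(0.9, 0.8, 0.8, 0.9, 0.65, 0.75)
  res <- quiet(padchest_filter(meta, masks))
  # im1 lateral, im2 null label, im3 "unchanged", im4 "exclude",
  # im5 "suboptimal study", im6 quality 0.65 -> only im7 survives
  expect_equal(res$n_kept, 1)
  expect_equal(res$table$ImageID, "im7")
  expect_error(quiet(padchest_filter(meta[, -2], masks)), "Projection")
  expect_error(quiet(padchest_filter(meta, masks[, "ImageID", drop = FALSE])),
               "Dice RCA")
})
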