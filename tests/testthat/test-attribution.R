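# Superpixels, the Shapley occlusion estimator, its enumeration oracle, and
# the in-ROI attribution share.

test_that("grid superpixels partition the image", {
  img <- matrix(0, 64, 64)
  one <- make_superpixels(img, 1)
  expect_true(all(one == 0))

  sp <- make_superpixels(img, 16)
  expect_equal(sort(unique(as.vector(sp))), 0:15)
  expect_true(all(table(sp) == 256))  # sixteen 16x16 blocks
  # non-square counts still give a full nonempty partition
  sp5 <- make_superpixels(img, 5)
  expect_equal(sort(unique(as.vector(sp5))), 0:4)
  expect_equal(sum(table(sp5)), 64 * 64)
  expect_error(make_superpixels(img, 0), "n_segments")
  expect_error(make_superpixels(img, 64 * 64 + 1), "n_segments")
})

test_that("single-segment attribution equals the full-vs-occluded difference", {
  img <- matrix(runif(16 * 16, 0.5, 1), 16, 16)
  sp <- make_superpixels(img, 1)
  f <- function(image) mean(image)
  res <- shapley_occlusion(f, img, sp, n_evals = 10, seed = 1)
  expect_equal(res$values[1, 1], f(img) - f(img * 0))
})

test_that("the enumeration oracle satisfies the Shapley axioms exactly", {
  set.seed(4)
  img <- matrix(1, 24, 24)  # uniform content makes equal-weight segments symmetric
  sp <- make_superpixels(img, 6)
  w <- c(2, 2, -1, 0.5, 0, 3)  # segment 5 (0-based 4) is a dummy
  f <- toy_linear_model(sp, w)
  res <- exact_shapley(f, img, sp)
  # efficiency
  expect_equal(sum(res$values), f(img) - f(img * 0), tolerance = 1e-12)
  # dummy
  expect_equal(res$values[5, 1], 0, tolerance = 1e-12)
  # symmetry: segments 1 and 2 have equal weight over identical content
  expect_equal(res$values[1, 1], res$values[2, 1], tolerance = 1e-12)
  # linearity: for an additive game the value is the segment's own term
  means <- vapply(0:5, function(l) mean(img[sp == l]), numeric(1))
  expect_equal(res$values[, 1], w * means, tolerance = 1e-12)
  expect_error(exact_shapley(f, img, make_superpixels(img, 16)), "M > 15")
})

test_that("the sampled estimator matches the oracle and keeps exact efficiency", {
  set.seed(9)
  img <- matrix(runif(24 * 24), 24, 24)
  sp <- make_superpixels(img, 9)
  f <- toy_interaction_model(sp)
  oracle <- exact_shapley(f, img, sp)

  # budget covering full enumeration: agreement to numerical precision
  full <- shapley_occlusion(f, img, sp, n_evals = 2^9 + 2, seed = 1)
  expect_lt(max(abs(full$values - oracle$values)), 1e-6)
  expect_error(shapley_occlusion(f, img, sp, n_evals = 9), "n_evals")

  # Monte-Carlo path (M = 12 exceeds the budget): efficiency exact,
  # estimates near the oracle, deterministic under the seed
  sp12 <- make_superpixels(img, 12)
  f12 <- toy_interaction_model(sp12)
  mc <- shapley_occlusion(f12, img, sp12, n_evals = 1600, seed = 7)
  expect_false(mc$exact)
  o12 <- exact_shapley(f12, img, sp12)
  expect_equal(sum(mc$values), sum(o12$values), tolerance = 1e-10)
  expect_lt(max(abs(mc$values - o12$values)), 0.06 * max(abs(o12$values)))
  mc2 <- shapley_occlusion(f12, img, sp12, n_evals = 1600, seed = 7)
  expect_identical(mc$values, mc2$values)

  # a dummy segment stays exactly zero on the sampling path as well
  fdum <- toy_linear_model(sp12, c(rep(1, 11), 0))
  md <- shapley_occlusion(fdum, img, sp12, n_evals = 500, seed = 3)
  expect_equal(md$values[12, 1], 0, tolerance = 1e-12)
})

test_that("estimator variance shrinks as the evaluation budget grows", {
  set.seed(11)
  img <- matrix(runif(24 * 24), 24, 24)
  sp <- make_superpixels(img, 12)
  f <- toy_interaction_model(sp)
  spread <- vapply(c(200, 800, 3000), function(budget) {
    est <- sapply(1:8, function(s) {
      shapley_occlusion(f, img, sp, n_evals = budget, seed = s)$values[, 1]
    })
    mean(apply(est, 1, var))
  }, numeric(1))
  expect_true(spread[2] < spread[1])
  expect_true(spread[3] < spread[2])
})

test_that("the in-ROI attribution share summarises positive mass by location", {
  mask <- matrix(0L, 32, 32); mask[1:16, ] <- 1L  # top half is ROI
  sp <- make_superpixels(mask, 16)
  vals <- matrix(0, 16, 1)
  in_top <- sapply(0:15, function(l) mean(mask[sp == l]) > 0.5)
  res <- structure(list(values = vals), class = "attribution_result")

  res$values[which(in_top)[1], 1] <- 2
  expect_equal(roi_attribution_share(res, sp, mask), 1)

  res$values[, 1] <- 0
  res$values[which(!in_top)[1], 1] <- 3
  res$values[which(in_top)[1], 1] <- -5  # negative mass is ignored
  expect_equal(roi_attribution_share(res, sp, mask), 0)

  res$values[, 1] <- -1
  expect_warning(sh <- roi_attribution_share(res, sp, mask), "positive")
  expect_true(is.na(sh))
})

test_that("attribution exports a per-segment table and an overlay image", {
  img <- matrix(runif(32 * 32), 32, 32)
  sp <- make_superpixels(img, 4)
  res <- shapley_occlusion(function(im) mean(im), img, sp, n_evals = 20, seed = 1)
  csv <- tempfile(fileext = ".csv"); png_f <- tempfile(fileext = ".png")
  tab <- export_attribution(res, sp, img, csv_path = csv, png_path = png_f)
  expect_equal(nrow(tab), 4)
  expect_true(file.exists(csv) && file.exists(png_f))
  expect_equal(dim(png::readPNG(png_f)), c(32, 32, 3))
})
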