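# Rank AUC, DeLong test, fold rule, cross-masking matrix, dilation sweeps.

test_that("rank AUC equals the pairwise oracle exactly, ties included", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  for (s in 1:30) {
    set.seed(s)
    n <- sample(20:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_identical(auc(scores, labels), auc_pairwise_oracle(scores, labels))
  }
  # complement property for tie-free scores
  set.seed(1)
  sc <- runif(100); lb <- rbinom(100, 1, 0.5)
  expect_equal(auc(sc, lb) + auc(-sc, lb), 1)
  expect_error(auc(runif(5), rep(1, 5)), "both classes")
})

test_that("DeLong handles identical, symmetric and degenerate comparisons", {
  set.seed(2)
  lb <- rbinom(150, 1, 0.4)
  a <- runif(150); b <- runif(150)
  expect_equal(delong_test(a, a, lb)$p, 1)
  r_ab <- delong_test(a, b, lb)
  r_ba <- delong_test(b, a, lb)
  expect_equal(r_ab$z, -r_ba$z)
  expect_equal(r_ab$p, r_ba$p)
  expect_error(delong_test(a, b[-1], lb), "length")
  # zero variance of the difference with unequal AUCs
  lb2 <- rep(c(0, 1), 5)
  expect_warning(res <- delong_test(lb2, 1 - lb2, lb2), "zero variance")
  expect_equal(res$p, 0)
})

test_that("DeLong separates well-separated AUCs and agrees with a paired bootstrap", {
  n <- 200
  n_sig <- 0
  for (rep in 1:100) {
    set.seed(rep)
    lb <- rep(c(1, 0), each = n / 2)
    a <- ifelse(lb == 1, rnorm(n, 1.81), rnorm(n))   # binormal AUC ~0.9
    b <- ifelse(lb == 1, rnorm(n, 0.36), rnorm(n))   # binormal AUC ~0.6
    p <- delong_test(a, b, lb)$p
    if (p < 0.001) n_sig <- n_sig + 1
    if (rep <= 10) {
      pb <- paired_bootstrap_auc_test(a, b, lb, B = 200, seed = rep)
      expect_lt(pb, 0.01)  # independent test reaches the same conclusion
    }
  }
  expect_gte(n_sig, 95)
})

test_that("DeLong single-AUC variance matches the exponential closed form", {
  # for exponential scores the Hanley-McNeil variance is exact:
  # Q1 = A/(2-A), Q2 = 2A^2/(1+A)
  n1 <- 100; n0 <- 100
  A <- 2 / 3  # Exp(mean 2) positives vs Exp(mean 1) negatives
  Q1 <- A / (2 - A); Q2 <- 2 * A^2 / (1 + A)
  v_true <- (A * (1 - A) + (n1 - 1) * (Q1 - A^2) + (n0 - 1) * (Q2 - A^2)) / (n1 * n0)
  set.seed(8)
  est <- replicate(400, {
    sc <- c(rexp(n1, 1 / 2), rexp(n0, 1))
    auc_variance(sc, rep(c(1, 0), c(n1, n0)))
  })
  expect_lt(abs(mean(est) - v_true) / v_true, 0.1)
})

test_that("the fold rule counts strictly sub-alpha folds", {
  expect_true(aggregate_significance(c(0.01, 0.02, 0.04, 0.9, 0.9)))
  expect_false(aggregate_significance(c(0.04, 0.04, 0.9, 0.9, 0.9)))
  expect_false(aggregate_significance(rep(0.05, 5)))  # strict inequality
  expect_true(aggregate_significance(c(0.04, 0.04, 0.049, 0.9, 0.9)))
  expect_error(aggregate_significance(numeric(0)), "nonempty")
})

test_that("permutation p-values detect signal and stay null-calibrated", {
  set.seed(5)
  lb <- rbinom(200, 1, 0.4)
  strong <- lb + rnorm(200, sd = 0.3)
  expect_lt(permutation_auc_pvalue(strong, lb, n_perm = 199, seed = 1)$p, 0.01)
  expect_gt(permutation_auc_pvalue(rnorm(200), lb, n_perm = 199, seed = 1)$p, 0.05)
})

test_that("the cross-masking matrix is complete and FULL dominates its row", {
  m <- cross_masking_evaluation(fx_matrix_models(), fx_lungs()$records)
  expect_s3_class(m, "auc_matrix")
  expect_equal(nrow(m), 25)
  expect_true(all(!is.na(m$mean_auc)))
  expect_true(all(m$mean_auc >= 0 & m$mean_auc <= 1))
  # masking only removes information on shortcut-free data
  full_row <- m[m$train_strategy == "FULL", ]
  diag_cell <- full_row$mean_auc[full_row$eval_strategy == "FULL"]
  expect_true(all(diag_cell >= full_row$mean_auc - 0.05))
  expect_error(cross_masking_evaluation(fx_matrix_models()["FULL"],
                                        fx_lungs()$records),
               "no trained models")
})

test_that("dilation sweeps anchor at the base evaluation and wash out to chance", {
  models <- fx_matrix_models()[["NO_ROI"]]
  recs <- fx_lungs()$records[1:60]
  sw <- dilation_sweep(models, recs, base = "NO_ROI", factors = c(0, 4),
                       subset = "all")
  expect_s3_class(sw, "dilation_curve")

  # factor 0 equals the plain cross-evaluation of the same records
  imgs <- lapply(recs, function(r) apply_strategy(r$image, r$mask, "NO_ROI"))
  a0 <- mean(vapply(models, function(mo) {
    auc(predict_proba(mo, imgs)[, 1], vapply(recs, function(r) r$labels[[1]], numeric(1)))
  }, numeric(1)))
  expect_equal(sw$mean_auc[1], a0)

  # dilating every mask past the image diagonal blacks out everything
  sw2 <- dilation_sweep(models, recs, base = "NO_ROI", factors = c(0, 100),
                        subset = "all")
  expect_equal(sw2$mean_auc[2], 0.5)

  expect_error(dilation_sweep(models, recs, factors = c(5, 5)), "increasing")
  one_class <- recs[vapply(recs, function(r) r$labels[[1]] == 1, logical(1))]
  expect_error(dilation_sweep(models, one_class, base = "NO_ROI",
                              factors = 0, subset = "negatives_only"),
               "empty")
})
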