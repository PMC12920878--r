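# Folds, the frozen trunk, head training with early stopping, prediction,
# embeddings, and the tabular baseline.

test_that("fold assignment is stratified, balanced and deterministic", {
  y <- rep(c(1, 0), c(300, 700))
  f <- make_folds(y, k = 5, seed = 3)
  expect_equal(as.integer(table(f)), rep(200L, 5))
  expect_equal(as.integer(table(f[y == 1])), rep(60L, 5))
  expect_identical(f, make_folds(y, k = 5, seed = 3))
  expect_false(identical(f, make_folds(y, k = 5, seed = 4)))
  expect_warning(make_folds(c(1, rep(0, 20)), k = 5, seed = 1), "fewer than")
  expect_error(make_folds(y, k = 1), "k")
})

test_that("trunk embeddings are deterministic with the documented dimension", {
  img <- matrix(runif(64 * 64), 64, 64)
  v1 <- featurize_image(img); v2 <- featurize_image(img)
  expect_identical(v1, v2)
  expect_length(v1, maskaudit:::embedding_dim_for(4L))
})

test_that("training learns a clear in-ROI signal and stops early on flat loss", {
  model <- fx_full_model()
  fs <- fx_lungs_features("FULL")
  va <- which(fs$folds == 0)
  a <- auc(predict_from_embedding(model, fs$X[va, , drop = FALSE])[, 1],
           fs$y[va, 1])
  expect_gt(a, 0.8)
  # early-stopping bookkeeping: the chosen epoch is within delta of optimal
  cfg <- fx_tconfig()
  expect_lte(model$val_history[model$best_epoch],
             min(model$val_history) + cfg$early_stop_delta)

  # constant images carry no improvable signal: training ends well short of
  # the epoch cap
  recs <- lapply(1:40, function(i) {
    list(image = matrix(0, 64, 64), mask = matrix(1L, 64, 64),
         labels = c(disease = i %% 2), fold = i %% 5)
  })
  m0 <- train_image_classifier(recs, "FULL", 0, training_config(seed = 1, n_augment = 0))
  expect_lt(length(m0$val_history), training_config()$max_epochs)

  bad <- lapply(recs, function(r) { r$labels <- c(disease = 1); r })
  expect_error(train_image_classifier(bad, "FULL", 0, training_config(seed = 1)),
               "single class")
})

test_that("training is reproducible for identical records, config and seed", {
  fs <- fx_lungs_features("FULL")
  m2 <- train_image_classifier(fx_lungs()$records, "FULL", 0, fx_tconfig(),
                               features = fs)
  expect_identical(fx_full_model()$head, m2$head)
})

test_that("prediction is deterministic, bounded, and reproduced by the stored head", {
  model <- fx_full_model()
  recs <- fx_lungs()$records[1:8]
  imgs <- lapply(recs, `[[`, "image")
  P <- predict_proba(model, imgs)
  expect_equal(dim(P), c(8L, 1L))
  expect_true(all(P >= 0 & P <= 1 & is.finite(P)))
  # duplicated image rows give identical outputs
  P2 <- predict_proba(model, c(imgs[1], imgs[1]))
  expect_identical(P2[1, ], P2[2, ])

  E <- extract_embeddings(model, imgs)
  expect_equal(dim(E), c(8L, model$embedding_dim))
  expect_identical(extract_embeddings(model, c(imgs[2], imgs[2]))[1, ],
                   extract_embeddings(model, c(imgs[2], imgs[2]))[2, ])
  expect_equal(predict_from_embedding(model, E), P)

  expect_error(predict_proba(model, matrix(0, 32, 32)), "size")
})

test_that("an ONLY_ROI model is invariant to pixels outside the ROI", {
  fs <- fx_lungs_features("ONLY_ROI")
  model <- train_image_classifier(fx_lungs()$records, "ONLY_ROI", 1,
                                  fx_tconfig(), features = fs)
  r <- fx_lungs()$records[[2]]
  scrambled <- r$image
  scrambled[r$mask == 0] <- runif(sum(r$mask == 0))
  p1 <- predict_proba(model, apply_strategy(r$image, r$mask, "ONLY_ROI"))
  p2 <- predict_proba(model, apply_strategy(scrambled, r$mask, "ONLY_ROI"))
  expect_identical(p1, p2)
})

test_that("model checkpoints round-trip through the JSON sidecar", {
  model <- fx_full_model()
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  imgs <- lapply(fx_lungs()$records[1:4], `[[`, "image")
  expect_equal(predict_proba(back, imgs), predict_proba(model, imgs),
               tolerance = 1e-12)
})

test_that("the tabular baseline is calibrated and drops incomplete rows", {
  y <- rep(c(1, 0), c(700, 1300))
  folds <- make_folds(y, k = 5, seed = 11)

  # label-independent metadata: chance-level CV AUC
  md0 <- generate_metadata(y, 0.5, seed = 21)
  fit0 <- train_tabular_baseline(md0, y, folds)
  expect_gt(fit0$mean_auc[[1]], 0.45)
  expect_lt(fit0$mean_auc[[1]], 0.55)

  # a perfectly predictive feature separates every fold
  md1 <- md0
  md1$birth_year <- ifelse(y == 1, 1990, 1950)
  fit1 <- train_tabular_baseline(md1, y, folds)
  expect_gt(fit1$mean_auc[[1]], 0.99)

  # rows with a missing feature are excluded before fitting
  md2 <- md0
  md2$sex[1:50] <- NA
  fit2 <- train_tabular_baseline(md2, y, folds)
  expect_equal(fit2$n_used, length(y) - 50)

  md3 <- md0
  md3$sex <- NA
  expect_error(train_tabular_baseline(md3, y, folds), "dropped")
})
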