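# Shared fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# Small chest-like dataset (two-lung ROI, clear disease signal).
fx_lungs <- function() fixture("lungs", {
  generate_dataset(synthetic_config(n_images = 140, image_size = 64, seed = 301))
})

# Small fundus-like dataset (disc ROI: ROI area much smaller than the image).
fx_disc <- function() fixture("disc", {
  generate_dataset(synthetic_config(n_images = 140, image_size = 64,
                                    roi_shape = "disc", seed = 302))
})

fx_tconfig <- function() training_config(seed = 1)

# Per-strategy feature sets for the lungs fixture.
fx_lungs_features <- function(strategy) fixture(paste0("lf_", strategy), {
  featurize_records(fx_lungs()$records, strategy, fx_tconfig(), augment = TRUE)
})

# One FULL-trained fold-0 model on the lungs fixture.
fx_full_model <- function() fixture("full_model", {
  train_image_classifier(fx_lungs()$records, "FULL", 0, fx_tconfig(),
                         features = fx_lungs_features("FULL"))
})

# Two fold models per strategy on the lungs fixture (for the cross matrix).
fx_matrix_models <- function() fixture("matrix_models", {
  out <- list()
  for (st in masking_strategies()) {
    fs <- fx_lungs_features(st)
    out[[st]] <- lapply(0:1, function(f) {
      train_image_classifier(fx_lungs()$records, st, f, fx_tconfig(), features = fs)
    })
  }
  out
})

# One FULL-trained fold-0 model on the disc fixture.
fx_disc_full_model <- function() fixture("disc_full_model", {
  fs <- featurize_records(fx_disc()$records, "FULL", fx_tconfig(), augment = TRUE)
  train_image_classifier(fx_disc()$records, "FULL", 0, fx_tconfig(), features = fs)
})

quiet <- function(expr) suppressMessages(expr)
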