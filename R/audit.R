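# End-to-end audit orchestration: generate (or load) -> filter -> mask ->
# train (K folds x strategies) -> cross-masking matrix -> significance ->
# verdict, with optional dilation sweeps, embedding similarity, and Shapley
# attribution, consolidated into one report.

#' Audit run configuration
#'
#' @param dataset A [synthetic_config()] describing the training data, or a
#'   directory path written by [write_dataset()].
#' @param test_dataset Optional test-set source (same types); by default a
#'   fresh synthetic test set is generated from `dataset` with
#'   `test_fraction` of its size and a child seed.
#' @param strategies Masking strategies to train (default all five).
#' @param training A [training_config()].
#' @param quality_threshold Strict mask-quality threshold (default 0.7).
#' @param alpha,min_folds Fold-rule parameters (default 0.05 and 3).
#' @param n_perm Label permutations for the above-chance null (default 200).
#' @param dilation_factors Radii for sweeps (`NULL` disables sweeps).
#' @param sweep_base,sweep_subset Sweep protocol: base strategy and which
#'   records' masks are dilated.
#' @param sweep_on `"FULL"` to sweep the FULL-trained models (inference-time
#'   masking of the test set), or `"base"` to sweep the models trained on
#'   `sweep_base`.
#' @param do_embeddings Compute the similarity table and 2-D projection.
#' @param attribution_n_evals Shapley budget per image (0 disables
#'   attribution).
#' @param attribution_n_images Positives to attribute.
#' @param n_segments Superpixels per image.
#' @param test_fraction Test-set size relative to the training set.
#' @param seed Master seed; all child streams derive from it.
#' @param out_dir Optional output directory for the report bundle.
#' @return Object of class `audit_config`.
#' @export
audit_config <- function(dataset = synthetic_config(),
                         test_dataset = NULL,
                         strategies = masking_strategies(),
                         training = training_config(),
                         quality_threshold = 0.7,
                         alpha = 0.05, min_folds = 3L, n_perm = 200L,
                         dilation_factors = NULL,
                         sweep_base = "ONLY_ROI",
                         sweep_subset = "positives_only",
                         sweep_on = c("FULL", "base"),
                         do_embeddings = FALSE,
                         attribution_n_evals = 0L,
                         attribution_n_images = 10L,
                         n_segments = 16L,
                         test_fraction = 0.5,
                         seed = 1L,
                         out_dir = NULL) {
  sweep_on <- match.arg(sweep_on)
  for (s in strategies) check_strategy(s)
  structure(list(dataset = dataset, test_dataset = test_dataset,
                 strategies = strategies, training = training,
                 quality_threshold = quality_threshold,
                 alpha = alpha, min_folds = as.integer(min_folds),
                 n_perm = as.integer(n_perm),
                 dilation_factors = dilation_factors,
                 sweep_base = sweep_base, sweep_subset = sweep_subset,
                 sweep_on = sweep_on,
                 do_embeddings = do_embeddings,
                 attribution_n_evals = as.integer(attribution_n_evals),
                 attribution_n_images = as.integer(attribution_n_images),
                 n_segments = as.integer(n_segments),
                 test_fraction = test_fraction,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "audit_config")
}

resolve_dataset <- function(src, what) {
  if (inherits(src, "shortcut_dataset")) return(src)
  if (inherits(src, "synthetic_config")) return(generate_dataset(src))
  if (is.character(src) && length(src) == 1) return(read_dataset(src))
  stopf("stage %s: dataset source must be a synthetic_config, shortcut_dataset, or directory path", what)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("audit stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full shortcut-learning audit
#'
#' Executes generate -> filter -> mask -> train (K folds x strategies) ->
#' cross-masking matrix -> significance -> (optional) dilation sweeps,
#' embedding similarity, Shapley attribution, and issues a shortcut-risk
#' verdict: risk is flagged when any `NO_ROI` / `NO_ROI_BB` diagonal cell of
#' the matrix is significantly above a label-permuted null in at least
#' `min_folds` folds. When `out_dir` is set, the report is written as JSON
#' plus CSV tables.
#'
#' @param config An [audit_config()].
#' @return Object of class `audit_report`.
#' @export
run_audit <- function(config) {
  stopifnot(inherits(config, "audit_config"))
  seed <- config$seed
  train_ds <- stage("generate", {
    src <- config$dataset
    if (inherits(src, "synthetic_config")) src$seed <- child_seed(seed, 1L, 20L)
    resolve_dataset(src, "generate")
  })
  test_ds <- stage("generate_test", {
    src <- config$test_dataset
    if (is.null(src)) {
      src <- train_ds$config
      if (is.null(src)) stopf("a loaded dataset needs an explicit `test_dataset`")
      src$n_images <- max(50L, as.integer(round(src$n_images * config$test_fraction)))
      src$seed <- child_seed(seed, 2L, 20L)
    } else if (inherits(src, "synthetic_config")) {
      src$seed <- child_seed(seed, 2L, 20L)
    }
    resolve_dataset(src, "generate_test")
  })

  counts <- list(generated = length(train_ds$records))
  records <- stage("filter", filter_records(train_ds$records, config$quality_threshold))
  test_records <- stage("filter", filter_records(test_ds$records, config$quality_threshold))
  counts$after_quality_filter <- length(records)
  counts$test_after_quality_filter <- length(test_records)

  folds <- sort(unique(vapply(records, `[[`, numeric(1), "fold")))
  tcfg <- config$training
  tcfg$seed <- child_seed(seed, 3L, 30L)

  models <- list()
  for (st in config$strategies) {
    fs <- stage("mask", featurize_records(records, st, tcfg, augment = TRUE))
    models[[st]] <- lapply(folds, function(f) {
      stage("train", train_image_classifier(records, st, f, tcfg, features = fs))
    })
  }

  matrix_res <- stage("evaluate",
    cross_masking_evaluation(models, test_records, config$strategies))

  # shortcut-risk verdict on the NO_ROI / NO_ROI_BB diagonal cells
  y_test <- labels_matrix(test_records)
  classes <- colnames(y_test)
  verdict_cells <- list()
  risky <- character(0)
  for (st in intersect(c("NO_ROI", "NO_ROI_BB"), config$strategies)) {
    imgs <- lapply(test_records, function(r) apply_strategy(r$image, r$mask, st))
    E <- extract_embeddings(models[[st]][[1]], imgs)
    for (cl in classes) {
      ps <- vapply(seq_along(models[[st]]), function(fi) {
        P <- predict_from_embedding(models[[st]][[fi]], E)
        permutation_auc_pvalue(P[, cl], y_test[, cl], n_perm = config$n_perm,
                               seed = child_seed(seed, fi, 40L))$p
      }, numeric(1))
      flag <- aggregate_significance(ps, config$alpha, config$min_folds)
      cell <- auc_cell(matrix_res, st, st, cl)
      verdict_cells[[paste(st, cl, sep = ":")]] <-
        list(strategy = st, class = cl, mean_auc = cell$mean_auc,
             p_values = ps, significant = flag)
      if (flag) risky <- c(risky, sprintf("(%s, %s) class %s, mean AUC %.3f",
                                          st, st, cl, cell$mean_auc))
    }
  }
  verdict <- if (length(risky)) {
    sprintf("shortcut risk detected: %s", paste(risky, collapse = "; "))
  } else "no shortcut risk detected"

  sweeps <- NULL
  if (!is.null(config$dilation_factors)) {
    sweeps <- stage("sweep", {
      swept <- if (config$sweep_on == "FULL") "FULL" else config$sweep_base
      if (!swept %in% names(models)) stopf("no trained models for sweep strategy %s", swept)
      dilation_sweep(models[[swept]], test_records, base = config$sweep_base,
                     factors = config$dilation_factors, subset = config$sweep_subset)
    })
  }

  embeddings_res <- NULL
  if (config$do_embeddings && "FULL" %in% names(models)) {
    embeddings_res <- stage("embed", {
      st_tab <- similarity_table(models[["FULL"]][[1]], test_records,
                                 setdiff(config$strategies, "FULL"))
      list(similarity = st_tab, note = SIMILARITY_CAVEAT)
    })
  }

  attribution_res <- NULL
  if (config$attribution_n_evals > 0 && "FULL" %in% names(models)) {
    attribution_res <- stage("attribute", {
      pos <- which(y_test[, 1] == 1)[seq_len(min(config$attribution_n_images,
                                                 sum(y_test[, 1] == 1)))]
      model <- models[["FULL"]][[1]]
      shares <- vapply(pos, function(i) {
        r <- test_records[[i]]
        segmap <- make_superpixels(r$image, config$n_segments)
        res <- shapley_occlusion(model, r$image, segmap,
                                 n_evals = config$attribution_n_evals,
                                 seed = child_seed(seed, i, 50L))
        suppressWarnings(roi_attribution_share(res, segmap, r$mask))
      }, numeric(1))
      list(records = pos, roi_share = shares,
           mean_roi_share = mean(shares, na.rm = TRUE))
    })
  }

  # tabular baseline on the training records' metadata
  baseline <- stage("baseline", {
    md <- do.call(rbind, lapply(records, function(r) as.data.frame(r$metadata)))
    train_tabular_baseline(md, labels_matrix(records),
                           vapply(records, `[[`, numeric(1), "fold"))
  })

  cfg_id <- unclass(config)
  cfg_id$out_dir <- NULL  # output location does not change run identity
  report <- structure(list(
    config = config, config_hash = config_hash(cfg_id),
    counts = counts, auc_matrix = matrix_res,
    verdict = verdict, verdict_cells = verdict_cells,
    sweeps = sweeps, embeddings = embeddings_res,
    attribution = attribution_res,
    baseline_auc = baseline$mean_auc,
    note = SIMILARITY_CAVEAT
  ), class = "audit_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.audit_report <- function(x, ...) {
  cat("== shortcut-learning audit ==\n")
  cat(sprintf("records: %d generated, %d after quality filter\n",
              x$counts$generated, x$counts$after_quality_filter))
  cat("verdict:", x$verdict, "\n")
  diag_rows <- x$auc_matrix[x$auc_matrix$train_strategy == x$auc_matrix$eval_strategy, ]
  cat("diagonal mean AUC by strategy:\n")
  for (i in seq_len(nrow(diag_rows))) {
    cat(sprintf("  %-12s %s: %.3f +/- %.3f\n", diag_rows$train_strategy[i],
                diag_rows$class[i], diag_rows$mean_auc[i], diag_rows$sd_auc[i]))
  }
  if (!is.null(x$baseline_auc)) {
    cat(sprintf("tabular baseline mean CV AUC: %s\n",
                paste(sprintf("%s %.3f", names(x$baseline_auc), x$baseline_auc),
                      collapse = ", ")))
  }
  cat(x$note, "\n")
  invisible(x)
}

#' Write an audit report bundle (JSON summary + CSV tables)
#'
#' @param report An `audit_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(report$auc_matrix),
            file.path(dir, "auc_matrix.csv"), row.names = FALSE)
  if (!is.null(report$sweeps)) {
    write.csv(as.data.frame(report$sweeps),
              file.path(dir, "dilation_sweep.csv"), row.names = FALSE)
  }
  if (!is.null(report$embeddings)) {
    write.csv(as.data.frame(report$embeddings$similarity),
              file.path(dir, "similarity_table.csv"), row.names = FALSE)
  }
  summary <- list(
    config_hash = report$config_hash,
    seed = report$config$seed,
    counts = report$counts,
    verdict = report$verdict,
    verdict_cells = lapply(report$verdict_cells, function(v) {
      v[c("strategy", "class", "mean_auc", "p_values", "significant")]
    }),
    baseline_auc = as.list(report$baseline_auc),
    attribution_mean_roi_share =
      if (is.null(report$attribution)) NULL else report$attribution$mean_roi_share,
    note = report$note
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
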