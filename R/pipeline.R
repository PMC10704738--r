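#' Full-pipeline configuration
#'
#' Bundles every stage's configuration with a master seed. Defaults are
#' the screening system's published operating point: modulator
#' threshold 4.67 (log10 units), 47 selected descriptors, SMOTE with
#' k=5 / seed 42, 100-tree random forest with seed 0, a 128/64/32 ReLU
#' network trained 100 epochs, a 15x15 GTM with 5x5 RBFs and
#' lambda 0.01 for 100 iterations, 5000-row screening chunks and an
#' 8x8 (64-compartment) secondary-selection grid.
#'
#' @param threshold modulator threshold, log10 units.
#' @param n_features_selected descriptor subset size (capped at F).
#' @param test_fraction test share of the 90/10 split.
#' @param smote,rf,dnn,gtm stage configs.
#' @param grid a [compartment_grid()].
#' @param quota per-compartment secondary-selection quota.
#' @param chunk_size screening chunk size.
#' @param backend `"dnn"` or `"rf"` screening model.
#' @param split_first if `TRUE`, run the pre-augmentation holdout
#'   protocol instead of the default augment-then-split order.
#' @param run_gtm if `FALSE`, stop after the first screening pass.
#' @param exclude deleterious compound ids, never selected.
#' @param seed master seed; stage seeds that are not fixed by their own
#'   configs are derived from it by fixed offsets.
#' @export
pipeline_config <- function(threshold = 4.67,
                            n_features_selected = 47L,
                            test_fraction = 0.10,
                            smote = smote_config(),
                            rf = rf_config(),
                            dnn = dnn_config(),
                            gtm = gtm_config(),
                            grid = compartment_grid(),
                            quota = 10L,
                            chunk_size = 5000L,
                            backend = c("dnn", "rf"),
                            split_first = FALSE,
                            run_gtm = TRUE,
                            exclude = character(0),
                            seed = 0L) {
  backend <- match.arg(backend)
  structure(list(threshold = threshold,
                 n_features_selected = as.integer(n_features_selected),
                 test_fraction = test_fraction,
                 smote = smote, rf = rf, dnn = dnn, gtm = gtm,
                 grid = grid, quota = as.integer(quota),
                 chunk_size = as.integer(chunk_size),
                 backend = backend, split_first = split_first,
                 run_gtm = run_gtm, exclude = exclude,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Executes the three-phase system end to end: (1) label modulators,
#' rank descriptors by random-forest importance and select the top
#' subset, SMOTE-balance the classes, train the ROS regressor (DNN,
#' with an RF baseline trained on the identical split) and evaluate
#' both on the held-out test fraction; (2) chunked first-pass screen of
#' the screening table against the modulator threshold; (3) GTM fit on
#' the candidates plus the known modulators, projection to the 2-D
#' map, and compartment-based secondary selection near the modulators.
#'
#' @param library a labelled training `compound_library`.
#' @param screen_table screening descriptors: a `compound_library`, a
#'   numeric matrix with ids as rownames, or a delimited-file path.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for artifacts (model bundle,
#'   metrics, funnel report, stage-2 CSV, run manifest).
#' @return list: `funnel`, `metrics` (per backend, train and test),
#'   `ranking`, `selected_features`, `model`, `rf_model`, `gtm_model`,
#'   `holdout` (when `split_first`), `manifest`.
#' @export
run_pipeline <- function(library, screen_table, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(library, "compound_library"))
  stage <- "labeling"
  res <- tryCatch({
    measured <- which(!is.na(library$log_ros))
    X_all <- library$descriptors[measured, , drop = FALSE]
    y_all <- library$log_ros[measured]
    labels <- library$labels[measured]
    if (sum(labels) == 0) stop("no modulators at the configured threshold")

    stage <- "feature ranking"
    ranking <- rank_features(X_all, y_all, n_trees = config$rf$n_trees,
                             seed = config$rf$seed)
    k <- min(config$n_features_selected, ncol(X_all))
    selected <- select_top_k(ranking, k)
    X <- X_all[, selected, drop = FALSE]

    stage <- "augmentation / training"
    holdout <- NULL
    if (config$split_first) {
      holdout <- holdout_generalization(
        library, selected,
        model_config = if (config$backend == "dnn") config$dnn else config$rf,
        smote_cfg = config$smote,
        holdout_fraction = config$test_fraction,
        seed = config$seed + 1L)
      model <- holdout$model
      rf_model <- NULL
      metrics <- list(holdout = holdout$metrics)
    } else {
      scaler <- fit_scaler(X)
      Xs <- apply_scaler(scaler, X)
      aug <- smote_resample(Xs, labels, config$smote, y = y_all)
      sp <- split_train_test(aug$X_aug, aug$y_aug,
                             test_fraction = config$test_fraction,
                             seed = config$seed + 1L)
      model <- train_ros_model(sp$train$X, sp$train$y, config$dnn,
                               scaler = scaler, threshold = config$threshold)
      rf_model <- train_ros_model(sp$train$X, sp$train$y, config$rf,
                                  scaler = scaler, threshold = config$threshold)
      eval_on <- function(m, part) {
        # split rows are already scaled; bypass the model's scaler
        pred <- if (m$kind == "dnn") {
          as.vector(mlp_predict_cpp(part$X, m$fit$weights, m$fit$biases))
        } else {
          predict(m$fit, data = part$X, num.threads = 1)$predictions
        }
        evaluate_predictions(part$y, pred, config$threshold)
      }
      metrics <- list(
        dnn_train = eval_on(model, sp$train),
        dnn_test = eval_on(model, sp$test),
        rf_train = eval_on(rf_model, sp$train),
        rf_test = eval_on(rf_model, sp$test))
      if (config$backend == "rf") model <- rf_model
    }

    stage <- "first-pass screening"
    screen_desc <- if (inherits(screen_table, "compound_library")) {
      screen_table$descriptors
    } else if (is.character(screen_table)) {
      read_library(screen_table)$descriptors
    } else {
      as.matrix(screen_table)
    }
    funnel <- screen_first_pass(screen_desc[, selected, drop = FALSE], model,
                                threshold = config$threshold,
                                chunk_size = config$chunk_size)

    gtm_model <- NULL
    if (config$run_gtm && funnel$n_first_pass > 0) {
      stage <- "GTM / secondary selection"
      ref_ids <- library$compound_ids[measured][labels]
      ref_X <- apply_scaler(model$scaler,
                            library$descriptors[ref_ids, selected,
                                                drop = FALSE])
      cand_X <- apply_scaler(model$scaler,
                             screen_desc[funnel$stage1$compound_id, selected,
                                         drop = FALSE])
      gtm_model <- gtm_fit(rbind(cand_X, ref_X), config$gtm)
      cand_coords <- gtm_project(gtm_model, cand_X)
      ref_coords <- gtm_project(gtm_model, ref_X)
      funnel <- secondary_select(funnel, cand_coords, ref_coords,
                                 grid = config$grid, quota = config$quota,
                                 exclude = config$exclude)
    }

    manifest <- list(
      seed = config$seed,
      backend = config$backend,
      threshold = config$threshold,
      n_training_compounds = length(measured),
      n_modulators = sum(labels),
      n_features_selected = k,
      split_first = config$split_first,
      funnel = list(n_input = funnel$n_input,
                    n_first_pass = funnel$n_first_pass,
                    n_second_pass = funnel$n_second_pass))

    out <- list(funnel = funnel, metrics = metrics, ranking = ranking,
                selected_features = selected, model = model,
                rf_model = rf_model, gtm_model = gtm_model,
                holdout = holdout, manifest = manifest)
    if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
    out
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  metr <- lapply(result$metrics, function(m)
    m[c("rmse", "precision", "recall", "f_measure", "n")])
  jsonlite::write_json(metr, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  funnel_report(result$funnel, file.path(out_dir, "funnel.json"))
  if (!is.null(result$funnel$stage2))
    write.table(result$funnel$stage2, file.path(out_dir, "stage2.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
  write_ranking(result$ranking, file.path(out_dir, "feature_ranking.csv"))
  write_selection(result$selected_features,
                  file.path(out_dir, "selected_features.txt"))
  save_ros_model(result$model, file.path(out_dir, "model"))
  invisible(out_dir)
}

#' Save / load a trained ROS model
#'
#' The bundle is a directory holding a JSON manifest (kind, config,
#' feature subset, scaler, threshold) sufficient to validate a
#' screening table's compatibility, plus the fitted parameters.
#'
#' @param model a `ros_model`.
#' @param path bundle directory.
#' @export
save_ros_model <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(kind = model$kind,
                   config = unclass(model$config),
                   selected_features = model$selected_features,
                   scaler = list(means = unname(model$scaler$means),
                                 stddevs = unname(model$scaler$stddevs)),
                   threshold = model$threshold)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  saveRDS(model$fit, file.path(path, "weights.rds"))
  invisible(path)
}

#' @rdname save_ros_model
#' @export
load_ros_model <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  fit <- readRDS(file.path(path, "weights.rds"))
  config <- if (manifest$kind == "dnn") {
    do.call(dnn_config, manifest$config[setdiff(names(manifest$config), "kind")])
  } else {
    cfgf <- manifest$config[setdiff(names(manifest$config), "kind")]
    do.call(rf_config, cfgf)
  }
  scaler <- structure(list(means = setNames(manifest$scaler$means,
                                            manifest$selected_features),
                           stddevs = setNames(manifest$scaler$stddevs,
                                              manifest$selected_features)),
                      class = "feature_scaler")
  structure(list(kind = manifest$kind, config = config, fit = fit,
                 selected_features = manifest$selected_features,
                 scaler = scaler, threshold = manifest$threshold),
            class = "ros_model")
}
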