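#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the two cohort
#' specifications (training and testing), the grid, preprocessing
#' parameters, mask thresholds, the decoder cost and a master seed. The
#' training and testing specs get distinct sub-seeds derived from `seed`,
#' and subject ids are prefixed `train_` / `test_`, so the two sets are
#' disjoint by construction.
#'
#' @param train_spec,test_spec [cohort_spec()] objects. Defaults mirror the
#'   design the pipeline was built around: 100 disease / 44 healthy for
#'   training, 19 / 20 for testing (testing ages around 42.5 +/- 15 and
#'   52 +/- 15 years).
#' @param grid A [grid_spec()] (default 48 x 56 x 48 at 2 mm).
#' @param fwhm_mm,target_mean Preprocessing parameters (defaults 8, 50).
#' @param p_voxel,k_min,connectivity Mask-stage thresholds (defaults 0.005,
#'   200, 18).
#' @param C Decoder soft-margin cost (default 1).
#' @param seed Master integer seed; the training cohort uses `seed`, the
#'   testing cohort `seed + 1`.
#' @param out_dir Optional directory; when given, [run_pipeline()] archives
#'   volumes, tables, model and report there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(train_spec = NULL, test_spec = NULL,
                       grid = grid_spec(c(48, 56, 48)),
                       fwhm_mm = 8, target_mean = 50,
                       p_voxel = 0.005, k_min = 200, connectivity = 18,
                       C = 1, seed, out_dir = NULL) {
  if (missing(seed)) stop("run_config requires an explicit integer seed")
  seed <- as.integer(seed)
  if (is.null(train_spec)) {
    train_spec <- cohort_spec(n_disease = 100, n_healthy = 44, seed = seed)
  }
  if (is.null(test_spec)) {
    test_spec <- cohort_spec(n_disease = 19, n_healthy = 20,
                             age_mean_disease = 42.5, age_sd_disease = 15,
                             age_mean_healthy = 52, age_sd_healthy = 15,
                             seed = seed + 1L)
  }
  stopifnot(inherits(train_spec, "cohort_spec"),
            inherits(test_spec, "cohort_spec"),
            inherits(grid, "grid_spec"))
  if (p_voxel <= 0 || p_voxel >= 1) stop("p_voxel must lie in (0, 1)")
  if (k_min < 1) stop("k_min must be >= 1")
  structure(list(train_spec = train_spec, test_spec = test_spec,
                 grid = grid, fwhm_mm = fwhm_mm, target_mean = target_mean,
                 p_voxel = p_voxel, k_min = k_min,
                 connectivity = connectivity, C = C, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

log_line <- function(log, fmt, ...) c(log, sprintf(fmt, ...))

#' Training branch: build mask and decoder from the training set only
#'
#' Generates (or accepts) the training cohort, preprocesses it, builds the
#' stage-1 discriminative mask and trains the stage-2 decoder. Nothing from
#' any testing set is touched; the provenance log records every parameter
#' used so the testing branch can replay them.
#'
#' @param config A [run_config()].
#' @param train_cohort Optional pre-generated raw `pet_cohort` (bypasses
#'   simulation, e.g. for cohorts read from disk).
#' @return A list of class `training_artifacts`: `cohort` (preprocessed),
#'   `statmap`, `mask` (`cluster_mask`), `model` (`decoder_model`),
#'   `scores` (training-set `score_set`), `log`.
#' @export
run_training <- function(config, train_cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  if (is.null(train_cohort)) {
    train_cohort <- generate_cohort(config$train_spec, config$grid,
                                    id_prefix = "train")
    log <- log_line(log, "simulated training cohort: %d disease / %d healthy, seed %d",
                    config$train_spec$n_disease, config$train_spec$n_healthy,
                    config$train_spec$seed)
  }
  co <- preprocess_cohort(train_cohort, config$fwhm_mm, config$target_mean)
  log <- log_line(log, "preprocessing: smooth fwhm %g mm then normalize in-mask mean to %g",
                  config$fwhm_mm, config$target_mean)
  stage1 <- build_discriminative_mask(co, config$p_voxel, config$k_min,
                                      config$connectivity)
  log <- log_line(log, "mask: p < %g one-sided (healthy > disease), k >= %d, connectivity %d -> %d clusters, %d voxels",
                  config$p_voxel, config$k_min, config$connectivity,
                  nrow(stage1$mask$report), sum(stage1$mask$mask))
  if (!any(stage1$mask$mask)) {
    stop("training produced an empty discriminative mask; ",
         "increase the planted effect or relax p_voxel / k_min")
  }
  feats <- extract_features(co, stage1$mask)
  model <- train_linear_svm(feats, C = config$C)
  log <- log_line(log, "decoder: linear SVM, C = %g, %d features, %d support vectors, checksum %s",
                  config$C, length(model$w), model$n_support,
                  model_checksum(model))
  scores <- decision_scores(model, feats)
  structure(list(cohort = co, statmap = stage1$statmap, mask = stage1$mask,
                 model = model, scores = scores, log = log),
            class = "training_artifacts")
}

#' Testing branch: apply frozen mask and model to held-out subjects
#'
#' Preprocesses the testing cohort with the training-time parameters,
#' extracts features through the frozen mask, scores with the frozen model
#' and evaluates. The mask and model are never re-fit here — the testing
#' set plays no part in their construction.
#'
#' @param config The [run_config()] used for training.
#' @param training A `training_artifacts` object from [run_training()].
#' @param test_cohort Optional pre-generated raw `pet_cohort`.
#' @return A list of class `run_report` with `scores`, `evaluation`
#'   (`eval_report`), `cluster_report`, `model_checksum`, `config`, `log`.
#' @export
run_testing <- function(config, training, test_cohort = NULL) {
  stopifnot(inherits(config, "run_config"),
            inherits(training, "training_artifacts"))
  log <- character()
  if (is.null(test_cohort)) {
    test_cohort <- generate_cohort(config$test_spec, config$grid,
                                   id_prefix = "test")
    log <- log_line(log, "simulated testing cohort: %d disease / %d healthy, seed %d",
                    config$test_spec$n_disease, config$test_spec$n_healthy,
                    config$test_spec$seed)
  }
  if (!identical(test_cohort$grid$shape, config$grid$shape)) {
    stop("testing cohort grid does not match the mask grid")
  }
  overlap <- intersect(test_cohort$manifest$subject_id,
                       training$cohort$manifest$subject_id)
  if (length(overlap)) {
    stop("train/test leakage: shared subject ids: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  co <- preprocess_cohort(test_cohort, config$fwhm_mm, config$target_mean)
  log <- log_line(log, "testing preprocessed with training-time parameters (fwhm %g, target %g)",
                  config$fwhm_mm, config$target_mean)
  feats <- extract_features(co, training$mask)
  scores <- decision_scores(training$model, feats)
  ev <- evaluate_scores(scores)
  log <- log_line(log, "evaluated %d held-out subjects: TP %d FN %d FP %d TN %d",
                  nrow(scores), ev$counts$TP, ev$counts$FN, ev$counts$FP,
                  ev$counts$TN)
  structure(list(scores = scores, evaluation = ev,
                 cluster_report = training$mask$report,
                 model_checksum = model_checksum(training$model),
                 config = config, log = c(training$log, log)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("== pipeline run report ==\n")
  print(x$evaluation)
  cat(sprintf("\nmask: %d clusters; model checksum %s\n",
              nrow(x$cluster_report), x$model_checksum))
  invisible(x)
}

#' Full two-branch pipeline
#'
#' [run_training()] followed by [run_testing()]; optionally archives all
#' artifacts (mask, t/z maps, weight map, cluster report, score table,
#' model JSON, report JSON, provenance log) under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return A list with `training` (`training_artifacts`) and `report`
#'   (`run_report`).
#' @export
run_pipeline <- function(config) {
  training <- run_training(config)
  report <- run_testing(config, training)
  if (!is.null(config$out_dir)) {
    archive_run(config$out_dir, config, training, report)
  }
  list(training = training, report = report)
}

archive_run <- function(dir, config, training, report) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- config$grid
  write_volume(training$statmap$t, g, file.path(dir, "tmap.nii.gz"))
  write_volume(training$statmap$z, g, file.path(dir, "zmap.nii.gz"))
  write_volume(training$mask$mask * 1, g, file.path(dir, "mask.nii.gz"))
  write_volume(weight_map(training$model, training$mask, g), g,
               file.path(dir, "weight_map.nii.gz"))
  write_cluster_report(training$mask, file.path(dir, "cluster_report.tsv"))
  utils::write.table(report$scores, file.path(dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_decoder_model(training$model, file.path(dir, "model.json"))
  mt <- report$evaluation$metrics
  jsonlite::write_json(
    list(counts = report$evaluation$counts[c("TP", "FN", "FP", "TN")],
         metrics = stats::setNames(as.list(mt$value), mt$metric),
         mann_whitney = report$evaluation$mann_whitney,
         model_checksum = report$model_checksum,
         parameters = list(fwhm_mm = config$fwhm_mm,
                           target_mean = config$target_mean,
                           p_voxel = config$p_voxel, k_min = config$k_min,
                           connectivity = config$connectivity, C = config$C,
                           seed = config$seed)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}
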