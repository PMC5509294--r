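#' Extract the masked feature matrix
#'
#' Rows are subjects in cohort order; columns are the masked voxels in
#' fixed column-major raster order. Values are the (already normalized)
#' intensities — no further per-feature standardization, so decoder weights
#' stay interpretable against raw intensity.
#'
#' @param cohort A preprocessed `pet_cohort`.
#' @param mask A `cluster_mask`, or a logical array on the cohort grid.
#' @return A numeric matrix of class `feature_matrix` with attributes
#'   `voxel_index` (linear voxel index per column), `labels` (+1 disease /
#'   -1 healthy) and `subject_id`.
#' @export
extract_features <- function(cohort, mask) {
  stopifnot(inherits(cohort, "pet_cohort"))
  m <- if (inherits(mask, "cluster_mask")) mask$mask else mask
  if (!identical(dim(m), cohort$grid$shape)) {
    stop("mask grid does not match cohort grid")
  }
  if (!any(m)) stop("empty mask: no voxels to extract features from")
  X <- cohort_matrix(cohort, m)
  labels <- ifelse(cohort$manifest$group == "disease", 1L, -1L)
  structure(X, labels = labels, subject_id = cohort$manifest$subject_id,
            class = c("feature_matrix", class(X)))
}

#' Train the linear maximum-margin decoder
#'
#' Solves the soft-margin linear SVM
#' `min 1/2 ||w||^2 + C * sum_i max(0, 1 - y_i (w.x_i + b))`
#' on the masked intensities (disease coded +1), via the convex dual
#' (libsvm through \pkg{e1071}, linear kernel, no feature scaling). The
#' primal weights are recovered as `w = sum_i alpha_i y_i x_i`, `b = -rho`,
#' oriented so that a positive decision score means disease.
#'
#' @param features A [extract_features()] matrix (or any numeric matrix
#'   with a `labels` attribute of +1/-1 or a `labels` argument).
#' @param C Soft-margin cost, default 1.
#' @param labels Optional +1/-1 vector overriding `attr(features, "labels")`.
#' @param tolerance Solver termination tolerance (default 1e-6).
#' @return A list of class `decoder_model` with `w`, `b`, `C`,
#'   `voxel_index`, `n_support`, `grid_shape`.
#' @export
train_linear_svm <- function(features, C = 1, labels = NULL,
                             tolerance = 1e-6) {
  if (is.null(labels)) labels <- attr(features, "labels")
  if (is.null(labels)) stop("no labels supplied")
  if (!all(labels %in% c(-1, 1)) || length(unique(labels)) < 2L) {
    stop("labels must contain both +1 (disease) and -1 (healthy)")
  }
  if (!is.numeric(C) || C <= 0) stop("C must be > 0")
  X <- unclass(features)
  attr(X, "labels") <- NULL
  attr(X, "subject_id") <- NULL
  y <- factor(ifelse(labels > 0, "disease", "healthy"),
              levels = c("disease", "healthy"))
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = C,
                    scale = FALSE, tolerance = tolerance)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # e1071 orients the decision value toward the first factor level
  # ("disease"); keep an explicit check in case of ties in level ordering
  dv <- as.numeric(X %*% w + b)
  lab_attr <- attr(fit$decision.values, "dimnames")[[2]]
  if (!is.null(lab_attr) && length(lab_attr) == 1 &&
      !startsWith(lab_attr, "disease")) {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, C = C,
                 voxel_index = attr(features, "voxel_index"),
                 n_support = nrow(fit$SV),
                 grid_shape = attr(features, "grid_shape")),
            class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model> %d voxel weights, b = %.4g, C = %g, %d support vectors\n",
              length(x$w), x$b, x$C, x$n_support))
  invisible(x)
}

#' Dot-product decision scores
#'
#' `s = w . x + b` per subject; a subject is predicted diseased iff
#' `s >= 0` (the tie `s = 0` resolves to disease, favouring sensitivity).
#'
#' @param model A `decoder_model`.
#' @param features A feature matrix whose columns match the model's
#'   `voxel_index` order.
#' @return A tibble of class `score_set` with columns `subject_id`,
#'   `score`, `predicted`, `true` (`predicted`/`true` as
#'   disease/healthy strings when labels are available).
#' @export
decision_scores <- function(model, features) {
  stopifnot(inherits(model, "decoder_model"))
  if (ncol(features) != length(model$w)) {
    stop("feature column count does not match model weight length")
  }
  vi <- attr(features, "voxel_index")
  if (!is.null(vi) && !is.null(model$voxel_index) &&
      !identical(as.integer(vi), as.integer(model$voxel_index))) {
    stop("feature voxel ordering does not match the model's mask")
  }
  s <- as.numeric(unclass(features) %*% model$w + model$b)
  labels <- attr(features, "labels")
  ids <- attr(features, "subject_id")
  if (is.null(ids)) ids <- sprintf("subj_%03d", seq_along(s))
  out <- tibble::tibble(
    subject_id = ids,
    score = s,
    predicted = ifelse(s >= 0, "disease", "healthy"),
    true = if (is.null(labels)) NA_character_ else
      ifelse(labels > 0, "disease", "healthy")
  )
  class(out) <- c("score_set", class(out))
  out
}

#' Back-project decoder weights to a brain volume
#'
#' Scatters the per-masked-voxel weights into a full volume (exact zero
#' outside the mask), e.g. for glass-brain style rendering or NIfTI export.
#'
#' @param model A `decoder_model`.
#' @param mask A `cluster_mask` or logical array consistent with the model.
#' @param grid A [grid_spec()].
#' @return Numeric array on `grid`.
#' @export
weight_map <- function(model, mask, grid) {
  m <- if (inherits(mask, "cluster_mask")) mask$mask else mask
  check_volume_grid(m, grid, "mask")
  if (sum(m) != length(model$w)) {
    stop("mask size does not match model weight length")
  }
  out <- array(0, dim = grid$shape)
  out[which(m)] <- model$w
  out
}

#' Pair decoder weights with the stage-1 z statistic
#'
#' One row per masked voxel: the univariate z (normal-quantile transform of
#' the one-sided GLM p-value) and the multivariate decoder weight. Strongly
#' hypometabolic voxels (high z) are expected to draw negative weights.
#'
#' @param model A `decoder_model`.
#' @param statmap The stage-1 `stat_map`.
#' @param mask The `cluster_mask` (or logical array) the model was trained
#'   on.
#' @return Tibble with columns `voxel`, `z`, `t`, `weight`.
#' @export
weight_vs_stat <- function(model, statmap, mask) {
  stopifnot(inherits(statmap, "stat_map"))
  m <- if (inherits(mask, "cluster_mask")) mask$mask else mask
  idx <- which(m)
  if (length(idx) != length(model$w)) {
    stop("mask size does not match model weight length")
  }
  tibble::tibble(voxel = idx, z = statmap$z[idx], t = statmap$t[idx],
                 weight = model$w)
}

#' Spearman rank correlation between z and weight
#'
#' Degenerate inputs (constant z or weight) yield `NA` with a warning
#' rather than an error.
#'
#' @param pairs Output of [weight_vs_stat()].
#' @return Single numeric (Spearman rho), possibly `NA`.
#' @export
weight_stat_correlation <- function(pairs) {
  if (stats::sd(pairs$z) == 0 || stats::sd(pairs$weight) == 0) {
    warning("constant z or weight: rank correlation undefined")
    return(NA_real_)
  }
  stats::cor(pairs$z, pairs$weight, method = "spearman")
}

#' Serialize / restore a decoder model as JSON
#'
#' @param model A `decoder_model`.
#' @param path Output path.
#' @return `read_decoder_model()` returns the `decoder_model`.
#' @export
write_decoder_model <- function(model, path) {
  stopifnot(inherits(model, "decoder_model"))
  obj <- list(w = model$w, b = model$b, C = model$C,
              voxel_index = model$voxel_index,
              n_support = model$n_support,
              checksum = model_checksum(model))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_decoder_model
#' @export
read_decoder_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w = as.numeric(obj$w), b = obj$b, C = obj$C,
                 voxel_index = as.integer(obj$voxel_index),
                 n_support = obj$n_support),
            class = "decoder_model")
}

#' MD5 checksum of a decoder model's numeric content
#'
#' Used by the pipeline's provenance report to assert that two runs with the
#' same configuration and seed produced the same model.
#'
#' @param model A `decoder_model`.
#' @return Character MD5 digest.
#' @export
model_checksum <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c(format(c(model$w, model$b, model$C), digits = 17),
               as.character(model$voxel_index)), f)
  unname(tools::md5sum(f))
}
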