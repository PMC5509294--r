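#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decoder model into one row per voxel weight
#'
#' @param x A `decoder_model`.
#' @param grid Optional [grid_spec()]; when supplied, voxel indices are
#'   expanded to `i, j, k` and template mm coordinates.
#' @param ... Unused.
#' @return Tibble with `voxel`, `weight` (plus coordinates when `grid` is
#'   given).
#' @method tidy decoder_model
#' @export
tidy.decoder_model <- function(x, grid = NULL, ...) {
  out <- tibble::tibble(voxel = as.integer(x$voxel_index), weight = x$w)
  if (!is.null(grid)) {
    ijk <- arrayInd(out$voxel, grid$shape)
    mm <- voxel_to_mm(grid, ijk)
    out <- dplyr::mutate(out, i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                         x_mm = mm[, 1], y_mm = mm[, 2], z_mm = mm[, 3])
  }
  out
}

#' One-row summary of a decoder model
#'
#' @param x A `decoder_model`.
#' @param ... Unused.
#' @return Tibble with `n_features`, `n_support`, `C`, `b`, `w_norm`.
#' @method glance decoder_model
#' @export
glance.decoder_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$w), n_support = x$n_support,
                 C = x$C, b = x$b, w_norm = sqrt(sum(x$w^2)))
}

#' Tidy a stage-1 statistical map
#'
#' @param x A `stat_map`.
#' @param ... Unused.
#' @return Tibble with one row per in-mask voxel: `voxel`, `t`, `p`, `z`.
#' @method tidy stat_map
#' @export
tidy.stat_map <- function(x, ...) {
  idx <- which(x$mask)
  tibble::tibble(voxel = idx, t = x$t[idx], p = x$p[idx], z = x$z[idx])
}

#' @method glance stat_map
#' @export
glance.stat_map <- function(x, ...) {
  idx <- which(x$mask)
  tibble::tibble(n_voxels = length(idx), df = x$df,
                 max_t = max(x$t[idx]), min_p = min(x$p[idx]))
}

#' Tidy an evaluation report into the five-metric table
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The metrics tibble with printed-style percentage columns.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  format_metrics_percent(x$metrics)
}

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  mt <- stats::setNames(x$metrics$value, x$metrics$metric)
  tibble::tibble(TP = x$counts$TP, FN = x$counts$FN, FP = x$counts$FP,
                 TN = x$counts$TN, Se = mt[["Se"]], Sp = mt[["Sp"]],
                 PPV = mt[["PPV"]], NPV = mt[["NPV"]], Acc = mt[["Acc"]],
                 mw_U = x$mann_whitney$U, mw_p = x$mann_whitney$p)
}

#' @method glance run_report
#' @export
glance.run_report <- function(x, ...) {
  dplyr::mutate(glance(x$evaluation),
                n_clusters = nrow(x$cluster_report),
                mask_voxels = sum(x$cluster_report$K))
}

#' Box plot of decision scores by true group
#'
#' The dot-product decision scores split by true group membership — the
#' standard way to visualize how well the decoder's scalar output separates
#' the classes. Scores above the dashed zero line are classified as
#' disease.
#'
#' @param object A `score_set` from [decision_scores()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot score_set
#' @export
autoplot.score_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$true, y = .data$score,
                                       fill = .data$true)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "true group", y = "decision score (w . x + b)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of decoder weight against univariate z
#'
#' @param pairs Output of [weight_vs_stat()].
#' @return A ggplot object.
#' @export
plot_weight_vs_z <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$z, y = .data$weight)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "univariate z (healthy > disease)",
                  y = "decoder weight") +
    ggplot2::theme_minimal()
}
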