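#' Build the voxel-wise ANCOVA design matrix
#'
#' Columns: intercept, group indicator (healthy = 1, disease = 0) and
#' mean-centred age. The contrast vector selects the group column, so a
#' positive effect is healthy-minus-disease — the hypometabolism direction.
#' If the age column is constant (zero variance) it is dropped with a
#' warning rather than producing a rank-deficient fit.
#'
#' @param cohort A `pet_cohort` containing both groups.
#' @param covariates Character vector of nuisance covariates to adjust for;
#'   currently `"age"` or empty.
#' @return A list of class `design_matrix` with `X` (n x p), `contrast`
#'   (length p), `groups`, and `terms`.
#' @export
build_design <- function(cohort, covariates = "age") {
  stopifnot(inherits(cohort, "pet_cohort"))
  man <- cohort$manifest
  if (length(unique(man$group)) < 2L) {
    stop("both groups must be present to build a group-contrast design")
  }
  healthy <- as.numeric(man$group == "healthy")
  X <- cbind(intercept = 1, group_healthy = healthy)
  if ("age" %in% covariates) {
    age_c <- man$age - mean(man$age)
    if (isTRUE(all.equal(stats::var(age_c), 0)) || all(age_c == 0)) {
      warning("age covariate is constant; dropping it from the design")
    } else {
      X <- cbind(X, age_centered = age_c)
    }
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  contrast <- as.numeric(colnames(X) == "group_healthy")
  structure(list(X = X, contrast = contrast, groups = man$group,
                 terms = colnames(X)),
            class = "design_matrix")
}

#' Voxel-wise general linear model t-map
#'
#' Fits the same ordinary-least-squares model independently at every
#' in-mask voxel and forms the contrast t statistic
#' `t = c'b / sqrt(s2 * c'(X'X)^-1 c)` with `s2 = RSS / df`,
#' `df = n - rank(X)`. The p-value is one-sided for a positive contrast
#' (healthy > disease, i.e. hypometabolism in the disease group), and
#' `z = qnorm(1 - p)` is the equivalent normal quantile (p is clipped to
#' `[1e-300, 1 - 1e-16]` so z stays finite at the conventions below).
#'
#' Conventions for degenerate voxels: an all-zero intensity series gives
#' `t = 0, p = 1`; a zero-residual voxel with a zero contrast estimate
#' (e.g. identical values in both groups) gives `t = 0, p = 0.5`.
#'
#' @param cohort A preprocessed `pet_cohort`.
#' @param design A [build_design()] result.
#' @param mask Logical analysis mask (default: the cohort brain mask).
#' @return A list of class `stat_map` with arrays `t`, `p`, `z` (NA outside
#'   `mask`), scalar `df`, and the `mask` and `grid` used.
#' @export
fit_voxelwise_glm <- function(cohort, design, mask = cohort$brain_mask) {
  stopifnot(inherits(cohort, "pet_cohort"), inherits(design, "design_matrix"))
  X <- design$X
  cvec <- design$contrast
  n <- nrow(X)
  stopifnot(n == length(cohort$subjects))
  df <- n - qr(X)$rank
  if (df < 1) stop("residual degrees of freedom < 1")
  Y <- cohort_matrix(cohort, mask)              # n x V
  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, Y)               # p x V
  resid <- Y - X %*% B
  rss <- colSums(resid^2)
  s2 <- rss / df
  cb <- as.numeric(crossprod(cvec, B))
  cvar <- as.numeric(crossprod(cvec, XtXinv %*% cvec))
  se <- sqrt(s2 * cvar)
  # voxels whose series are (numerically) perfectly fit need the 0/0
  # convention: compare residual SD and contrast against the voxel's own
  # scale rather than against exact zero
  scale <- sqrt(colSums(Y^2) / n) + 1e-300
  zero_resid <- sqrt(s2) <= 1e-10 * scale
  zero_cb <- abs(cb) <= 1e-8 * scale
  tval <- ifelse(!zero_resid, cb / se,
                 ifelse(zero_cb, 0, sign(cb) * Inf))
  pval <- stats::pt(tval, df, lower.tail = FALSE)
  allzero <- colSums(Y != 0) == 0L
  tval[allzero] <- 0
  pval[allzero] <- 1
  shape <- cohort$grid$shape
  to_vol <- function(v) {
    out <- array(NA_real_, dim = shape)
    out[mask] <- v
    out
  }
  pc <- pmin(pmax(pval, 1e-300), 1 - 1e-16)
  structure(list(t = to_vol(tval), p = to_vol(pval),
                 z = to_vol(stats::qnorm(pc, lower.tail = FALSE)),
                 df = df, mask = mask, grid = cohort$grid,
                 contrast = cvec, terms = design$terms),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  tv <- x$t[x$mask]
  cat(sprintf("<stat_map> %d in-mask voxels, df = %d, t range [%.3g, %.3g]\n",
              sum(x$mask), x$df, min(tv), max(tv)))
  invisible(x)
}

#' Voxel-level p threshold
#'
#' Retains a voxel iff its one-sided p-value is strictly below `p_voxel`
#' (the conventional `P < 0.005` reads as a strict inequality). Voxels
#' outside the analysis mask are never retained.
#'
#' @param statmap A [fit_voxelwise_glm()] result.
#' @param p_voxel Voxel-level threshold, default 0.005.
#' @return Logical array.
#' @export
threshold_voxels <- function(statmap, p_voxel = 0.005) {
  stopifnot(inherits(statmap, "stat_map"))
  if (!is.numeric(p_voxel) || p_voxel <= 0 || p_voxel >= 1) {
    stop("p_voxel must lie in (0, 1)")
  }
  out <- !is.na(statmap$p) & statmap$p < p_voxel
  out
}

# neighbor offsets for 6 (faces), 18 (faces+edges) or 26 (faces+edges+
# corners) connectivity in 3D
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26")
  }
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(off != 0)
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

#' Label connected components of a binary volume
#'
#' Breadth-first labelling of foreground voxels under 6-, 18- (default,
#' faces plus edges but not corners) or 26-connectivity. Components are
#' numbered 1..n in raster-scan order of their first (column-major
#' smallest-index) voxel, so labelling is deterministic.
#'
#' @param binary Logical (or 0/1) 3D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same shape; 0 is background.
#' @export
label_clusters <- function(binary, connectivity = 18) {
  stopifnot(length(dim(binary)) == 3L)
  d <- dim(binary)
  fg <- binary != 0 & !is.na(binary)
  labels <- array(0L, dim = d)
  off <- connectivity_offsets(as.integer(connectivity))
  todo <- which(fg)
  cur <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    labels[start] <- cur
    frontier <- arrayInd(start, d)
    while (nrow(frontier)) {
      # expand every frontier voxel by every offset at once
      cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), ,
                       drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(frontier)), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) break
      lin <- unique(cand[, 1] + d[1] * (cand[, 2] - 1) +
                      d[1] * d[2] * (cand[, 3] - 1))
      lin <- lin[fg[lin] & labels[lin] == 0L]
      if (!length(lin)) break
      labels[lin] <- cur
      frontier <- arrayInd(lin, d)
    }
  }
  labels
}

#' Cluster-extent filtering and cluster report
#'
#' Retains connected components with at least `k_min` voxels (inclusive:
#' "k >= 200 voxels" keeps a 200-voxel cluster) and builds the
#' discriminative mask as their union. Clusters are re-labelled 1..n by
#' decreasing size, and the report lists, per retained cluster, its voxel
#' count `K`, the peak (maximum-t) voxel's template mm coordinates, the
#' peak t and its one-sided p-value.
#'
#' @param labels Integer label array from [label_clusters()].
#' @param statmap The [fit_voxelwise_glm()] result the labels derive from.
#' @param k_min Minimum cluster extent in voxels, default 200.
#' @return A list of class `cluster_mask` with `mask` (logical array),
#'   `labels` (size-ordered integer array) and `report` (tibble with
#'   columns `cluster_id`, `K`, `peak_x_mm`, `peak_y_mm`, `peak_z_mm`,
#'   `peak_t`, `p_peak`, sorted by decreasing `K`). An empty result (no
#'   surviving cluster) is valid but warned about.
#' @export
apply_extent_threshold <- function(labels, statmap, k_min = 200) {
  stopifnot(inherits(statmap, "stat_map"))
  stopifnot(identical(dim(labels), dim(statmap$t)))
  if (k_min < 1) stop("k_min must be >= 1")
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= k_min)
  grid <- statmap$grid
  d <- dim(labels)
  out_labels <- array(0L, dim = d)
  mask <- array(FALSE, dim = d)
  if (length(keep) == 0L) {
    warning("no cluster survives the extent threshold; mask is empty")
    report <- tibble::tibble(cluster_id = integer(), K = integer(),
                             peak_x_mm = numeric(), peak_y_mm = numeric(),
                             peak_z_mm = numeric(), peak_t = numeric(),
                             p_peak = numeric())
    return(structure(list(mask = mask, labels = out_labels, report = report,
                          grid = grid, k_min = k_min),
                     class = "cluster_mask"))
  }
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    old <- keep[i]
    vox <- which(labels == old)
    out_labels[vox] <- i
    mask[vox] <- TRUE
    peak <- vox[which.max(statmap$t[vox])]
    pk <- voxel_to_mm(grid, as.numeric(arrayInd(peak, d)))
    rows[[i]] <- tibble::tibble(
      cluster_id = i, K = length(vox),
      peak_x_mm = pk[1], peak_y_mm = pk[2], peak_z_mm = pk[3],
      peak_t = statmap$t[peak], p_peak = statmap$p[peak]
    )
  }
  structure(list(mask = mask, labels = out_labels,
                 report = dplyr::bind_rows(rows), grid = grid, k_min = k_min),
            class = "cluster_mask")
}

#' @export
print.cluster_mask <- function(x, ...) {
  cat(sprintf("<cluster_mask> %d clusters, %d voxels retained (k_min = %d)\n",
              nrow(x$report), sum(x$mask), x$k_min))
  if (nrow(x$report)) print(x$report)
  invisible(x)
}

#' Stage-1 wrapper: t-map, voxel threshold, cluster-extent mask
#'
#' Runs [build_design()], [fit_voxelwise_glm()], [threshold_voxels()],
#' [label_clusters()] and [apply_extent_threshold()] in sequence on a
#' preprocessed cohort.
#'
#' @param cohort A preprocessed `pet_cohort`.
#' @param p_voxel Voxel-level one-sided p threshold (default 0.005).
#' @param k_min Cluster extent threshold in voxels (default 200).
#' @param connectivity Component connectivity, 6/18/26 (default 18).
#' @param covariates Nuisance covariates for the design (default `"age"`).
#' @return List with `statmap` (`stat_map`) and `mask` (`cluster_mask`).
#' @export
build_discriminative_mask <- function(cohort, p_voxel = 0.005, k_min = 200,
                                      connectivity = 18,
                                      covariates = "age") {
  design <- build_design(cohort, covariates = covariates)
  statmap <- fit_voxelwise_glm(cohort, design)
  supra <- threshold_voxels(statmap, p_voxel)
  labels <- label_clusters(supra, connectivity)
  cmask <- apply_extent_threshold(labels, statmap, k_min)
  list(statmap = statmap, mask = cmask)
}

#' Write a cluster report as TSV
#'
#' @param cluster_mask A `cluster_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(cluster_mask, path) {
  stopifnot(inherits(cluster_mask, "cluster_mask"))
  utils::write.table(cluster_mask$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
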