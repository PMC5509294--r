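#' Planted hypometabolic cluster specification
#'
#' A sphere in template mm coordinates inside which the disease group's
#' tracer uptake is reduced by a fixed fraction. Effects of overlapping
#' spheres combine by maximum (never sum), so the planted fractional
#' reduction can never exceed 1.
#'
#' @param center_mm Numeric length-3 sphere centre, template mm coordinates.
#' @param radius_mm Sphere radius in mm (> 0).
#' @param effect_fraction Fractional intensity reduction in the disease
#'   group, in `[0, 1]`. 0.1 means disease subjects lose 10% of the local
#'   signal.
#' @return An object of class `cluster_spec`.
#' @export
cluster_spec <- function(center_mm, radius_mm, effect_fraction) {
  stopifnot(length(center_mm) == 3L, all(is.finite(center_mm)))
  if (!is.numeric(radius_mm) || radius_mm <= 0) stop("radius_mm must be > 0")
  if (!is.numeric(effect_fraction) || effect_fraction < 0 || effect_fraction > 1) {
    stop("effect_fraction must lie in [0, 1]")
  }
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = as.numeric(radius_mm),
                 effect_fraction = as.numeric(effect_fraction)),
            class = "cluster_spec")
}

#' Default planted clusters
#'
#' Four spheres emulating a predominantly posterior (bilateral
#' occipito-temporal plus midline) hypometabolic pattern with a weaker
#' frontal component, sized so each comfortably exceeds the default
#' 200-voxel cluster-extent threshold at 2 mm resolution. Effect fractions
#' of 8-12% are in the range routinely described for regional
#' hypometabolism in FDG-PET group studies.
#'
#' @return A list of [cluster_spec()] objects.
#' @export
default_clusters <- function() {
  list(
    cluster_spec(c(-18, -34, -14), 12, 0.12),
    cluster_spec(c(18, -34, -14), 12, 0.12),
    cluster_spec(c(0, -28, 12), 14, 0.10),
    cluster_spec(c(0, 30, -6), 10, 0.08)
  )
}

#' Synthetic cohort specification
#'
#' Parameters of a two-group synthetic FDG-PET cohort. Defaults mirror the
#' training-set structure the pipeline was designed around (100 disease /
#' 44 healthy; group ages around 46 +/- 12 and 45 +/- 16 years) and a noise
#' level of 10% of the template baseline.
#'
#' @param n_disease,n_healthy Subject counts per group (each >= 1).
#' @param age_mean_disease,age_sd_disease,age_mean_healthy,age_sd_healthy
#'   Group age distributions in years; ages are drawn Normal and truncated
#'   to `[18, 90]`.
#' @param age_slope Additive intensity change per year of age (applied to
#'   centred age, reference = the cohort's expected pooled mean age), in the
#'   same units as the template intensity. Negative values emulate the mild
#'   metabolic decline with age.
#' @param noise_sd SD of i.i.d. additive Gaussian voxel noise (intensity
#'   units), applied inside the brain mask only.
#' @param global_scale_sd SD of the per-subject multiplicative global
#'   scaling factor `g ~ Normal(1, global_scale_sd)` truncated to be
#'   positive, emulating injected-dose / uptake-time variation.
#' @param clusters List of [cluster_spec()] planted hypometabolic spheres.
#' @param seed Integer seed; mandatory, since reproducibility of simulated
#'   cohorts is part of the generator's contract.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_disease = 100, n_healthy = 44,
                        age_mean_disease = 46.5, age_sd_disease = 12,
                        age_mean_healthy = 45.4, age_sd_healthy = 16,
                        age_slope = -0.2, noise_sd = 10,
                        global_scale_sd = 0.1,
                        clusters = default_clusters(), seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("cohort_spec requires an explicit integer seed")
  }
  stopifnot(n_disease >= 1, n_healthy >= 1,
            noise_sd >= 0, global_scale_sd >= 0,
            age_sd_disease >= 0, age_sd_healthy >= 0)
  if (!is.list(clusters) ||
      !all(vapply(clusters, inherits, logical(1), "cluster_spec"))) {
    stop("clusters must be a list of cluster_spec objects")
  }
  structure(list(
    n_disease = as.integer(n_disease), n_healthy = as.integer(n_healthy),
    age_mean_disease = age_mean_disease, age_sd_disease = age_sd_disease,
    age_mean_healthy = age_mean_healthy, age_sd_healthy = age_sd_healthy,
    age_slope = age_slope, noise_sd = noise_sd,
    global_scale_sd = global_scale_sd, clusters = clusters,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# expected pooled mean age, used as the reference age of the additive
# age trend (centred so the trend has mean ~0 across the cohort)
reference_age <- function(spec) {
  (spec$n_disease * spec$age_mean_disease +
     spec$n_healthy * spec$age_mean_healthy) /
    (spec$n_disease + spec$n_healthy)
}

#' Ellipsoidal brain template
#'
#' Builds the shared "brain": an axis-aligned ellipsoid centred on the grid
#' centre with semi-axes 90% of the half-extent of each axis, filled with a
#' constant baseline intensity, zero outside. Deliberately anatomy-free —
#' the pipeline only needs a compact in-mask region on which group effects
#' and noise live.
#'
#' @param grid A [grid_spec()]; every axis must have at least 3 voxels.
#' @param baseline Constant in-mask intensity (> 0), default 100.
#' @return List with `volume` (numeric array) and `brain_mask` (logical
#'   array) on `grid`.
#' @export
make_template <- function(grid, baseline = 100) {
  stopifnot(inherits(grid, "grid_spec"))
  if (any(grid$shape < 3L)) stop("degenerate grid: every axis needs >= 3 voxels")
  if (!is.numeric(baseline) || baseline <= 0) stop("baseline must be > 0")
  ax <- axis_coords_mm(grid)
  center <- vapply(ax, function(v) mean(range(v)), numeric(1))
  semi <- vapply(1:3, function(a) {
    0.9 * (grid$shape[a] * grid$voxel_size_mm) / 2
  }, numeric(1))
  u <- lapply(1:3, function(a) ((ax[[a]] - center[a]) / semi[a])^2)
  # outer sum of squared normalized coordinates; <= 1 is inside
  q <- outer(outer(u[[1]], u[[2]], "+"), u[[3]], "+")
  brain_mask <- q <= 1
  volume <- array(0, dim = grid$shape)
  volume[brain_mask] <- baseline
  list(volume = volume, brain_mask = brain_mask)
}

#' Fractional-reduction effect map
#'
#' Rasterizes planted clusters onto the grid: each voxel carries the maximum
#' `effect_fraction` over all spheres that cover its centre, clipped to the
#' brain mask, zero elsewhere. A cluster whose support misses the brain mask
#' entirely triggers a warning (it can never be recovered downstream).
#'
#' @param grid A [grid_spec()].
#' @param brain_mask Logical array on `grid`.
#' @param clusters List of [cluster_spec()].
#' @return Numeric array of fractional reductions in `[0, 1]`.
#' @export
effect_map <- function(grid, brain_mask, clusters) {
  check_volume_grid(brain_mask, grid, "brain_mask")
  eff <- array(0, dim = grid$shape)
  if (length(clusters) == 0L) return(eff)
  ax <- axis_coords_mm(grid)
  for (cl in clusters) {
    d2 <- outer(outer((ax[[1]] - cl$center_mm[1])^2,
                      (ax[[2]] - cl$center_mm[2])^2, "+"),
                (ax[[3]] - cl$center_mm[3])^2, "+")
    inside <- d2 <= cl$radius_mm^2
    if (!any(inside & brain_mask)) {
      warning(sprintf("planted cluster at (%s) mm lies entirely outside the brain mask",
                      paste(cl$center_mm, collapse = ", ")))
    }
    eff <- pmax(eff, cl$effect_fraction * inside)
  }
  eff[!brain_mask] <- 0
  eff
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Simulate one subject scan
#'
#' The generative model is
#' `g * (template * (1 - effect * is_disease) + age_slope * (age - ref_age)) + noise`
#' inside the brain mask and exactly zero outside, with
#' `g ~ Normal(1, global_scale_sd)` truncated positive and voxel noise
#' i.i.d. `Normal(0, noise_sd)`. Disease lowers intensity multiplicatively
#' (hypometabolism); age shifts it additively.
#'
#' Randomness is taken from the current RNG state: callers (normally
#' [generate_cohort()]) are responsible for seeding.
#'
#' @param template Output of [make_template()].
#' @param effect Effect map from [effect_map()].
#' @param group `"disease"` or `"healthy"`.
#' @param age Subject age in years.
#' @param spec A [cohort_spec()] (supplies `age_slope`, `noise_sd`,
#'   `global_scale_sd` and the reference age).
#' @param id Subject identifier string.
#' @return A list of class `subject_scan` with fields `id`, `group`, `age`,
#'   `volume`.
#' @export
simulate_subject <- function(template, effect, group, age, spec,
                             id = "subj") {
  group <- match.arg(group, c("disease", "healthy"))
  mask <- template$brain_mask
  vol <- template$volume
  if (group == "disease") vol <- vol * (1 - effect)
  age_term <- spec$age_slope * (age - reference_age(spec))
  vol[mask] <- vol[mask] + age_term
  g <- rnorm_trunc(1, 1, spec$global_scale_sd, lower = .Machine$double.eps)
  vol <- g * vol
  if (spec$noise_sd > 0) {
    vol[mask] <- vol[mask] + rnorm(sum(mask), 0, spec$noise_sd)
  }
  vol[!mask] <- 0
  structure(list(id = id, group = group, age = age, volume = vol),
            class = "subject_scan")
}

#' Generate a complete synthetic cohort
#'
#' Draws ages (Normal per group, truncated to `[18, 90]`), then simulates
#' every subject scan on the shared template. All randomness flows from
#' `spec$seed` through a fixed draw order (all ages first, then each
#' subject's global scale and noise in manifest order), so two calls with
#' the same spec and grid are bit-identical.
#'
#' @param spec A [cohort_spec()].
#' @param grid A [grid_spec()] (default 48 x 56 x 48 at 2 mm, a
#'   reduced-resolution template-like lattice).
#' @param baseline Template in-mask intensity.
#' @param id_prefix Prefix for subject ids (e.g. `"train"`).
#' @return An object of class `pet_cohort`: list with `grid`, `subjects`
#'   (list of `subject_scan`), `brain_mask`, `effect` (ground-truth
#'   fractional-reduction map), `spec`, and `manifest` (tibble with
#'   `subject_id`, `group`, `age`).
#' @examples
#' co <- generate_cohort(cohort_spec(n_disease = 3, n_healthy = 3, seed = 1),
#'                       grid_spec(c(16, 16, 16)))
#' co$manifest
#' @export
generate_cohort <- function(spec, grid = grid_spec(c(48, 56, 48)),
                            baseline = 100, id_prefix = "subj") {
  stopifnot(inherits(spec, "cohort_spec"), inherits(grid, "grid_spec"))
  tpl <- make_template(grid, baseline = baseline)
  eff <- effect_map(grid, tpl$brain_mask, spec$clusters)
  n <- spec$n_disease + spec$n_healthy
  groups <- rep(c("disease", "healthy"), c(spec$n_disease, spec$n_healthy))
  set.seed(spec$seed)
  ages <- c(
    rnorm_trunc(spec$n_disease, spec$age_mean_disease, spec$age_sd_disease, 18, 90),
    rnorm_trunc(spec$n_healthy, spec$age_mean_healthy, spec$age_sd_healthy, 18, 90)
  )
  ids <- sprintf("%s_%s_%03d", id_prefix, substr(groups, 1, 1), seq_len(n))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- simulate_subject(tpl, eff, groups[i], ages[i], spec,
                                      id = ids[i])
  }
  manifest <- tibble::tibble(subject_id = ids, group = groups, age = ages)
  structure(list(grid = grid, subjects = subjects,
                 brain_mask = tpl$brain_mask, effect = eff,
                 template = tpl$volume, spec = spec, manifest = manifest),
            class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat(sprintf("<pet_cohort> %d subjects (%s), grid %s, %d in-mask voxels\n",
              nrow(x$manifest),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              paste(x$grid$shape, collapse = "x"), sum(x$brain_mask)))
  invisible(x)
}

#' Assemble a cohort from existing volumes
#'
#' Builds a `pet_cohort` from volumes already in memory (e.g. read from
#' NIfTI files with [read_volume()]), bypassing simulation. All volumes
#' must share `grid`.
#'
#' @param volumes List of 3D numeric arrays, one per subject.
#' @param groups Character vector, `"disease"`/`"healthy"` per subject.
#' @param ages Numeric ages in years.
#' @param grid A [grid_spec()].
#' @param brain_mask Logical array on `grid`; default marks voxels that are
#'   nonzero in every subject.
#' @param ids Subject identifiers (default `subj_001`, ...).
#' @return A `pet_cohort`.
#' @export
cohort_from_volumes <- function(volumes, groups, ages, grid,
                                brain_mask = NULL, ids = NULL) {
  stopifnot(inherits(grid, "grid_spec"),
            length(volumes) == length(groups),
            length(volumes) == length(ages),
            all(groups %in% c("disease", "healthy")))
  for (v in volumes) check_volume_grid(v, grid)
  if (is.null(brain_mask)) {
    brain_mask <- Reduce(`&`, lapply(volumes, function(v) v != 0))
  }
  if (!any(brain_mask)) stop("brain_mask is empty")
  if (is.null(ids)) ids <- sprintf("subj_%03d", seq_along(volumes))
  subjects <- Map(function(id, g, a, v) {
    structure(list(id = id, group = g, age = a, volume = v),
              class = "subject_scan")
  }, ids, groups, ages, volumes)
  names(subjects) <- NULL
  structure(list(grid = grid, subjects = subjects, brain_mask = brain_mask,
                 effect = NULL, template = NULL, spec = NULL,
                 manifest = tibble::tibble(subject_id = ids, group = groups,
                                           age = ages)),
            class = "pet_cohort")
}

#' Cohort volumes as a subjects-by-voxels matrix
#'
#' Stacks all subject volumes row-wise, restricted to the voxels selected by
#' `mask` (default: the cohort brain mask) in R's column-major (raster)
#' order. This is the layout both the voxel-wise GLM and the decoder
#' consume.
#'
#' @param cohort A `pet_cohort`.
#' @param mask Logical array on the cohort grid.
#' @return Numeric matrix, `n_subjects` x `sum(mask)`; rownames are subject
#'   ids, attribute `voxel_index` holds the linear voxel indices of columns.
#' @export
cohort_matrix <- function(cohort, mask = cohort$brain_mask) {
  check_volume_grid(mask, cohort$grid, "mask")
  idx <- which(mask)
  out <- vapply(cohort$subjects, function(s) s$volume[idx],
                numeric(length(idx)))
  # vapply drops to a plain vector for a single-voxel mask
  out <- t(matrix(out, nrow = length(idx)))
  rownames(out) <- cohort$manifest$subject_id
  attr(out, "voxel_index") <- idx
  out
}

#' Write cohort volumes and manifest to disk
#'
#' Each subject volume is written as NIfTI-1 under `dir`, and a tab-separated
#' manifest with columns `subject_id`, `group`, `age`, `path` is written as
#' `manifest.tsv`.
#'
#' @param cohort A `pet_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with the `path` column), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(cohort$manifest$subject_id, ".nii.gz"))
  for (i in seq_along(cohort$subjects)) {
    write_volume(cohort$subjects[[i]]$volume, cohort$grid, paths[i])
  }
  man <- dplyr::mutate(cohort$manifest, path = paths)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_volume(cohort$brain_mask * 1, cohort$grid,
               file.path(dir, "brain_mask.nii.gz"))
  invisible(man)
}
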