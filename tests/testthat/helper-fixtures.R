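# Shared small fixtures, built in code at test time.

small_grid <- function(n = c(16, 16, 16), vs = 2) grid_spec(n, vs)

# A tiny cohort wrapping explicit per-voxel values: `values` is an
# n_subjects x n_voxels matrix scattered into the first voxels of a small
# all-brain grid. Lets GLM tests control voxel series exactly.
value_cohort <- function(values, groups, ages = NULL, shape = c(3, 3, 3)) {
  grid <- grid_spec(shape)
  n <- nrow(values)
  if (is.null(ages)) ages <- rep(50, n)
  mask <- array(TRUE, dim = shape)
  vols <- lapply(seq_len(n), function(i) {
    v <- array(1, dim = shape)   # nonzero filler so brain_mask stays full
    v[seq_len(ncol(values))] <- values[i, ]
    v
  })
  cohort_from_volumes(vols, groups, ages, grid, brain_mask = mask)
}

# Quick two-group synthetic cohort on a small grid with one centred sphere.
quick_cohort <- function(n_disease, n_healthy, effect, seed,
                         noise_sd = 10, radius_mm = 10,
                         shape = c(32, 32, 32), global_scale_sd = 0.1,
                         age_slope = -0.2, id_prefix = "subj") {
  clusters <- if (effect > 0) {
    list(cluster_spec(c(0, 0, 0), radius_mm, effect))
  } else {
    list()
  }
  generate_cohort(
    cohort_spec(n_disease = n_disease, n_healthy = n_healthy,
                noise_sd = noise_sd, global_scale_sd = global_scale_sd,
                age_slope = age_slope, clusters = clusters, seed = seed),
    grid_spec(shape), id_prefix = id_prefix)
}
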