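test_that("grid affine maps voxel indices to template mm and back", {
  g <- grid_spec(c(48, 56, 48), voxel_size_mm = 2)
  expect_equal(voxel_to_mm(g, c(1, 1, 1)), g$origin_mm)
  ijk <- rbind(c(1, 1, 1), c(24, 28, 24), c(48, 56, 48))
  expect_equal(mm_to_voxel(g, voxel_to_mm(g, ijk)), ijk)
  expect_error(grid_spec(c(0, 4, 4)), "shape")
  expect_error(grid_spec(c(4, 4, 4), voxel_size_mm = 0), "voxel_size")
})

test_that("volumes round-trip through NIfTI-1 with grid metadata intact", {
  g <- grid_spec(c(8, 10, 12))
  v <- array(rnorm(prod(g$shape)), dim = g$shape)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, g, path)
  back <- read_volume(path)
  expect_equal(back$volume, v, tolerance = 1e-7)
  expect_equal(back$grid$voxel_size_mm, g$voxel_size_mm)
  expect_equal(back$grid$origin_mm, g$origin_mm)
})

test_that("template is a constant-intensity ellipsoid matching the lattice equation", {
  g <- grid_spec(c(32, 32, 32))
  tpl <- make_template(g, baseline = 100)
  expect_true(all(tpl$volume[tpl$brain_mask] == 100))
  expect_true(all(tpl$volume[!tpl$brain_mask] == 0))

  # reflection symmetry about the ellipsoid centre on every axis
  m <- tpl$brain_mask
  expect_identical(m, m[rev(seq_len(32)), , ])
  expect_identical(m, m[, rev(seq_len(32)), ])
  expect_identical(m, m[, , rev(seq_len(32))])

  # exhaustive lattice scan of the ellipsoid inequality
  coords <- as.matrix(expand.grid(i = 1:32, j = 1:32, k = 1:32))
  mm <- voxel_to_mm(g, coords)
  center <- colMeans(rbind(voxel_to_mm(g, c(1, 1, 1)),
                           voxel_to_mm(g, c(32, 32, 32))))
  semi <- 0.9 * 32 * 2 / 2
  inside <- rowSums(sweep(mm, 2, center)^2) / semi^2 <= 1
  expect_identical(sum(tpl$brain_mask), sum(inside))

  expect_error(make_template(grid_spec(c(2, 8, 8))), "degenerate")
  expect_error(make_template(g, baseline = 0), "baseline")
})

test_that("effect map follows the sphere lattice scan and the max-overlap rule", {
  g <- grid_spec(c(24, 24, 24))
  tpl <- make_template(g)

  expect_equal(effect_map(g, tpl$brain_mask, list()),
               array(0, dim = g$shape))

  # single sphere: nonzero support equals the brute-force ||x - c|| <= r scan
  cl <- cluster_spec(c(0, 0, 0), radius_mm = 6, effect_fraction = 0.2)
  eff <- effect_map(g, tpl$brain_mask, list(cl))
  coords <- as.matrix(expand.grid(1:24, 1:24, 1:24))
  mm <- voxel_to_mm(g, coords)
  inside <- sqrt(rowSums(mm^2)) <= 6
  expect_identical(which(eff != 0), which(inside & tpl$brain_mask))
  expect_true(all(eff[eff != 0] == 0.2))

  # overlapping spheres: max, not sum
  cl1 <- cluster_spec(c(0, 0, 0), 8, 0.1)
  cl2 <- cluster_spec(c(4, 0, 0), 8, 0.3)
  eff2 <- effect_map(g, tpl$brain_mask, list(cl1, cl2))
  overlap <- effect_map(g, tpl$brain_mask, list(cl1)) > 0 &
    effect_map(g, tpl$brain_mask, list(cl2)) > 0
  expect_true(all(eff2[overlap] == 0.3))
  expect_true(max(eff2) <= 0.3)

  # a sphere entirely outside the brain warns but does not error
  expect_warning(
    effect_map(g, tpl$brain_mask,
               list(cluster_spec(c(200, 200, 200), 4, 0.5))),
    "outside")
})

test_that("subject simulation has the stated closed forms when randomness is off", {
  g <- grid_spec(c(16, 16, 16))
  tpl <- make_template(g, baseline = 100)
  spec <- cohort_spec(n_disease = 2, n_healthy = 2, noise_sd = 0,
                      global_scale_sd = 0, age_slope = 0,
                      clusters = list(cluster_spec(c(0, 0, 0), 6, 0.2)),
                      seed = 1)
  eff <- effect_map(g, tpl$brain_mask, spec$clusters)

  dis <- simulate_subject(tpl, eff, "disease", age = 40, spec)
  expect_equal(unique(dis$volume[eff > 0]), 0.8 * 100)
  expect_equal(unique(dis$volume[tpl$brain_mask & eff == 0]), 100)

  hea <- simulate_subject(tpl, eff, "healthy", age = 40, spec)
  expect_equal(hea$volume, tpl$volume)
  expect_true(all(dis$volume[!tpl$brain_mask] == 0))
})

test_that("age acts additively through the centred slope", {
  g <- grid_spec(c(8, 8, 8))
  tpl <- make_template(g, baseline = 100)
  spec <- cohort_spec(n_disease = 1, n_healthy = 1, noise_sd = 0,
                      global_scale_sd = 0, age_slope = -0.5,
                      age_mean_disease = 50, age_mean_healthy = 50,
                      clusters = list(), seed = 1)
  eff <- effect_map(g, tpl$brain_mask, list())
  s60 <- simulate_subject(tpl, eff, "healthy", age = 60, spec)
  s40 <- simulate_subject(tpl, eff, "healthy", age = 40, spec)
  expect_equal(unique(s60$volume[tpl$brain_mask] - s40$volume[tpl$brain_mask]),
               -0.5 * 20)
})

test_that("cohort generation yields the configured sizes and is seed-reproducible", {
  g <- small_grid(c(12, 12, 12))
  spec_tr <- cohort_spec(n_disease = 100, n_healthy = 44, clusters = list(),
                         seed = 7)
  co <- generate_cohort(spec_tr, g)
  expect_equal(nrow(co$manifest), 144)
  expect_equal(sum(co$manifest$group == "disease"), 100)

  spec_te <- cohort_spec(n_disease = 19, n_healthy = 20, clusters = list(),
                         seed = 8)
  expect_equal(nrow(generate_cohort(spec_te, g)$manifest), 39)

  co2 <- generate_cohort(spec_tr, g)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$subjects[[5]]$volume, co2$subjects[[5]]$volume)
  expect_true(all(co$manifest$age >= 18 & co$manifest$age <= 90))

  expect_error(cohort_spec(n_disease = 5, n_healthy = 5), "seed")
})

test_that("planted effects calibrate: group difference matches baseline * effect", {
  # low noise so 3 standard errors is a tight band
  co <- quick_cohort(50, 50, effect = 0.2, seed = 31, noise_sd = 1,
                     radius_mm = 8, shape = c(24, 24, 24),
                     global_scale_sd = 0, age_slope = 0)
  ctr <- round(mm_to_voxel(co$grid, c(0, 0, 0)))
  vals <- vapply(co$subjects, function(s) s$volume[ctr[1], ctr[2], ctr[3]],
                 numeric(1))
  dis <- vals[co$manifest$group == "disease"]
  hea <- vals[co$manifest$group == "healthy"]
  se <- sqrt(stats::var(dis) / length(dis) + stats::var(hea) / length(hea))
  expect_lt(abs((mean(hea) - mean(dis)) - 100 * 0.2), 3 * se)

  # a voxel well outside the planted sphere shows no group difference
  far <- round(mm_to_voxel(co$grid, c(14, 0, 0)))
  vals0 <- vapply(co$subjects, function(s) s$volume[far[1], far[2], far[3]],
                  numeric(1))
  d0 <- vals0[co$manifest$group == "disease"]
  h0 <- vals0[co$manifest$group == "healthy"]
  se0 <- sqrt(stats::var(d0) / length(d0) + stats::var(h0) / length(h0))
  expect_lt(abs(mean(h0) - mean(d0)), 3 * se0)
})

test_that("cohorts write a manifest and NIfTI volumes that read back", {
  co <- quick_cohort(2, 2, effect = 0.1, seed = 5, shape = c(8, 8, 8))
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(all(file.exists(man$path)))
  tsv <- read.delim(file.path(dir, "manifest.tsv"))
  expect_identical(names(tsv), c("subject_id", "group", "age", "path"))
  back <- read_volume(man$path[1])
  expect_equal(back$volume, co$subjects[[1]]$volume, tolerance = 1e-6)
})
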