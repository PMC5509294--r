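test_that("design matrix has the specified columns, centring and contrast", {
  co <- quick_cohort(3, 3, effect = 0, seed = 2, shape = c(6, 6, 6))
  d <- build_design(co)
  expect_equal(dim(d$X), c(6, 3))
  expect_identical(colnames(d$X), c("intercept", "group_healthy", "age_centered"))
  expect_equal(mean(d$X[, "age_centered"]), 0, tolerance = 1e-12)
  # contrast selects the group column only
  expect_equal(d$contrast[colnames(d$X) == "group_healthy"], 1)
  expect_equal(sum(abs(d$contrast[colnames(d$X) != "group_healthy"])), 0)

  # all-equal ages: covariate dropped with a warning, design still full rank
  co$manifest$age <- rep(50, 6)
  expect_warning(d2 <- build_design(co), "constant")
  expect_equal(ncol(d2$X), 2)

  co_one <- co
  co_one$manifest$group <- rep("disease", 6)
  expect_error(build_design(co_one), "both groups")
})

test_that("intercept-only voxel-wise GLM reduces to the pooled two-sample t", {
  # the worked example: disease {1,2,3} vs healthy {4,5,6} at one voxel
  vals <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  co <- value_cohort(vals, rep(c("disease", "healthy"), each = 3))
  d <- build_design(co, covariates = character())
  sm <- fit_voxelwise_glm(co, d)
  expect_equal(sm$df, 4)
  expect_equal(sm$t[1], 3 / sqrt((2 / 3)), tolerance = 1e-8)  # 3.674
  expect_equal(sm$t[1], pooled_t(c(4, 5, 6), c(1, 2, 3)), tolerance = 1e-10)
  expect_equal(sm$p[1], pt(sm$t[1], 4, lower.tail = FALSE))

  # identical values in both groups: t = 0, p = 0.5
  co0 <- value_cohort(matrix(rep(2, 6), ncol = 1),
                      rep(c("disease", "healthy"), each = 3))
  sm0 <- fit_voxelwise_glm(co0, build_design(co0, covariates = character()))
  expect_equal(sm0$t[1], 0)
  expect_equal(sm0$p[1], 0.5)
})

test_that("voxel-wise t matches the closed-form pooled t on many random cohorts", {
  set.seed(404)
  for (rep_i in 1:25) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    vals <- matrix(rnorm((n1 + n2) * 10, 50, 8), nrow = n1 + n2)
    co <- value_cohort(vals, rep(c("disease", "healthy"), c(n1, n2)),
                       shape = c(4, 4, 4))
    sm <- fit_voxelwise_glm(co, build_design(co, covariates = character()))
    for (v in 1:10) {
      expect_equal(sm$t[v],
                   pooled_t(vals[-(1:n1), v], vals[1:n1, v]),
                   tolerance = 1e-8)
    }
  }
})

test_that("age adjustment residualizes an age-driven voxel to t ~ 0", {
  set.seed(11)
  n <- 20
  ages <- seq(30, 68, length.out = n)
  groups <- rep(c("disease", "healthy"), each = n / 2)
  # voxel value is a pure linear function of age: after adjustment the
  # group effect must vanish
  vals <- matrix(100 - 0.8 * ages, ncol = 1)
  co <- value_cohort(vals, groups, ages = ages)
  sm <- fit_voxelwise_glm(co, build_design(co))
  expect_lt(abs(sm$t[1]), 1e-6)
})

test_that("age-adjusted group t equals the residualized-regression oracle", {
  set.seed(12)
  n <- 24
  ages <- rnorm(n, 50, 10)
  groups <- rep(c("disease", "healthy"), each = n / 2)
  y <- rnorm(n, 100, 5) - 0.5 * ages + 3 * (groups == "healthy")
  co <- value_cohort(matrix(y, ncol = 1), groups, ages = ages)
  sm <- fit_voxelwise_glm(co, build_design(co))
  fit <- stats::lm(y ~ I(groups == "healthy") + I(ages - mean(ages)))
  tt <- summary(fit)$coefficients[2, "t value"]
  expect_equal(sm$t[1], tt, tolerance = 1e-8)
  expect_equal(sm$df, n - 3)
})

test_that("all-zero voxel series get the t = 0, p = 1 convention and finite z", {
  vals <- cbind(c(1, 2, 3, 4, 5, 6), 0)
  co <- value_cohort(vals, rep(c("disease", "healthy"), each = 3))
  co$subjects <- lapply(co$subjects, function(s) { s$volume[2] <- 0; s })
  sm <- fit_voxelwise_glm(co, build_design(co, covariates = character()))
  expect_equal(sm$t[2], 0)
  expect_equal(sm$p[2], 1)
  expect_true(is.finite(sm$z[2]))
})

test_that("the voxel threshold is strictly below p_voxel", {
  co <- quick_cohort(5, 5, effect = 0, seed = 14, shape = c(6, 6, 6),
                     noise_sd = 5)
  sm <- fit_voxelwise_glm(co, build_design(co))
  # plant exact boundary p-values
  idx <- which(co$brain_mask)[1:3]
  sm$p[idx] <- c(0.005, 0.0049999, 0.0050001)
  supra <- threshold_voxels(sm, 0.005)
  expect_identical(as.logical(supra[idx]), c(FALSE, TRUE, FALSE))

  # the t just above the one-sided critical value is included
  df <- 142
  tcrit <- qt(0.005, df, lower.tail = FALSE)
  p_above <- pt(tcrit + 1e-6, df, lower.tail = FALSE)
  sm$p[idx[1]] <- p_above
  expect_true(threshold_voxels(sm, 0.005)[idx[1]])
})

test_that("cluster labelling matches the scalar flood-fill oracle on handcrafted cases", {
  a <- array(0, dim = c(5, 5, 5))
  a[1, 1, 1] <- 1
  a[2, 1, 1] <- 1           # face neighbour -> same cluster
  lab <- label_clusters(a, 18)
  expect_equal(max(lab), 1)
  expect_equal(sum(lab == 1), 2)

  b <- array(0, dim = c(5, 5, 5))
  b[1, 1, 1] <- 1
  b[2, 2, 2] <- 1           # corner-only contact
  expect_equal(max(label_clusters(b, 18)), 2)  # separate under 18
  expect_equal(max(label_clusters(b, 26)), 1)  # joined under 26

  e <- array(0, dim = c(4, 4, 4))
  expect_equal(max(label_clusters(e, 18)), 0)

  c2 <- array(0, dim = c(5, 5, 5))
  c2[1, 1, 1] <- 1
  c2[2, 2, 1] <- 1          # edge contact
  expect_equal(max(label_clusters(c2, 6)), 2)   # separate under 6
  expect_equal(max(label_clusters(c2, 18)), 1)  # joined under 18
})

test_that("cluster labelling agrees with the flood-fill oracle on random volumes", {
  set.seed(77)
  for (i in 1:12) {
    vol <- array(runif(10^3) < 0.45, dim = c(10, 10, 10))
    for (conn in c(6, 18, 26)) {
      got <- canonical_labels(label_clusters(vol, conn))
      ref <- canonical_labels(flood_fill_labels(vol, conn))
      expect_identical(got, ref)
    }
  }
})

test_that("extent threshold is inclusive at k_min and reports peaks in mm", {
  g <- grid_spec(c(12, 12, 12))
  co <- quick_cohort(4, 4, effect = 0, seed = 3, shape = c(12, 12, 12))
  sm <- fit_voxelwise_glm(co, build_design(co))

  # synthetic label field: one cluster of 199 voxels, one of 200
  labels <- array(0L, dim = g$shape)
  labels[1:199] <- 1L
  labels[1000 + 1:200] <- 2L
  sm$t[labels > 0] <- runif(399, 1, 5)
  peak_vox <- 1000 + 57
  sm$t[peak_vox] <- 9.9
  sm$p[labels > 0] <- 1e-4

  cm199 <- apply_extent_threshold(labels, sm, k_min = 200)
  expect_equal(nrow(cm199$report), 1)
  expect_equal(cm199$report$K, 200)
  expect_equal(cm199$report$peak_t, 9.9)
  expect_equal(unname(c(cm199$report$peak_x_mm, cm199$report$peak_y_mm,
                        cm199$report$peak_z_mm)),
               unname(voxel_to_mm(g, as.numeric(arrayInd(peak_vox, g$shape)))))

  cm150 <- apply_extent_threshold(labels, sm, k_min = 150)
  expect_equal(nrow(cm150$report), 2)
  # report sorted by descending extent
  expect_identical(cm150$report$K, sort(cm150$report$K, decreasing = TRUE))

  expect_warning(empty <- apply_extent_threshold(labels, sm, k_min = 500),
                 "no cluster")
  expect_equal(sum(empty$mask), 0)
})

test_that("planted-sphere recovery reports K equal to the flood-fill count", {
  co <- quick_cohort(25, 25, effect = 0.3, seed = 55, noise_sd = 10,
                     radius_mm = 8, shape = c(20, 20, 20))
  pp <- preprocess_cohort(co, fwhm_mm = 0, target_mean = 50)
  sm <- fit_voxelwise_glm(pp, build_design(pp))
  supra <- threshold_voxels(sm, 0.005)
  labels <- label_clusters(supra, 18)
  cm <- apply_extent_threshold(labels, sm, k_min = 100)
  expect_gte(nrow(cm$report), 1)
  ref <- flood_fill_labels(supra, 18)
  ref_sizes <- sort(tabulate(ref[ref > 0]), decreasing = TRUE)
  expect_equal(cm$report$K[1], ref_sizes[1])
})

test_that("mask shrinks monotonically as thresholds tighten", {
  co <- quick_cohort(20, 20, effect = 0.25, seed = 91, noise_sd = 10,
                     radius_mm = 10, shape = c(20, 20, 20))
  pp <- preprocess_cohort(co, fwhm_mm = 0, target_mean = 50)
  sm <- fit_voxelwise_glm(pp, build_design(pp))
  masks <- lapply(c(0.01, 0.005, 0.001), function(p) {
    labels <- label_clusters(threshold_voxels(sm, p), 18)
    apply_extent_threshold(labels, sm, k_min = 50)$mask
  })
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))
  labels <- label_clusters(threshold_voxels(sm, 0.005), 18)
  m_k50 <- apply_extent_threshold(labels, sm, k_min = 50)$mask
  m_k200 <- apply_extent_threshold(labels, sm, k_min = 200)$mask
  expect_true(all(m_k200 <= m_k50))
})
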