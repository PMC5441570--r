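test_that("pooled t-test matches stats::t.test and the sign convention", {
  x <- matrix(c(1, 2, 3, 4, 3, 4, 5, 6), ncol = 1)
  grp <- c(rep("control", 4), rep("patient", 4))
  res <- univariate_ttest(x, grp)
  oracle <- t.test(x[5:8], x[1:4], var.equal = TRUE)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(res$t, 2.19089, tolerance = 1e-4)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-10)
  expect_equal(res$p, 0.0710, tolerance = 1e-3)
  expect_gt(res$t, 0)  # positive t <=> patient mean above control mean

  # identical groups: t = 0, p = 1
  x0 <- matrix(rep(c(1, 2, 3), 2), ncol = 1)
  res0 <- univariate_ttest(x0, c(rep("patient", 3), rep("control", 3)))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  # label swap flips t, keeps p
  swapped <- univariate_ttest(x, ifelse(grp == "patient", "control", "patient"))
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)

  expect_error(univariate_ttest(x, c("patient", rep("control", 7))),
               "at least 2")
})

test_that("zero pooled variance is handled as a degenerate contract", {
  x <- matrix(c(1, 1, 1, 2, 2, 2, 5, 5, 5, 5, 5, 5), ncol = 2)
  grp <- c(rep("patient", 3), rep("control", 3))
  res <- univariate_ttest(x, grp)
  expect_true(res$degenerate[1])
  expect_equal(res$p[1], 0)  # means differ, no variance
  expect_true(res$degenerate[2])
  expect_equal(res$p[2], 1)  # identical constants
})

test_that("vectorized t-tests agree with per-column t.test on random data", {
  set.seed(31)
  x <- matrix(rnorm(40 * 25), 40)
  grp <- rep(c("patient", "control"), each = 20)
  res <- univariate_ttest(x, grp)
  for (j in c(1, 7, 25)) {
    o <- t.test(x[grp == "patient", j], x[grp == "control", j],
                var.equal = TRUE)
    expect_equal(res$t[j], unname(o$statistic), tolerance = 1e-10)
    expect_equal(res$p[j], o$p.value, tolerance = 1e-10)
  }
})

test_that("Bonferroni mask uses the strict alpha/m rule", {
  expect_true(bonferroni_mask(4e-4, alpha = 0.05, m = 100))
  expect_false(bonferroni_mask(6e-4, alpha = 0.05, m = 100))
  expect_equal(bonferroni_mask(c(0.04, 0.06), alpha = 0.05, m = 1),
               c(TRUE, FALSE))
})

test_that("BH step-up matches the hand-computed rejection set", {
  p <- c(0.01, 0.02, 0.04, 0.5)
  expect_equal(bh_fdr_mask(p, 0.05), c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(bh_fdr_mask(rep(1, 10), 0.05)))
  expect_true(all(bh_fdr_mask(rep(0, 10), 0.05)))
})

test_that("Bonferroni survivors are always a subset of FDR survivors", {
  set.seed(12)
  for (i in 1:20) {
    p <- runif(50)^sample(1:4, 1)
    bon <- bonferroni_mask(p, 0.05)
    fdr <- bh_fdr_mask(p, 0.05)
    expect_true(all(fdr[bon]))
  }
})

test_that("stable Bonferroni set is the intersection across folds", {
  mk <- function(idx, m = 10) { v <- rep(FALSE, m); v[idx] <- TRUE; v }
  expect_equal(stable_bonferroni(list(mk(1:3), mk(2:4), mk(2:3))), c(2L, 3L))
  expect_equal(stable_bonferroni(list(mk(1:2), mk(3:4))), integer(0))
  expect_equal(stable_bonferroni(list(mk(c(1, 5)))), c(1L, 5L))
  expect_error(stable_bonferroni(list()), "no folds")
})

test_that("residualization removes covariates exactly", {
  set.seed(5)
  n <- 50
  cov1 <- rnorm(n)
  x <- cbind(a = cov1 * 1.0, b = rnorm(n))
  res <- residualize_features(x, cbind(cov1))
  expect_true(all(abs(res[, "a"]) < 1e-10))  # feature equal to covariate

  # residuals orthogonal to every covariate column (normal-equations oracle)
  covs <- cbind(rnorm(n), rnorm(n))
  xr <- matrix(rnorm(n * 8), n)
  r <- residualize_features(xr, covs)
  expect_true(all(abs(crossprod(covs, r)) < 1e-8))
  expect_true(all(abs(colSums(r)) < 1e-8))

  # orthogonal covariate leaves the feature unchanged up to mean removal
  f <- rnorm(n); f <- f - mean(f)
  c_orth <- rnorm(n); c_orth <- c_orth - mean(c_orth)
  c_orth <- c_orth - f * sum(c_orth * f) / sum(f^2)
  r2 <- residualize_features(matrix(f), cbind(c_orth))
  expect_equal(r2[, 1], f, tolerance = 1e-8)

  # rank-deficient design drops the redundant column with a warning
  expect_warning(residualize_features(xr, cbind(covs, covs[, 1])),
                 "redundant")
})

test_that("feature QC reports sigma-bar summaries and calibrated KS tests", {
  set.seed(77)
  x <- matrix(rnorm(60 * 30), 60)
  grp <- rep(c("patient", "control"), each = 30)
  qc <- feature_qc(x, grp)
  expect_equal(nrow(qc$sigma_bar), 2)
  expect_true(all(abs(qc$sigma_bar$mean_sd - 1) < 0.15))

  # identical groups give equal summaries
  x2 <- rbind(x[1:30, ], x[1:30, ])
  qc2 <- feature_qc(x2, grp)
  expect_equal(qc2$sigma_bar$mean_sd[1], qc2$sigma_bar$mean_sd[2])

  # Gaussian data: KS rejections near (below, Lilliefors-conservative) alpha
  x3 <- matrix(rnorm(200 * 100), 200)
  qc3 <- feature_qc(x3, rep(c("patient", "control"), each = 100))
  frac <- mean(qc3$ks$ks_p < 0.05)
  expect_lt(frac, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200))
})

test_that("type-I error is calibrated on the synthetic null cohort", {
  # delta_r = 0, independent supervoxel signals: fraction of p < 0.05
  # within the 99% binomial CI around 0.05 over 496 link features
  cfg <- synth_config(n_sites = 2, patients_per_site = 10,
                      controls_per_site = 10, runs_per_subject = 2,
                      grid_dims = c(8, 8, 4), block_dims = c(2, 2, 2),
                      t_points = 137, base_corr = 0, delta_r = 0,
                      planted_links = matrix(integer(0), 0, 2),
                      scale_weights = numeric(0), subject_link_sd = 0,
                      site_common_sd = 0, seed = 55)
  co <- generate_cohort(cfg)
  fm <- extract_features(co, "ss_link_weight", block_dims = c(2, 2, 2))
  res <- univariate_ttest(fm)
  m <- nrow(res)
  expect_gte(m, 200)
  frac <- mean(res$p < 0.05)
  half <- 2.576 * sqrt(0.05 * 0.95 / m)
  expect_gt(frac, 0.05 - half)
  expect_lt(frac, 0.05 + half)
})

test_that("planted links survive Bonferroni while null links do not", {
  co <- generate_cohort(effect_cfg(seed = 3))
  fm <- extract_features(co, "ss_link_weight", block_dims = c(2, 2, 2))
  res <- univariate_ttest(fm)
  cfg <- effect_cfg()
  idx <- pair_index(cfg$planted_links[, 1], cfg$planted_links[, 2], 8)
  expect_true(all(res$bonferroni[idx]))
})
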