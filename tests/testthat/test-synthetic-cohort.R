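test_that("config validation rejects impossible correlation structures", {
  expect_error(tiny_cfg(base_corr = 0.8, delta_r = 0.3), "below 1")
  expect_error(tiny_cfg(planted_links = rbind(c(1, 99))), "planted_links")
  expect_error(tiny_cfg(planted_links = rbind(c(2, 2))), "planted_links")
  expect_error(tiny_cfg(runs_per_subject = 0))
  expect_error(tiny_cfg(patients_per_site = c(3, 3, 3)), "length-n_sites")
})

test_that("group covariance is compound-symmetric with planted patient increments", {
  cfg <- tiny_cfg(base_corr = 0.2, delta_r = 0.3,
                  planted_links = rbind(c(1, 2)), scale_weights = 1)
  ctrl <- generate_cov_structure(cfg, "control")
  pat <- generate_cov_structure(cfg, "patient")
  expect_equal(pat[1, 2], 0.5)
  expect_equal(pat[2, 1], 0.5)
  off <- pat[upper.tri(pat)]
  expect_equal(sum(abs(off - 0.5) < 1e-12), 1)   # only the planted link
  expect_equal(sum(abs(off - 0.2) < 1e-12), length(off) - 1)
  expect_equal(diag(pat), rep(1, 8))

  # zero effect: groups identical
  cfg0 <- tiny_cfg(delta_r = 0)
  expect_identical(generate_cov_structure(cfg0, "patient"),
                   generate_cov_structure(cfg0, "control"))
})

test_that("covariance matrices are positive semi-definite across configs", {
  # eigen-decomposition oracle over a range of effect sizes
  for (d in c(0, 0.2, 0.4, 0.6)) {
    for (b in c(0, 0.1, 0.3)) {
      if (b + d >= 1) next
      cfg <- tiny_cfg(base_corr = b, delta_r = d,
                      planted_links = rbind(c(1, 2), c(1, 3), c(2, 3)),
                      scale_weights = c(1, 1, 1))
      m <- generate_cov_structure(cfg, "patient")
      expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-8)
    }
  }
})

test_that("generated runs reproduce the requested instantaneous correlation", {
  # identity covariance: off-diagonal sample correlations behave as null
  # Fisher-z normal approximation oracle: |r| < 4/sqrt(T) for >= 99% of pairs
  cfg <- tiny_cfg(base_corr = 0, within_share = 1, t_points = 500,
                  site_common_sd = 0)
  run <- generate_run(cfg, diag(8), seed = 11)
  sv <- build_supervoxels(run, c(2, 2, 2))
  cm <- correlation_matrix(sv$series)
  offdiag <- abs(cm[upper.tri(cm)])
  expect_gte(mean(offdiag < 4 / sqrt(500)), 0.99)
  expect_lt(mean(offdiag), 0.1)

  # strong correlation recovered: r = 0.9, T = 2000
  cov <- diag(8); cov[1, 2] <- cov[2, 1] <- 0.9
  cfg2 <- tiny_cfg(within_share = 1, t_points = 2000, site_common_sd = 0)
  run2 <- generate_run(cfg2, cov, seed = 12)
  sv2 <- build_supervoxels(run2, c(2, 2, 2))
  r_hat <- correlation_matrix(sv2$series)[1, 2]
  expect_lt(abs(r_hat - 0.9), 0.05)
})

test_that("run generation is deterministic given a seed", {
  cfg <- tiny_cfg()
  cov <- generate_cov_structure(cfg, "patient")
  r1 <- generate_run(cfg, cov, seed = 5)
  r2 <- generate_run(cfg, cov, seed = 5)
  expect_identical(r1, r2)
  expect_error(generate_run(cfg, matrix(c(1, 2, 2, 1), 2), seed = 1),
               "positive semi-definite")
})

test_that("scale scores are integers in 0..5 and degenerate latents hit mid-range", {
  cfg <- tiny_cfg(scale_weights = c(0, 0, 0), scale_noise_sd = 0)
  sc <- generate_scales(c(0.3, 0.4, 0.2), cfg, seed = 1)
  expect_true(all(sc == 3L))

  cfg2 <- tiny_cfg(scale_noise_sd = 2)
  for (s in 1:20) {
    sc <- generate_scales(runif(3, -1, 1), cfg2, seed = s)
    expect_true(all(sc %in% 0:5))
  }
})

test_that("scales track the planted link weights (Spearman recovery)", {
  # simulation oracle: strong weight on one link, low noise, n = 60 patients
  cfg <- synth_config(n_sites = 1, patients_per_site = 60,
                      controls_per_site = 2, runs_per_subject = 4,
                      grid_dims = c(4, 4, 4), block_dims = c(2, 2, 2),
                      t_points = 137, planted_links = rbind(c(1, 2)),
                      scale_weights = matrix(1, 9, 1), scale_noise_sd = 0.01,
                      n_scales = 9, seed = 33)
  co <- generate_cohort(cfg)
  fm <- extract_features(co, "link_weight", block_dims = c(2, 2, 2))
  idx <- pair_index(1, 2, 8)
  subj <- unique(co$samples$subject_id[co$samples$group == "patient"])
  lw <- vapply(subj, function(s)
    mean(fm$values[co$samples$subject_id == s, idx]), numeric(1))
  sc <- vapply(subj, function(s)
    co$samples$scale_1[co$samples$subject_id == s][1], numeric(1))
  expect_gt(cor(lw, sc, method = "spearman"), 0.5)
})

test_that("cohort counts, metadata consistency, and determinism hold", {
  co <- tiny_cohort()
  cfg <- tiny_cfg()
  n_subj <- sum(cfg$patients_per_site) + sum(cfg$controls_per_site)
  expect_equal(nrow(co$samples), n_subj * cfg$runs_per_subject)
  expect_equal(length(co$runs), nrow(co$samples))

  # all runs of a subject share site, group, and scales
  meta_cols <- setdiff(names(co$samples), "run_id")
  per_subj <- vapply(split(co$samples[meta_cols], co$samples$subject_id),
                     function(d) nrow(unique(d)), integer(1))
  expect_true(all(per_subj == 1))

  # patient scales present and in range; control scales missing
  pat <- co$samples$group == "patient"
  expect_true(all(co$samples$scale_1[pat] %in% 0:5))
  expect_true(all(is.na(co$samples$scale_1[!pat])))

  co2 <- generate_cohort(tiny_cfg())
  expect_identical(co$samples, co2$samples)
  expect_identical(co$runs[[7]], co2$runs[[7]])
})

test_that("two subjects with four runs yield eight samples", {
  cfg <- synth_config(n_sites = 1, patients_per_site = 1,
                      controls_per_site = 1, runs_per_subject = 4,
                      grid_dims = c(4, 4, 2), block_dims = c(2, 2, 1),
                      t_points = 30, planted_links = rbind(c(1, 2)),
                      scale_weights = 1, seed = 2)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$samples), 8)
  expect_equal(length(unique(co$samples$subject_id)), 2)
})

test_that("planted hyperconnectivity raises patient link-weights", {
  # recovery direction across seeds
  hits <- vapply(1:5, function(s) {
    co <- generate_cohort(effect_cfg(seed = s))
    fm <- extract_features(co, "link_weight", block_dims = c(2, 2, 2))
    idx <- pair_index(effect_cfg()$planted_links[, 1],
                      effect_cfg()$planted_links[, 2], 8)
    pat <- fm$samples$group == "patient"
    all(colMeans(fm$values[pat, idx, drop = FALSE]) >
          colMeans(fm$values[!pat, idx, drop = FALSE]))
  }, logical(1))
  expect_true(all(hits))
})
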