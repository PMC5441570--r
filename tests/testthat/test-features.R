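test_that("correlation_matrix matches hand-computed Pearson values", {
  m <- rbind(c(1, 2, 3), c(3, 2, 1))
  cm <- correlation_matrix(m)
  expect_equal(cm[1, 2], -1)
  expect_equal(diag(cm), c(1, 1))

  m2 <- rbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4))
  expect_equal(correlation_matrix(m2)[1, 2], 0.8)

  expect_equal(correlation_matrix(rbind(1:3, 1:3))[1, 2], 1)
  expect_error(correlation_matrix(rbind(c(1, 2), c(2, 1))), "3 time points")
})

test_that("constant series get correlation 0 and are flagged", {
  m <- rbind(c(5, 5, 5, 5), c(1, 2, 3, 4))
  cm <- correlation_matrix(m)
  expect_equal(cm[1, 2], 0)
  expect_equal(diag(cm), c(1, 1))
  expect_equal(attr(cm, "constant_nodes"), 1L)
})

test_that("correlation agrees with stats::cor on random input", {
  set.seed(4)
  m <- matrix(rnorm(10 * 50), 10)
  expect_equal(unname(correlation_matrix(m))[1:10, ], unname(cor(t(m))),
               tolerance = 1e-12)
})

test_that("thresholding is strict and signed", {
  cm <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_equal(sum(threshold_network(cm, 0.7)$adjacency) / 2, 1)
  cm2 <- matrix(c(1, 0.7, 0.7, 1), 2)
  expect_equal(sum(threshold_network(cm2, 0.7)$adjacency), 0)
  expect_equal(sum(threshold_network(diag(5), 0.5)$adjacency), 0)
  # signed: strong negative correlation is not a link unless absolute
  cm3 <- matrix(c(1, -0.9, -0.9, 1), 2)
  expect_equal(sum(threshold_network(cm3, 0.7)$adjacency), 0)
  expect_equal(sum(threshold_network(cm3, 0.7, absolute = TRUE)$adjacency) / 2,
               1)
  expect_error(threshold_network(cm, 1.5), "\\[-1, 1\\]")
})

test_that("degrees equal adjacency row sums and sum to twice the links", {
  # complete graph and path graph
  full <- matrix(0.9, 4, 4); diag(full) <- 1
  expect_equal(degrees(threshold_network(full, 0.7)), rep(3L, 4))
  path <- diag(3); path[1, 2] <- path[2, 1] <- 0.8; path[2, 3] <- path[3, 2] <- 0.8
  expect_equal(degrees(threshold_network(path, 0.7)), c(1L, 2L, 1L))

  # brute-force row-sum oracle on a random 20-node matrix
  set.seed(9)
  z <- matrix(rnorm(20 * 30), 20)
  net <- threshold_network(correlation_matrix(z), 0.2)
  expect_equal(degrees(net), as.integer(rowSums(net$adjacency)))
  # degree sum = 2 x link count
  expect_equal(sum(degrees(net)), 2L * sum(net$adjacency[upper.tri(net$adjacency)]))
})

test_that("log_degree is log10(d + 1) and strictly increasing", {
  expect_equal(log_degree(0), 0)
  expect_equal(log_degree(9), 1)
  expect_equal(log_degree(99), 2)
  expect_true(all(diff(log_degree(0:50)) > 0))
  expect_error(log_degree(-1), "non-negative")
})

test_that("tiled degree accumulation equals the full-matrix computation", {
  set.seed(21)
  ts <- matrix(rnorm(60 * 40), 60)
  ts[13, ] <- 7  # constant row
  for (c in c(0.2, 0.5, -0.1)) {
    naive <- degrees(threshold_network(correlation_matrix(ts), c))
    expect_equal(degrees_tiled(ts, c, tile_size = 7), naive)
  }
  expect_equal(degrees_tiled(ts, 0.3, absolute = TRUE, tile_size = 11),
               degrees(threshold_network(correlation_matrix(ts), 0.3,
                                         absolute = TRUE)))
})

test_that("supervoxel aggregation averages in-mask members per block", {
  run <- generate_run(tiny_cfg(), diag(8), seed = 3)
  sv <- build_supervoxels(run, c(2, 2, 2))
  expect_equal(nrow(sv$series), 8)
  expect_equal(sv$grid_dims, c(2L, 2L, 2L))

  # identical member series: supervoxel series equals it
  run2 <- run
  run2$series <- matrix(rep(sin(1:60), each = 64), 64, byrow = FALSE)
  sv2 <- build_supervoxels(run2, c(2, 2, 2))
  expect_equal(sv2$series[1, ], sin(1:60))

  # masked members are excluded from the mean
  run3 <- run
  run3$mask[] <- FALSE
  run3$mask[1:2, 1, 1] <- TRUE
  keep <- run$node_coords[, 1] %in% 0:1 & run$node_coords[, 2] == 0 &
    run$node_coords[, 3] == 0
  run3$node_coords <- run$node_coords[keep, , drop = FALSE]
  run3$series <- matrix(c(rep(1, 60), rep(3, 60)), 2, byrow = TRUE)
  sv3 <- build_supervoxels(run3, c(2, 2, 2), min_fill = 0.2)
  expect_equal(nrow(sv3$series), 1)
  expect_equal(sv3$series[1, ], rep(2, 60))

  # empty mask errors; low-fill blocks are dropped
  run4 <- run3; run4$mask[] <- FALSE
  run4$node_coords <- run$node_coords[0, , drop = FALSE]
  expect_error(build_supervoxels(run4, c(2, 2, 2)), "mask")
  expect_error(build_supervoxels(run3, c(2, 2, 2), min_fill = 0.5),
               "min_fill")
})

test_that("an 8x8x6 grid with 4x4x3 blocks yields 8 supervoxels", {
  cfg <- synth_config(grid_dims = c(8, 8, 6), block_dims = c(4, 4, 3),
                      planted_links = rbind(c(1, 2)), scale_weights = 1,
                      t_points = 30, n_sites = 1, patients_per_site = 1,
                      controls_per_site = 1, seed = 1)
  run <- generate_run(cfg, generate_cov_structure(cfg, "control"), seed = 1)
  sv <- build_supervoxels(run, c(4, 4, 3))
  expect_equal(nrow(sv$series), 8)
})

test_that("link-weight features enumerate the upper triangle in canonical order", {
  set.seed(2)
  cm <- correlation_matrix(matrix(rnorm(4 * 30), 4))
  lw <- link_weight_features(cm)
  expect_equal(length(lw$values), 6)
  expect_equal(lw$pairs[, 1], c(1L, 1L, 1L, 2L, 2L, 3L))
  expect_equal(lw$pairs[, 2], c(2L, 3L, 4L, 3L, 4L, 4L))
  expect_equal(lw$values, cm[cbind(lw$pairs[, 1], lw$pairs[, 2])])
  expect_equal(length(link_weight_features(diag(2))$values), 1)
  # n(n-1)/2 scaling, including the whole-brain supervoxel count
  expect_equal(nrow(connstab:::link_pairs(569)), 161596)
})

test_that("site standardization zeroes within-site means and unitizes SDs", {
  x <- matrix(c(1, 2, 3), 3, 1)
  z <- site_standardize(x, rep("a", 3))
  expect_equal(z[, 1], c(-1, 0, 1))

  # location shift per site leaves standardized values identical
  x2 <- rbind(x, x + 100)
  z2 <- site_standardize(x2, rep(c("a", "b"), each = 3))
  expect_equal(z2[1:3, 1], z2[4:6, 1])

  # direct recomputation oracle on random input
  set.seed(8)
  xr <- matrix(rnorm(40 * 15), 40)
  site <- rep(c("s1", "s2", "s3", "s4"), each = 10)
  zr <- site_standardize(xr, site)
  for (s in unique(site)) {
    sub <- zr[site == s, ]
    expect_true(all(abs(colMeans(sub)) < 1e-10))
    expect_true(all(abs(apply(sub, 2, sd) - 1) < 1e-10))
  }

  expect_error(site_standardize(xr, c("solo", site[-1])), "fewer than 2")

  # constant-within-site features become 0 and are flagged
  xc <- xr; xc[site == "s1", 3] <- 5
  zc <- site_standardize(xc, site)
  expect_true(all(zc[site == "s1", 3] == 0))
  flags <- attr(zc, "constant_flags")
  expect_equal(flags$feature, 3L)
  expect_equal(flags$site, "s1")
})

test_that("extract_features shapes, determinism, and ss typing", {
  co <- tiny_cohort()
  fm <- extract_features(co, "ss_link_weight", block_dims = c(2, 2, 2))
  expect_equal(dim(fm$values), c(nrow(co$samples), choose(8, 2)))
  expect_equal(fm$feature_type, "ss_link_weight")
  expect_true(all(c("node_i", "node_j") %in% names(fm$descriptors)))

  fm2 <- extract_features(co, "ss_link_weight", block_dims = c(2, 2, 2))
  expect_identical(fm$values, fm2$values)

  fmd <- extract_features(co, "log_degree", threshold = 0.4)
  expect_equal(ncol(fmd$values), 64)
  expect_true(all(c("x", "y", "z") %in% names(fmd$descriptors)))
  # log-degree values live on the log10(d+1) lattice
  expect_true(all(fmd$values %in% log_degree(0:63)))

  # inconsistent node sets across runs error
  co_bad <- co
  co_bad$runs[[2]]$node_coords <- co$runs[[2]]$node_coords[-1, ]
  expect_error(extract_features(co_bad, "ss_link_weight",
                                block_dims = c(2, 2, 2)), "inconsistent")
})

test_that("planted links have higher expected ss link-weight in patients", {
  fm <- tiny_linkfm()
  cfg <- tiny_cfg()
  idx <- pair_index(cfg$planted_links[, 1], cfg$planted_links[, 2], 8)
  pat <- fm$samples$group == "patient"
  expect_true(all(colMeans(fm$values[pat, idx, drop = FALSE]) >
                    colMeans(fm$values[!pat, idx, drop = FALSE])))
})
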