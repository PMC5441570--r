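# shared fixtures, generated in code and cached per test session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small fast configuration: 8 supervoxels of 8 voxels on a 4x4x4 grid
tiny_cfg <- function(...) {
  args <- modifyList(list(
    n_sites = 2, patients_per_site = 5, controls_per_site = 5,
    runs_per_subject = 2, grid_dims = c(4, 4, 4), block_dims = c(2, 2, 2),
    t_points = 60, seed = 101L), list(...))
  do.call(synth_config, args)
}

# planted-effect cohort at study-like conditions, desk scale:
# 20/20 subjects, T = 137, delta_r = 0.3
effect_cfg <- function(seed = 1L, ...) {
  args <- modifyList(list(
    n_sites = 2, patients_per_site = 10, controls_per_site = 10,
    runs_per_subject = 4, grid_dims = c(4, 4, 4), block_dims = c(2, 2, 2),
    t_points = 137, base_corr = 0.1, delta_r = 0.3, seed = seed), list(...))
  do.call(synth_config, args)
}

tiny_cohort <- function() cached("tiny_cohort", generate_cohort(tiny_cfg()))

tiny_linkfm <- function() cached("tiny_linkfm",
  extract_features(tiny_cohort(), "ss_link_weight", block_dims = c(2, 2, 2)))

# canonical feature index of supervoxel pair (i, j) among n supervoxels
pair_index <- function(i, j, n) {
  p <- t(apply(cbind(i, j), 1, sort))
  apply(p, 1, function(r) {
    (r[1] - 1) * n - r[1] * (r[1] - 1) / 2 + (r[2] - r[1])
  })
}
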