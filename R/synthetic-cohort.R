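#' Configuration for a synthetic multi-site fMRI cohort
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' generator emulates a multi-site case/control task-fMRI study: per-run
#' node-by-time BOLD-like series on a 3-D voxel grid, several acquisition
#' sites with batch effects, a fixed number of runs per subject, a set of
#' planted supervoxel-level links whose correlation is elevated in patients
#' (hyperconnectivity), and integer 0--5 symptom-severity scales generated
#' from a sparse linear function of the planted link-weights plus noise.
#'
#' The voxel grid of `grid_dims` is tiled (from the origin) into blocks of
#' `block_dims`; each block is a supervoxel and doubles as one latent signal
#' source. Every voxel's series is `sqrt(within_share)` times its
#' supervoxel's latent signal plus independent noise, so supervoxel-mean
#' series inherit the planted correlation structure with mild attenuation.
#'
#' Site ("batch") effects have three components, drawn once per site: a
#' per-node additive offset (`site_offset_sd`), a per-node multiplicative
#' gain (`exp(N(0, site_scale_sd))`), and a site-specific amplitude of a
#' per-run common-mode signal shared by all nodes (`site_common_sd`). The
#' affine components distort raw signal scale; the common-mode component
#' shifts within-site correlations, which is what makes within-site
#' standardization of correlation-derived features consequential.
#'
#' Patients additionally receive a per-subject Gaussian perturbation of the
#' planted-link correlations (`subject_link_sd`), giving the symptom scales
#' a true between-subject signal to encode.
#'
#' @param n_sites number of acquisition sites.
#' @param patients_per_site,controls_per_site subjects per site and group;
#'   a scalar (same at every site) or a length-`n_sites` vector. The
#'   defaults reproduce a 95-subject cohort (46 patients, 49 controls over
#'   five sites, 380 run samples).
#' @param runs_per_subject runs (samples) per subject.
#' @param grid_dims integer triple, voxel grid dimensions.
#' @param block_dims integer triple, supervoxel block dimensions.
#' @param t_points time points per run.
#' @param base_corr baseline correlation between supervoxel signals, in
#'   `[0, 1)`.
#' @param planted_links 2-column matrix of supervoxel index pairs (1-based)
#'   whose correlation is raised in patients.
#' @param delta_r correlation increment on planted links for patients
#'   (positive models hyperconnectivity); `base_corr + delta_r` must be
#'   below 1.
#' @param subject_link_sd SD of the per-patient perturbation of planted-link
#'   correlations.
#' @param within_share fraction of each voxel's variance carried by its
#'   supervoxel latent signal, in `(0, 1]`.
#' @param site_offset_sd,site_scale_sd,site_common_sd batch-effect
#'   magnitudes (see Details).
#' @param scale_weights coefficients mapping planted links to the latent
#'   symptom score: a vector of length `nrow(planted_links)` shared by all
#'   scales, or an `n_scales` x `nrow(planted_links)` matrix.
#' @param scale_noise_sd SD of the additive noise on the latent score.
#' @param n_scales number of symptom scales.
#' @param seed integer RNG seed; the whole cohort is a pure function of the
#'   configuration including this seed.
#'
#' @return A validated `synth_config` object (a list).
#' @export
synth_config <- function(n_sites = 5,
                         patients_per_site = c(10, 9, 9, 9, 9),
                         controls_per_site = c(10, 10, 10, 10, 9),
                         runs_per_subject = 4,
                         grid_dims = c(8, 8, 6),
                         block_dims = c(4, 4, 3),
                         t_points = 137,
                         base_corr = 0.1,
                         planted_links = rbind(c(1, 2), c(2, 7), c(3, 5)),
                         delta_r = 0.3,
                         subject_link_sd = 0.1,
                         within_share = 0.6,
                         site_offset_sd = 0.5,
                         site_scale_sd = 0.2,
                         site_common_sd = 0.15,
                         scale_weights = c(1, 0.8, 0.6),
                         scale_noise_sd = 0.05,
                         n_scales = 9,
                         seed = 1L) {
  stopifnot(is_count(n_sites), is_count(runs_per_subject), is_count(t_points),
            is_count(n_scales), t_points >= 3)
  expand <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, n_sites)
    if (length(x) != n_sites || any(x < 1) || any(x != floor(x)))
      stop(what, " must be a count or a length-n_sites vector of counts")
    as.integer(x)
  }
  patients_per_site <- expand(patients_per_site, "patients_per_site")
  controls_per_site <- expand(controls_per_site, "controls_per_site")

  stopifnot(length(grid_dims) == 3, length(block_dims) == 3,
            all(grid_dims >= 1), all(block_dims >= 1),
            all(grid_dims == floor(grid_dims)), all(block_dims == floor(block_dims)))
  grid_dims <- as.integer(grid_dims)
  block_dims <- as.integer(block_dims)
  n_sv <- prod(ceiling(grid_dims / block_dims))

  if (!is.matrix(planted_links)) planted_links <- matrix(planted_links, ncol = 2)
  storage.mode(planted_links) <- "integer"
  if (nrow(planted_links) > 0) {
    pl <- t(apply(planted_links, 1, sort))
    if (any(pl[, 1] == pl[, 2]) || any(pl < 1) || any(pl > n_sv))
      stop("planted_links must be distinct supervoxel index pairs within the grid")
    planted_links <- pl
  }

  stopifnot(base_corr >= 0, base_corr < 1, delta_r >= 0)
  if (base_corr + delta_r >= 1)
    stop("base_corr + delta_r must be below 1 for a valid correlation matrix")
  stopifnot(within_share > 0, within_share <= 1,
            subject_link_sd >= 0, site_offset_sd >= 0, site_scale_sd >= 0,
            site_common_sd >= 0, scale_noise_sd >= 0)

  if (is.matrix(scale_weights)) {
    stopifnot(nrow(scale_weights) == n_scales,
              ncol(scale_weights) == nrow(planted_links))
  } else {
    stopifnot(length(scale_weights) == nrow(planted_links))
    scale_weights <- matrix(rep(scale_weights, each = n_scales),
                            nrow = n_scales)
  }

  cfg <- list(
    n_sites = as.integer(n_sites),
    patients_per_site = patients_per_site,
    controls_per_site = controls_per_site,
    runs_per_subject = as.integer(runs_per_subject),
    grid_dims = grid_dims, block_dims = block_dims,
    t_points = as.integer(t_points),
    base_corr = base_corr, planted_links = planted_links, delta_r = delta_r,
    subject_link_sd = subject_link_sd, within_share = within_share,
    site_offset_sd = site_offset_sd, site_scale_sd = site_scale_sd,
    site_common_sd = site_common_sd,
    scale_weights = scale_weights, scale_noise_sd = scale_noise_sd,
    n_scales = as.integer(n_scales), seed = as.integer(seed),
    n_supervoxels = as.integer(n_sv)
  )
  class(cfg) <- "synth_config"
  # fail fast if the planted increments break positive semi-definiteness
  generate_cov_structure(cfg, "patient")
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", sum(x$patients_per_site), " patients + ",
      sum(x$controls_per_site), " controls, ", x$n_sites, " sites, ",
      x$runs_per_subject, " runs x ", x$t_points, " time points\n",
      "  grid ", paste(x$grid_dims, collapse = "x"), ", blocks ",
      paste(x$block_dims, collapse = "x"), " (", x$n_supervoxels,
      " supervoxels), ", nrow(x$planted_links), " planted links, delta_r = ",
      x$delta_r, "\n", sep = "")
  invisible(x)
}

#' Group-level supervoxel correlation structure
#'
#' Compound-symmetric baseline correlation (`base_corr` off the diagonal)
#' among supervoxel latent signals; for patients the planted links receive
#' an additional `delta_r`. The result is repaired to the nearest valid
#' correlation matrix by eigenvalue clipping and re-normalization to unit
#' diagonal, and rejected if it is still not positive semi-definite.
#'
#' @param config a [synth_config()].
#' @param group `"patient"` or `"control"`.
#' @param subject_shift optional per-link perturbation added to the planted
#'   entries (used internally for patient-level heterogeneity).
#' @return A symmetric unit-diagonal positive semi-definite matrix.
#' @export
generate_cov_structure <- function(config, group = c("control", "patient"),
                                   subject_shift = NULL) {
  group <- match.arg(group)
  n <- config$n_supervoxels
  m <- matrix(config$base_corr, n, n)
  diag(m) <- 1
  pl <- config$planted_links
  if (group == "patient" && nrow(pl) > 0) {
    shift <- config$delta_r + (subject_shift %||% rep(0, nrow(pl)))
    # keep every entry a valid correlation
    shift <- pmin(shift, 0.995 - config$base_corr)
    shift <- pmax(shift, -config$base_corr)
    for (r in seq_len(nrow(pl))) {
      m[pl[r, 1], pl[r, 2]] <- m[pl[r, 2], pl[r, 1]] <-
        config$base_corr + shift[r]
    }
  }
  psd_repair(m)
}

# Clip negative eigenvalues and re-normalize to unit diagonal; error if the
# result is still meaningfully non-PSD.
psd_repair <- function(m, tol = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < -tol) {
    v <- pmax(e$values, 0)
    m <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    diag(m) <- 1
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -tol)
      stop("correlation structure is not positive semi-definite after repair; ",
           "reduce delta_r or base_corr")
  }
  (m + t(m)) / 2
}

#' Simulate one run of node-by-time series
#'
#' Draws `t_points` samples of a zero-mean Gaussian process over the voxel
#' grid. Each supervoxel block shares a latent signal with instantaneous
#' correlation `cov` (Cholesky construction); each voxel mixes that latent
#' with independent noise (`within_share`), then the site's batch effects
#' are applied: common-mode signal, per-node gain, per-node offset.
#'
#' @param config a [synth_config()].
#' @param cov supervoxel correlation matrix (see [generate_cov_structure()]).
#' @param site site-effect parameters as produced internally per site:
#'   a list with `offset` and `gain` (per-voxel vectors) and `common_amp`
#'   (scalar); `NULL` means no batch effect.
#' @param seed optional seed; with a seed the output is bit-reproducible.
#' @return A `run_ts` object: list with `series` (node x time matrix),
#'   `node_coords` (0-based voxel triples), `mask` (logical 3-D array),
#'   `grid_dims`.
#' @export
generate_run <- function(config, cov, site = NULL, seed = NULL) {
  with_seed(seed, {
    e <- eigen(cov, symmetric = TRUE)
    if (min(e$values) < -1e-8) stop("cov is not positive semi-definite")
    l <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(cov))
    tt <- config$t_points
    n_sv <- nrow(cov)
    latent <- l %*% matrix(rnorm(n_sv * tt), n_sv, tt)

    grid <- voxel_grid(config$grid_dims)
    sv_of <- supervoxel_index(grid$coords, config$block_dims,
                              config$grid_dims)
    n_vox <- nrow(grid$coords)
    a <- config$within_share
    series <- sqrt(a) * latent[sv_of, , drop = FALSE] +
      sqrt(1 - a) * matrix(rnorm(n_vox * tt), n_vox, tt)

    if (!is.null(site)) {
      if (site$common_amp > 0)
        series <- series + matrix(rep(site$common_amp * rnorm(tt), each = n_vox),
                                  n_vox, tt)
      series <- series * site$gain + site$offset
    }
    new_run_ts(series, grid$coords, grid$mask, config$grid_dims)
  })
}

new_run_ts <- function(series, node_coords, mask, grid_dims) {
  structure(list(series = series, node_coords = node_coords,
                 mask = mask, grid_dims = as.integer(grid_dims)),
            class = "run_ts")
}

#' @export
print.run_ts <- function(x, ...) {
  cat("<run_ts> ", nrow(x$series), " nodes x ", ncol(x$series),
      " time points on a ", paste(x$grid_dims, collapse = "x"), " grid (",
      sum(x$mask), " in mask)\n", sep = "")
  invisible(x)
}

# full-grid coordinates (0-based triples) and an all-TRUE mask
voxel_grid <- function(grid_dims) {
  coords <- as.matrix(expand.grid(x = 0:(grid_dims[1] - 1L),
                                  y = 0:(grid_dims[2] - 1L),
                                  z = 0:(grid_dims[3] - 1L)))
  storage.mode(coords) <- "integer"
  mask <- array(TRUE, dim = grid_dims)
  list(coords = coords, mask = mask)
}

# map voxel coordinates to a 1-based supervoxel (block) linear index
supervoxel_index <- function(coords, block_dims, grid_dims) {
  nb <- ceiling(grid_dims / block_dims)
  bx <- coords[, 1] %/% block_dims[1]
  by <- coords[, 2] %/% block_dims[2]
  bz <- coords[, 3] %/% block_dims[3]
  as.integer(1L + bx + nb[1] * (by + nb[2] * bz))
}

# block-index triple (0-based) for each supervoxel linear index
supervoxel_coords <- function(block_dims, grid_dims) {
  nb <- ceiling(grid_dims / block_dims)
  coords <- as.matrix(expand.grid(x = 0:(nb[1] - 1L), y = 0:(nb[2] - 1L),
                                  z = 0:(nb[3] - 1L)))
  storage.mode(coords) <- "integer"
  coords
}

#' Integer symptom-severity scales from planted link-weights
#'
#' The latent severity for each scale is a weighted sum of the subject's
#' mean planted-link weights (across runs) plus Gaussian noise; it is
#' mapped to an integer score in `{0,...,5}` by fixed equal-width binning
#' of the latent's theoretical range (model-implied mean plus/minus three
#' model-implied SDs). A degenerate (zero-width) range maps every subject
#' to the mid-range score 3, preserving the convention that the score is a
#' monotone function of the latent.
#'
#' @param link_weights numeric vector, the subject's mean observed weight of
#'   each planted link (aligned with `config$planted_links` rows).
#' @param config a [synth_config()].
#' @param seed optional seed for the noise draw.
#' @return Named integer vector of length `config$n_scales`, values in 0..5.
#' @export
generate_scales <- function(link_weights, config, seed = NULL) {
  stopifnot(length(link_weights) == nrow(config$planted_links))
  with_seed(seed, {
    w <- config$scale_weights                       # n_scales x n_links
    latent <- as.numeric(w %*% link_weights) +
      rnorm(config$n_scales, 0, config$scale_noise_sd)
    rng <- scale_latent_range(config)
    score <- vapply(seq_len(config$n_scales), function(s) {
      lo <- rng$lo[s]; hi <- rng$hi[s]
      if (hi - lo <= 0) return(3L)
      bin <- floor((latent[s] - lo) / ((hi - lo) / 6))
      as.integer(min(max(bin, 0), 5))
    }, integer(1))
    names(score) <- paste0("scale_", seq_len(config$n_scales))
    score
  })
}

# model-implied mean and SD of the latent severity, per scale
scale_latent_range <- function(config) {
  r_pat <- config$base_corr + config$delta_r
  # sampling variance of a mean-over-runs Pearson estimate (Fisher approx.)
  samp_var <- ((1 - r_pat^2)^2 / max(config$t_points - 1, 1)) /
    config$runs_per_subject
  w <- config$scale_weights
  mu <- rowSums(w) * r_pat
  sigma <- sqrt(rowSums(w^2) * (config$subject_link_sd^2 + samp_var) +
                  config$scale_noise_sd^2)
  list(lo = mu - 3 * sigma, hi = mu + 3 * sigma)
}

#' Generate a full synthetic multi-site cohort
#'
#' Draws site batch-effect parameters, subject-level planted-link
#' perturbations (patients), all runs, and the symptom scales, fully
#' reproducibly from `config$seed`.
#'
#' @param config a [synth_config()].
#' @return A list with `samples` (a tibble, one row per run: `subject_id`,
#'   `run_id`, `site_id`, `group`, `scale_1` ... — scales are `NA` for
#'   controls) and `runs` (list of [generate_run()] outputs aligned with
#'   `samples` rows).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n_vox <- prod(config$grid_dims)
    cov_control <- generate_cov_structure(config, "control")
    pl <- config$planted_links

    samples <- list(); runs <- list(); idx <- 0L
    for (s in seq_len(config$n_sites)) {
      site <- list(
        offset = rnorm(n_vox, 0, config$site_offset_sd),
        gain = exp(rnorm(n_vox, 0, config$site_scale_sd)),
        common_amp = abs(rnorm(1, 0, config$site_common_sd))
      )
      groups <- c(rep("patient", config$patients_per_site[s]),
                  rep("control", config$controls_per_site[s]))
      for (g in seq_along(groups)) {
        grp <- groups[g]
        subj <- sprintf("S%02d_%02d", s, g)
        if (grp == "patient") {
          shift <- if (nrow(pl) > 0 && config$subject_link_sd > 0)
            rnorm(nrow(pl), 0, config$subject_link_sd) else NULL
          cov_s <- generate_cov_structure(config, "patient", shift)
        } else cov_s <- cov_control

        subj_runs <- lapply(seq_len(config$runs_per_subject), function(r)
          generate_run(config, cov_s, site))

        scales <- rep(NA_integer_, config$n_scales)
        if (grp == "patient") {
          lw <- planted_link_weights(subj_runs, config)
          scales <- generate_scales(lw, config)
        }
        names(scales) <- paste0("scale_", seq_len(config$n_scales))

        for (r in seq_len(config$runs_per_subject)) {
          idx <- idx + 1L
          runs[[idx]] <- subj_runs[[r]]
          samples[[idx]] <- tibble::tibble(
            subject_id = subj, run_id = r, site_id = sprintf("site%02d", s),
            group = grp, !!!as.list(scales))
        }
      }
    }
    list(samples = dplyr::bind_rows(samples), runs = runs)
  })
}

# subject's mean observed planted-link weight across runs, from the
# supervoxel-mean series
planted_link_weights <- function(subj_runs, config) {
  pl <- config$planted_links
  if (nrow(pl) == 0) return(numeric(0))
  per_run <- vapply(subj_runs, function(run) {
    sv <- build_supervoxels(run, config$block_dims)
    cm <- correlation_matrix(sv$series)
    cm[pl]
  }, numeric(nrow(pl)))
  if (nrow(pl) == 1L) mean(per_run) else rowMeans(per_run)
}
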