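#' Pearson correlation matrix of node time series
#'
#' Pairwise Pearson correlations among the rows of a node-by-time matrix.
#' Rows with zero variance (constant series) are defined to have
#' correlation 0 with everything and are flagged; the diagonal is forced
#' to 1.
#'
#' @param ts numeric matrix, nodes in rows, time points in columns (at
#'   least 3).
#' @return Symmetric correlation matrix with attribute `constant_nodes`
#'   (integer indices of flagged rows).
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) stop("at least 3 time points are required")
  z <- row_standardize(ts)
  cm <- tcrossprod(z$z)
  cm[cm > 1] <- 1; cm[cm < -1] <- -1
  diag(cm) <- 1
  if (length(z$constant)) {
    cm[z$constant, ] <- 0
    cm[, z$constant] <- 0
    diag(cm) <- 1
  }
  attr(cm, "constant_nodes") <- z$constant
  cm
}

# center rows and scale to unit norm; constant rows become zero rows
row_standardize <- function(ts) {
  mu <- rowMeans(ts)
  z <- ts - mu
  nrm <- sqrt(rowSums(z^2))
  constant <- which(nrm == 0)
  nrm[nrm == 0] <- 1
  list(z = z / nrm, constant = constant)
}

#' Threshold a correlation matrix into a functional network
#'
#' A link joins nodes `i != j` when `corr[i, j] > c` (strict; signed by
#' default, so strong negative correlations do not create links unless
#' `absolute = TRUE`).
#'
#' @param corr symmetric correlation matrix.
#' @param c Pearson cutoff in `[-1, 1]` (default 0.7).
#' @param absolute threshold `|r|` instead of `r`.
#' @param node_coords optional per-node coordinate matrix carried along.
#' @return A `conn_network`: list with `corr`, `threshold`, `adjacency`
#'   (logical symmetric, empty diagonal), `node_coords`.
#' @export
threshold_network <- function(corr, c = 0.7, absolute = FALSE,
                              node_coords = NULL) {
  if (!is.numeric(c) || length(c) != 1 || is.na(c) || c < -1 || c > 1)
    stop("threshold c must lie in [-1, 1]")
  adj <- if (absolute) abs(corr) > c else corr > c
  diag(adj) <- FALSE
  structure(list(corr = corr, threshold = c, adjacency = adj,
                 node_coords = node_coords),
            class = "conn_network")
}

#' @export
print.conn_network <- function(x, ...) {
  cat("<conn_network> ", nrow(x$adjacency), " nodes, ",
      sum(x$adjacency) / 2, " links (r > ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Node degrees of a thresholded network
#'
#' The degree of a node is the number of links incident to it; the degree
#' sum equals twice the link count.
#'
#' @param net a [threshold_network()] result.
#' @return Integer vector of per-node degrees.
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "conn_network"))
  as.integer(rowSums(net$adjacency))
}

#' Log-transformed degree
#'
#' `log10(degree + 1)`, the monotone compression used for voxel-level
#' degree features.
#'
#' @param d non-negative integer degree(s).
#' @return Numeric vector.
#' @export
log_degree <- function(d) {
  if (any(d < 0)) stop("degrees must be non-negative")
  log10(d + 1)
}

#' Node degrees by tiled accumulation
#'
#' Computes thresholded-network degrees directly from the time series
#' without ever materializing the full node-by-node correlation matrix:
#' correlations are evaluated tile-by-tile (a `tile_size` x n working set)
#' and only the per-node link counts are accumulated. Equivalent to
#' `degrees(threshold_network(correlation_matrix(ts), c))`.
#'
#' @inheritParams correlation_matrix
#' @inheritParams threshold_network
#' @param tile_size rows per tile.
#' @return Integer vector of per-node degrees.
#' @export
degrees_tiled <- function(ts, c = 0.7, absolute = FALSE, tile_size = 1024) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) stop("at least 3 time points are required")
  zi <- row_standardize(ts)
  z <- zi$z
  n <- nrow(z)
  # self term to drop from each row's count: r = 1 on the diagonal, except
  # constant rows whose (defined-as-0) self entry appears as a 0 dot product
  self <- rep(as.integer(1 > c), n)
  self[zi$constant] <- as.integer(0 > c)
  deg <- integer(n)
  starts <- seq(1L, n, by = tile_size)
  for (s in starts) {
    rows <- s:min(s + tile_size - 1L, n)
    block <- tcrossprod(z[rows, , drop = FALSE], z)  # |tile| x n
    hits <- if (absolute) abs(block) > c else block > c
    deg[rows] <- deg[rows] + as.integer(rowSums(hits)) - self[rows]
  }
  deg
}

#' Aggregate voxels into supervoxels
#'
#' Tiles the voxel grid, anchored at the origin, into non-overlapping
#' blocks of `block_dims` (half-open `[origin, origin + block_dims)`).
#' Each supervoxel's series is the arithmetic mean of its in-mask member
#' voxels' series. Blocks whose in-mask member fraction is below
#' `min_fill` are dropped.
#'
#' @param run a `run_ts` (see [generate_run()]).
#' @param block_dims integer triple.
#' @param min_fill minimum in-mask fraction for a block to be kept.
#' @return A `run_ts` at supervoxel level: `node_coords` are 0-based block
#'   index triples, `mask` marks retained blocks.
#' @export
build_supervoxels <- function(run, block_dims = c(4, 4, 3), min_fill = 0.5) {
  stopifnot(inherits(run, "run_ts"))
  if (sum(run$mask) == 0) stop("mask is empty")
  block_dims <- as.integer(block_dims)
  grid_dims <- run$grid_dims
  nb <- as.integer(ceiling(grid_dims / block_dims))
  sv_of <- supervoxel_index(run$node_coords, block_dims, grid_dims)
  n_blocks <- prod(nb)

  # block volume clipped at the grid edge, for the fill criterion
  sv_coords_all <- supervoxel_coords(block_dims, grid_dims)
  vol <- vapply(seq_len(n_blocks), function(b) {
    o <- sv_coords_all[b, ] * block_dims
    prod(pmin(o + block_dims, grid_dims) - o)
  }, numeric(1))

  counts <- tabulate(sv_of, nbins = n_blocks)
  keep <- which(counts / vol >= min_fill & counts > 0)
  if (length(keep) == 0) stop("no supervoxel reaches min_fill in-mask voxels")

  tt <- ncol(run$series)
  agg <- matrix(0, length(keep), tt)
  for (k in seq_along(keep)) {
    members <- which(sv_of == keep[k])
    agg[k, ] <- colMeans(run$series[members, , drop = FALSE])
  }
  mask <- array(FALSE, dim = nb)
  mask[sv_coords_all[keep, , drop = FALSE] + 1L] <- TRUE
  new_run_ts(agg, sv_coords_all[keep, , drop = FALSE], mask, nb)
}

#' Link-weight features from a correlation matrix
#'
#' All upper-triangle correlations in the canonical lexicographic pair
#' order (`(1,2), (1,3), ..., (n-1,n)`), `n(n-1)/2` values.
#'
#' @param corr symmetric correlation matrix over at least 2 nodes.
#' @return List with `values` (numeric vector) and `pairs` (2-column
#'   integer matrix, smaller index first).
#' @export
link_weight_features <- function(corr) {
  n <- nrow(corr)
  if (n < 2) stop("at least 2 nodes are required")
  list(values = upper_tri_lex(corr), pairs = link_pairs(n))
}

#' Within-site standardization of a feature matrix
#'
#' z-transforms every feature within each acquisition site (subtract the
#' within-site mean, divide by the within-site sample SD, `ddof = 1`)
#' before samples from different sites are combined. Features constant
#' within a site are set to 0 there and flagged.
#'
#' @param fm a [conn_features] object, or a numeric sample-by-feature
#'   matrix (then `site` must be given).
#' @param site character/factor vector of site labels per sample (ignored
#'   for `conn_features` input, which carries its own metadata).
#' @return Same shape as the input with `ss_`-prefixed feature type (for
#'   `conn_features`) and attribute `constant_flags`, a tibble of flagged
#'   (site, feature) pairs.
#' @export
site_standardize <- function(fm, site = NULL) {
  if (inherits(fm, "conn_features")) {
    out <- fm
    std <- site_standardize(fm$values, fm$samples$site_id)
    out$values <- std
    attr(out$values, "constant_flags") <- NULL
    out$feature_type <- if (startsWith(fm$feature_type, "ss_"))
      fm$feature_type else paste0("ss_", fm$feature_type)
    out$constant_flags <- attr(std, "constant_flags")
    return(out)
  }
  x <- as.matrix(fm)
  stopifnot(!is.null(site), length(site) == nrow(x))
  flags <- list()
  for (s in unique(site)) {
    rows <- which(site == s)
    if (length(rows) < 2)
      stop("site ", s, " has fewer than 2 samples; cannot standardize")
    xs <- x[rows, , drop = FALSE]
    mu <- colMeans(xs)
    sdv <- apply(xs, 2, sd)
    const <- which(sdv == 0)
    sdv[const] <- 1
    x[rows, ] <- sweep(sweep(xs, 2, mu), 2, sdv, "/")
    if (length(const))
      flags[[s]] <- tibble::tibble(site = s, feature = const)
  }
  attr(x, "constant_flags") <- if (length(flags)) dplyr::bind_rows(flags)
    else tibble::tibble(site = character(), feature = integer())
  x
}

#' Extract a feature matrix from cohort runs
#'
#' Builds one feature row per run sample. Degree-type features
#' (`degree`, `log_degree`, `ss_log_degree`) are per-voxel link counts of
#' the thresholded voxel-level network (computed by tiled accumulation);
#' link-type features (`link_weight`, `ss_link_weight`) are all pairwise
#' supervoxel correlations. `ss_` types apply [site_standardize()].
#'
#' @param cohort list with `samples` (tibble) and `runs` (list of
#'   `run_ts`), as returned by [generate_cohort()] or [read_cohort()].
#' @param feature_type one of `"degree"`, `"log_degree"`,
#'   `"ss_log_degree"`, `"link_weight"`, `"ss_link_weight"`.
#' @param threshold Pearson cutoff for degree features.
#' @param block_dims,min_fill supervoxel construction (link features).
#' @param absolute threshold on `|r|` instead of `r`.
#' @param tile_size tile rows for the voxel-degree accumulation.
#' @return A `conn_features` object: list with `values` (samples x
#'   features matrix), `feature_type`, `descriptors` (tibble: voxel/block
#'   coordinates for degree features, node pairs plus both end
#'   coordinates for link features), `samples` (the metadata tibble).
#' @export
extract_features <- function(cohort,
                             feature_type = c("ss_link_weight", "link_weight",
                                              "degree", "log_degree",
                                              "ss_log_degree"),
                             threshold = 0.7, block_dims = c(4, 4, 3),
                             min_fill = 0.5, absolute = FALSE,
                             tile_size = 1024) {
  feature_type <- match.arg(feature_type)
  samples <- cohort$samples
  runs <- cohort$runs
  stopifnot(nrow(samples) == length(runs), length(runs) > 0)

  ref_coords <- runs[[1]]$node_coords
  same_nodes <- vapply(runs, function(r)
    identical(dim(r$node_coords), dim(ref_coords)) &&
      all(r$node_coords == ref_coords), logical(1))
  if (!all(same_nodes)) stop("runs have inconsistent node sets")

  if (feature_type %in% c("degree", "log_degree", "ss_log_degree")) {
    values <- t(vapply(runs, function(r)
      as.numeric(degrees_tiled(r$series, c = threshold, absolute = absolute,
                               tile_size = tile_size)),
      numeric(nrow(ref_coords))))
    if (feature_type != "degree") values <- log_degree(values)
    descriptors <- tibble::tibble(feature = seq_len(ncol(values)),
                                  x = ref_coords[, 1], y = ref_coords[, 2],
                                  z = ref_coords[, 3])
  } else {
    svs <- lapply(runs, build_supervoxels, block_dims = block_dims,
                  min_fill = min_fill)
    sv_coords <- svs[[1]]$node_coords
    lw <- lapply(svs, function(s) link_weight_features(
      correlation_matrix(s$series)))
    values <- do.call(rbind, lapply(lw, `[[`, "values"))
    pairs <- lw[[1]]$pairs
    descriptors <- tibble::tibble(
      feature = seq_len(nrow(pairs)),
      node_i = pairs[, 1], node_j = pairs[, 2],
      xi = sv_coords[pairs[, 1], 1], yi = sv_coords[pairs[, 1], 2],
      zi = sv_coords[pairs[, 1], 3],
      xj = sv_coords[pairs[, 2], 1], yj = sv_coords[pairs[, 2], 2],
      zj = sv_coords[pairs[, 2], 3])
  }
  rownames(values) <- NULL

  fm <- structure(list(values = values,
                       feature_type = sub("^ss_", "", feature_type),
                       descriptors = descriptors, samples = samples,
                       threshold = threshold, block_dims = block_dims),
                  class = "conn_features")
  if (startsWith(feature_type, "ss_")) fm <- site_standardize(fm)
  fm
}

#' @export
print.conn_features <- function(x, ...) {
  cat("<conn_features> ", nrow(x$values), " samples x ", ncol(x$values),
      " features (", x$feature_type, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.conn_features <- function(x) dim(x$values)
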