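#' Top-k features by ascending p-value
#'
#' Indices of the `k` smallest p-values; ties are broken by ascending
#' feature index so intersections across folds are reproducible.
#'
#' @param p numeric vector of p-values.
#' @param k subset size, `1 <= k <= length(p)`.
#' @return Integer vector of `k` feature indices, in rank order.
#' @export
top_k <- function(p, k) {
  if (k < 1 || k > length(p)) stop("k must lie in [1, length(p)]")
  order(p, seq_along(p))[seq_len(k)]
}

#' Fraction of features common to all folds' top-k sets
#'
#' @param per_fold_topk list of equally sized index sets (one per fold).
#' @param k the common subset size (defaults to the sets' size).
#' @return `|intersection| / k`, in `[0, 1]`.
#' @export
stability_fraction <- function(per_fold_topk, k = NULL) {
  sizes <- lengths(per_fold_topk)
  k <- k %||% sizes[1]
  if (any(sizes != k)) stop("all per-fold sets must have size k")
  length(Reduce(intersect, per_fold_topk)) / k
}

#' Feature-selection stability curve over subset sizes
#'
#' For each subset size `k`, selects the `k` lowest-p features in every
#' fold and records the fraction common to all folds. At `k = N` (all
#' features) the fraction is exactly 1.
#'
#' @param per_fold_pvalues list of p-value vectors, one per fold, aligned
#'   on the same feature set.
#' @param k_grid subset sizes; default powers of 2 up to `min(N, 2^14)`
#'   plus 30 and `N`.
#' @param feature_type optional tag carried into the result.
#' @return A `conn_stability` tibble: `k`, `k_frac` (`k/N`),
#'   `fraction_common`; attributes `n_folds`, `n_features`,
#'   `feature_type`.
#' @export
stability_curve <- function(per_fold_pvalues, k_grid = NULL,
                            feature_type = NULL) {
  n <- unique(lengths(per_fold_pvalues))
  if (length(n) != 1) stop("folds are not aligned on one feature set")
  k_grid <- k_grid %||% default_k_grid(n)
  k_grid <- sort(unique(pmin(as.integer(k_grid), n)))
  topk_all <- lapply(per_fold_pvalues, function(p) order(p, seq_along(p)))
  frac <- vapply(k_grid, function(k) {
    sets <- lapply(topk_all, function(o) o[seq_len(k)])
    stability_fraction(sets, k)
  }, numeric(1))
  out <- tibble::tibble(k = k_grid, k_frac = k_grid / n,
                        fraction_common = frac)
  attr(out, "n_folds") <- length(per_fold_pvalues)
  attr(out, "n_features") <- n
  attr(out, "feature_type") <- feature_type
  class(out) <- c("conn_stability", class(out))
  out
}

default_k_grid <- function(n) {
  ks <- c(2^(1:14), 30, n)
  sort(unique(ks[ks <= n]))
}

#' Stable top-k links across folds
#'
#' Intersection across folds of the top-k (lowest p-value) feature sets at
#' a fixed `k`, with link descriptors attached when available.
#'
#' @param per_fold_pvalues list of p-value vectors (or a list of already
#'   selected index sets of size `k`).
#' @param k subset size.
#' @param descriptors optional per-feature descriptor tibble with a
#'   `feature` column ([extract_features()] provides one).
#' @return Tibble of the stable features (joined with descriptors when
#'   supplied), attribute `indices` holding the raw index set.
#' @export
stable_topk <- function(per_fold_pvalues, k, descriptors = NULL) {
  sets <- lapply(per_fold_pvalues, function(p) {
    if (length(p) == k && all(p == floor(p)) && all(p >= 1)) as.integer(p)
    else top_k(p, k)
  })
  idx <- sort(Reduce(intersect, sets))
  out <- if (!is.null(descriptors)) {
    dplyr::semi_join(descriptors, tibble::tibble(feature = idx),
                     by = "feature")
  } else tibble::tibble(feature = idx)
  attr(out, "indices") <- idx
  out
}
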