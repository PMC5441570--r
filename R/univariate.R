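#' Mass-univariate two-sample t-tests per feature
#'
#' Pooled-variance (Student) two-sample t-test for every feature column,
#' patients vs. controls, with two-sided p-values from the t distribution
#' on `n1 + n2 - 2` degrees of freedom. The sign convention is positive t
#' when the patient mean exceeds the control mean. Features with zero
#' pooled variance are degenerate: p is 1 when the group means are equal
#' and 0 otherwise, and the feature is flagged.
#'
#' @param fm a [conn_features] object or a numeric sample-by-feature
#'   matrix.
#' @param group vector of group labels per sample containing `"patient"`
#'   and `"control"`; taken from `fm$samples$group` when omitted for
#'   `conn_features` input.
#' @param alpha family-wise / false-discovery rate threshold for the
#'   correction masks.
#' @return A `conn_univariate` tibble with one row per feature: `feature`,
#'   `t`, `p`, `mean_patient`, `mean_control`, `sd_patient`,
#'   `sd_control`, `degenerate`, `bonferroni`, `fdr`; attributes `m`,
#'   `alpha`, `n_patient`, `n_control`, and the feature descriptors when
#'   available.
#' @export
univariate_ttest <- function(fm, group = NULL, alpha = 0.05) {
  if (inherits(fm, "conn_features")) {
    group <- group %||% fm$samples$group
    x <- fm$values
    desc <- fm$descriptors
  } else {
    x <- as.matrix(fm)
    desc <- NULL
  }
  stopifnot(!is.null(group), length(group) == nrow(x))
  pat <- group == "patient"
  ctl <- group == "control"
  n1 <- sum(pat); n2 <- sum(ctl)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")

  m1 <- colMeans(x[pat, , drop = FALSE])
  m2 <- colMeans(x[ctl, , drop = FALSE])
  v1 <- matrixStats_colVars(x[pat, , drop = FALSE], m1)
  v2 <- matrixStats_colVars(x[ctl, , drop = FALSE], m2)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))

  degenerate <- se == 0
  se_safe <- ifelse(degenerate, 1, se)
  t_stat <- (m1 - m2) / se_safe
  p <- 2 * pt(abs(t_stat), df = n1 + n2 - 2, lower.tail = FALSE)
  t_stat[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 0, Inf *
                                 sign(m1[degenerate] - m2[degenerate]))
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)

  out <- tibble::tibble(
    feature = seq_along(p), t = t_stat, p = p,
    mean_patient = m1, mean_control = m2,
    sd_patient = sqrt(v1), sd_control = sqrt(v2),
    degenerate = degenerate,
    bonferroni = bonferroni_mask(p, alpha),
    fdr = bh_fdr_mask(p, alpha))
  attr(out, "m") <- length(p)
  attr(out, "alpha") <- alpha
  attr(out, "n_patient") <- n1
  attr(out, "n_control") <- n2
  attr(out, "descriptors") <- desc
  class(out) <- c("conn_univariate", class(out))
  out
}

# column variances given precomputed means (ddof = 1)
matrixStats_colVars <- function(x, mu) {
  n <- nrow(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

#' Bonferroni correction mask
#'
#' A feature survives iff `p < alpha / m` where `m` is the number of tests.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param alpha family-wise error threshold.
#' @param m number of tests (defaults to `length(p)`).
#' @return Logical survivor mask.
#' @export
bonferroni_mask <- function(p, alpha = 0.05, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1))
  p < alpha / m
}

#' Benjamini--Hochberg FDR mask
#'
#' Step-up rule: reject the `i*` smallest p-values where
#' `i* = max { i : p_(i) <= i * alpha / m }`.
#'
#' @inheritParams bonferroni_mask
#' @return Logical survivor mask.
#' @export
bh_fdr_mask <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH") <= alpha
}

#' Stable Bonferroni feature set across folds
#'
#' Intersection, across leave-one-subject-out folds, of the features
#' surviving Bonferroni correction within each fold.
#'
#' @param per_fold_results list of [univariate_ttest()] results (or of
#'   logical survivor masks) over the same feature set.
#' @return Sorted integer vector of feature indices.
#' @export
stable_bonferroni <- function(per_fold_results) {
  if (length(per_fold_results) == 0) stop("no folds supplied")
  sets <- lapply(per_fold_results, function(r) {
    if (is.logical(r)) which(r) else which(r$bonferroni)
  })
  sort(Reduce(intersect, sets))
}

#' Residualize features on nuisance covariates
#'
#' Replaces every feature by the residual of its least-squares regression
#' on an intercept plus the covariate columns (e.g. motion summaries).
#' Redundant covariate columns are dropped with a warning.
#'
#' @param fm a [conn_features] object or numeric matrix.
#' @param covariates numeric sample-by-q matrix, row-aligned with the
#'   samples.
#' @return Same type as `fm`, with residualized values.
#' @export
residualize_features <- function(fm, covariates) {
  x <- if (inherits(fm, "conn_features")) fm$values else as.matrix(fm)
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == nrow(x))
  design <- cbind(intercept = 1, covariates)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    warning("dropping redundant covariate column(s): ",
            paste(dropped, collapse = ", "))
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(design)
  }
  res <- qr.resid(qrd, x)
  if (inherits(fm, "conn_features")) {
    fm$values <- res
    fm
  } else res
}

#' Per-feature distributional QC
#'
#' For each feature and group, a one-sample Kolmogorov--Smirnov test
#' against a normal with the group's estimated mean and SD (a
#' Lilliefors-style check: parameters are estimated from the same data, so
#' the p-values are conservative guides rather than exact), plus the
#' groupwise mean-of-SDs summary used to compare feature variances across
#' groups.
#'
#' @inheritParams univariate_ttest
#' @return List with `ks` (tibble: feature, group, ks_p) and `sigma_bar`
#'   (tibble: group, mean_sd, sd_of_sds).
#' @export
feature_qc <- function(fm, group = NULL) {
  if (inherits(fm, "conn_features")) {
    group <- group %||% fm$samples$group
    x <- fm$values
  } else x <- as.matrix(fm)
  stopifnot(length(group) == nrow(x))
  groups <- intersect(c("patient", "control"), unique(group))
  ks <- list(); sb <- list()
  for (g in groups) {
    xs <- x[group == g, , drop = FALSE]
    if (nrow(xs) < 5) stop("group ", g, " needs at least 5 samples")
    kp <- apply(xs, 2, function(v) {
      s <- sd(v)
      if (s == 0) return(NA_real_)
      suppressWarnings(ks.test(v, "pnorm", mean(v), s)$p.value)
    })
    sds <- apply(xs, 2, sd)
    ks[[g]] <- tibble::tibble(feature = seq_len(ncol(x)), group = g, ks_p = kp)
    sb[[g]] <- tibble::tibble(group = g, mean_sd = mean(sds),
                              sd_of_sds = sd(sds))
  }
  list(ks = dplyr::bind_rows(ks), sigma_bar = dplyr::bind_rows(sb))
}
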