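#' Plot a stability curve
#'
#' Fraction of features common to all folds' top-k sets against the
#' normalized subset size `k/N` (log scale).
#'
#' @param object a [stability_curve()] result (several can be compared by
#'   row-binding tidied curves and mapping `feature_type`).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.conn_stability <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = 100 * .data$k_frac,
                               y = .data$fraction_common)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "feature subset size, % of N (log scale)",
                  y = "fraction common to all folds",
                  title = attr(object, "feature_type")) +
    ggplot2::ylim(0, 1)
}

#' Plot classification error against subset size
#'
#' Mean leave-one-subject-out error (with FP/FN rates) per feature subset
#' size.
#'
#' @param object a [run_cv()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.conn_classification <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary, -"k",
                              names_to = "metric", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$rate,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "k top-ranked features (log scale)", y = "rate",
                  title = paste0(object$classifier_family, ", ",
                                 object$n_folds, " LOSO folds"))
}

#' Volcano-style plot of mass-univariate results
#'
#' @param object a [univariate_ttest()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.conn_univariate <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$survives <- dplyr::case_when(df$bonferroni ~ "Bonferroni",
                                  df$fdr ~ "FDR only",
                                  TRUE ~ "none")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = -log10(pmax(.data$p,
                                                                1e-300)),
                                   colour = .data$survives)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "t statistic (patient - control)",
                  y = expression(-log[10](p)), colour = "survives")
}

#' Plot scale-prediction performance over the configuration grid
#'
#' @param object a [predict_scales_loso()] result (or row-bound table).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.conn_scalepred <- function(object, ...) {
  df <- tidy.conn_scalepred(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$target_nonzero),
                                   y = .data$rho,
                                   colour = factor(.data$lambda2),
                                   group = factor(.data$lambda2))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$scale) +
    ggplot2::labs(x = "target support size", y = "Spearman rho",
                  colour = "lambda2")
}

#' Descending univariate feature--scale correlation curves
#'
#' One curve per scale: all per-feature Spearman correlations with that
#' scale, sorted in descending order.
#'
#' @param fm a [conn_features] object over link-weight features.
#' @param scales character vector of scale column names (default: all
#'   `scale_*` columns).
#' @return A ggplot object.
#' @export
plot_scale_correlations <- function(fm, scales = NULL) {
  scales <- scales %||% grep("^scale_", names(fm$samples), value = TRUE)
  df <- dplyr::bind_rows(lapply(scales, function(s) {
    rho <- sort(scale_correlations(fm, s)$rho, decreasing = TRUE)
    tibble::tibble(scale = s, rank = seq_along(rho), rho = rho)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$rho,
                                   colour = .data$scale)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "feature rank (descending rho)", y = "Spearman rho")
}
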