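#' Tidy a feature matrix into long form
#'
#' @param x a [conn_features] object.
#' @param ... unused.
#' @return Long tibble: sample metadata, `feature`, `value`.
#' @export
tidy.conn_features <- function(x, ...) {
  vals <- tibble::as_tibble(as.data.frame(x$values),
                            .name_repair = ~ as.character(seq_along(.x)))
  dplyr::bind_cols(x$samples, vals) |>
    tidyr::pivot_longer(cols = dplyr::all_of(names(vals)),
                        names_to = "feature", values_to = "value",
                        names_transform = as.integer)
}

#' @export
glance.conn_features <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$values), n_features = ncol(x$values),
                 feature_type = x$feature_type,
                 n_subjects = length(unique(x$samples$subject_id)),
                 n_sites = length(unique(x$samples$site_id)))
}

#' @export
tidy.conn_univariate <- function(x, ...) {
  out <- tibble::as_tibble(x)
  desc <- attr(x, "descriptors")
  if (!is.null(desc)) out <- dplyr::left_join(out, desc, by = "feature")
  out
}

#' @export
glance.conn_univariate <- function(x, ...) {
  tibble::tibble(m = attr(x, "m"), alpha = attr(x, "alpha"),
                 n_patient = attr(x, "n_patient"),
                 n_control = attr(x, "n_control"),
                 n_bonferroni = sum(x$bonferroni), n_fdr = sum(x$fdr),
                 min_p = min(x$p))
}

#' @export
tidy.conn_classification <- function(x, ...) x$summary

#' @export
glance.conn_classification <- function(x, ...) {
  best <- x$summary[which.min(x$summary$mean_error), ]
  tibble::tibble(classifier = x$classifier_family, n_folds = x$n_folds,
                 best_k = best$k, best_error = best$mean_error,
                 best_accuracy = 1 - best$mean_error)
}

#' @export
tidy.conn_scalepred <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x),
                -dplyr::any_of(c("supports", "stable_support")))
}

#' @export
glance.conn_scalepred <- function(x, ...) {
  best <- x[which.max(x$rho), ]
  tibble::tibble(scale = best$scale[1], n_configs = nrow(x),
                 best_rho = best$rho, best_p = best$p, best_mae = best$mae,
                 n_subjects = attr(x, "n_subjects"))
}

#' @export
tidy.conn_stability <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.conn_stability <- function(x, ...) {
  tibble::tibble(n_folds = attr(x, "n_folds"),
                 n_features = attr(x, "n_features"),
                 feature_type = attr(x, "feature_type") %||% NA_character_,
                 min_fraction = min(x$fraction_common),
                 max_fraction = max(x$fraction_common))
}
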