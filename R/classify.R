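#' Leave-one-subject-out fold specifications
#'
#' One fold per subject: all of that subject's runs form the test set and
#' every other run is training data, so no subject contributes to both
#' sides of a fold.
#'
#' @param samples tibble with `subject_id` per run sample (e.g.
#'   `cohort$samples` or `fm$samples`).
#' @return Tibble with one row per fold: `fold`, `subject_id`,
#'   `test_rows`, `train_rows` (list-columns of row indices).
#' @export
make_loso_folds <- function(samples) {
  subj <- samples$subject_id
  ids <- unique(subj)
  if (length(ids) < 2) stop("at least 2 subjects are required")
  rows <- seq_along(subj)
  tibble::tibble(
    fold = seq_along(ids),
    subject_id = ids,
    test_rows = lapply(ids, function(s) rows[subj == s]),
    train_rows = lapply(ids, function(s) rows[subj != s]))
}

classifier_families <- c("nearest_neighbors", "linear_svm", "rbf_svm",
                         "decision_tree", "random_forest",
                         "logistic_regression", "gaussian_nb", "lda")

# fit/predict wrappers over established implementations; the bespoke
# contract lives in run_cv (fold construction, per-fold ranking,
# aggregation), not here
fit_predict <- function(family, x_train, y_train, x_test, params = list()) {
  y_train <- factor(y_train, levels = c("control", "patient"))
  colnames(x_train) <- colnames(x_test) <- paste0("f", seq_len(ncol(x_train)))
  switch(
    family,
    nearest_neighbors = {
      k <- params$knn_k %||% 5L
      as.character(class::knn(x_train, x_test, y_train, k = k))
    },
    linear_svm = {
      fit <- e1071::svm(x_train, y_train, kernel = "linear",
                        cost = params$cost %||% 1, scale = FALSE)
      as.character(predict(fit, x_test))
    },
    rbf_svm = {
      fit <- e1071::svm(x_train, y_train, kernel = "radial",
                        cost = params$cost %||% 1, scale = FALSE)
      as.character(predict(fit, x_test))
    },
    decision_tree = {
      df <- as.data.frame(x_train); df$.y <- y_train
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      as.character(predict(fit, as.data.frame(x_test), type = "class"))
    },
    random_forest = {
      fit <- randomForest::randomForest(x_train, y_train,
                                        ntree = params$ntree %||% 100L)
      as.character(predict(fit, x_test))
    },
    logistic_regression = {
      # ridge-regularized logistic fit so k may exceed the sample count
      fit <- glmnet::glmnet(x_train, y_train, family = "binomial",
                            alpha = 0, lambda = params$lambda %||%
                              1 / nrow(x_train), standardize = FALSE)
      pr <- predict(fit, x_test, type = "class")
      as.character(pr[, 1])
    },
    gaussian_nb = {
      fit <- e1071::naiveBayes(x_train, y_train)
      as.character(predict(fit, x_test))
    },
    lda = {
      fit <- suppressWarnings(MASS::lda(x_train, grouping = y_train))
      as.character(suppressWarnings(predict(fit, x_test)$class))
    },
    stop("unknown classifier family: ", family)
  )
}

#' Leave-one-subject-out CV with per-fold filter feature selection
#'
#' For every fold, features are ranked by the two-sample t-test computed on
#' the training rows only (no double-dipping); for each subset size `k`
#' the classifier is trained on the top-k features of the training rows
#' and evaluated on the held-out subject's runs. The positive class for
#' FP/FN bookkeeping is `patient`.
#'
#' @param fm a [conn_features] object (or numeric matrix with `group`
#'   and `folds` supplied).
#' @param classifier_family one of `r paste(classifier_families, collapse=", ")`.
#' @param k_grid feature subset sizes; values above the feature count are
#'   skipped with a warning.
#' @param folds fold table from [make_loso_folds()]; derived from
#'   `fm$samples` when omitted.
#' @param group group labels per sample, defaulting to `fm$samples$group`.
#' @param params named list of classifier hyperparameters
#'   (`knn_k`, `cost`, `ntree`, `lambda`).
#' @param seed base seed for any classifier randomness (per-fold seeds are
#'   derived from it).
#' @return A `conn_classification` object: list with `per_fold` (tibble:
#'   fold, subject_id, k, error, fp_rate, fn_rate, selected list-col),
#'   `summary` (tibble: k, mean_error, mean_fp_rate, mean_fn_rate),
#'   `classifier_family`, `k_grid`, `n_folds`.
#' @export
run_cv <- function(fm, classifier_family = "linear_svm", k_grid = c(10, 30),
                   folds = NULL, group = NULL, params = list(), seed = 1L) {
  stopifnot(classifier_family %in% classifier_families)
  if (inherits(fm, "conn_features")) {
    x <- fm$values
    group <- group %||% fm$samples$group
    folds <- folds %||% make_loso_folds(fm$samples)
  } else x <- as.matrix(fm)
  stopifnot(!is.null(group), !is.null(folds))
  n_feat <- ncol(x)
  k_use <- as.integer(k_grid[k_grid <= n_feat])
  if (length(k_use) < length(k_grid))
    warning("dropping k values above the feature count (", n_feat, ")")
  if (length(k_use) == 0) stop("no usable k in k_grid")

  fold_seeds <- derive_seeds(seed, nrow(folds))
  recs <- vector("list", nrow(folds))
  for (f in seq_len(nrow(folds))) {
    tr <- folds$train_rows[[f]]
    te <- folds$test_rows[[f]]
    rank_p <- univariate_ttest(x[tr, , drop = FALSE], group[tr])$p
    ord <- order(rank_p, seq_along(rank_p))
    y_te <- group[te]
    rec <- vector("list", length(k_use))
    for (ki in seq_along(k_use)) {
      k <- k_use[ki]
      sel <- ord[seq_len(k)]
      pred <- with_seed(fold_seeds[f],
        fit_predict(classifier_family, x[tr, sel, drop = FALSE], group[tr],
                    x[te, sel, drop = FALSE], params))
      n_pos <- sum(y_te == "patient"); n_neg <- sum(y_te == "control")
      rec[[ki]] <- tibble::tibble(
        fold = folds$fold[f], subject_id = folds$subject_id[f], k = k,
        error = mean(pred != y_te),
        fp_rate = if (n_neg > 0) sum(pred == "patient" & y_te == "control") /
          n_neg else NA_real_,
        fn_rate = if (n_pos > 0) sum(pred == "control" & y_te == "patient") /
          n_pos else NA_real_,
        selected = list(sel))
    }
    recs[[f]] <- dplyr::bind_rows(rec)
  }
  per_fold <- dplyr::bind_rows(recs)
  summary <- per_fold |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(mean_error = mean(.data$error),
                     mean_fp_rate = mean(.data$fp_rate, na.rm = TRUE),
                     mean_fn_rate = mean(.data$fn_rate, na.rm = TRUE),
                     .groups = "drop")
  structure(list(per_fold = per_fold, summary = summary,
                 classifier_family = classifier_family, k_grid = k_use,
                 n_folds = nrow(folds)),
            class = "conn_classification")
}

#' @export
print.conn_classification <- function(x, ...) {
  best <- x$summary[which.min(x$summary$mean_error), ]
  cat("<conn_classification> ", x$classifier_family, ", ", x$n_folds,
      " LOSO folds; best mean error ", sprintf("%.3f", best$mean_error),
      " at k = ", best$k, "\n", sep = "")
  invisible(x)
}

#' Proper vs. double-dipped feature selection
#'
#' Runs the same classifier and folds twice: once with per-fold
#' (train-only) feature ranking, and once with features ranked a single
#' time on all samples before cross-validation ("double-dipping"). The
#' difference in mean accuracy measures the optimism introduced by
#' selecting features with test data in hand.
#'
#' @inheritParams run_cv
#' @param k feature subset size used by both protocols.
#' @return Tibble with `protocol` (`"proper"`, `"double_dipped"`) and
#'   `accuracy` (mean over folds of per-fold accuracy).
#' @export
double_dip_comparison <- function(fm, classifier_family = "gaussian_nb",
                                  k = 100, folds = NULL, group = NULL,
                                  params = list(), seed = 1L) {
  if (inherits(fm, "conn_features")) {
    x <- fm$values
    group <- group %||% fm$samples$group
    folds <- folds %||% make_loso_folds(fm$samples)
  } else x <- as.matrix(fm)
  proper <- run_cv(x, classifier_family, k_grid = k, folds = folds,
                   group = group, params = params, seed = seed)
  sel_global <- top_k(univariate_ttest(x, group)$p, k)
  fold_seeds <- derive_seeds(seed, nrow(folds))
  acc_dd <- vapply(seq_len(nrow(folds)), function(f) {
    tr <- folds$train_rows[[f]]; te <- folds$test_rows[[f]]
    pred <- with_seed(fold_seeds[f],
      fit_predict(classifier_family, x[tr, sel_global, drop = FALSE],
                  group[tr], x[te, sel_global, drop = FALSE], params))
    mean(pred == group[te])
  }, numeric(1))
  tibble::tibble(
    protocol = c("proper", "double_dipped"),
    accuracy = c(1 - proper$summary$mean_error[1], mean(acc_dd)))
}

#' Majority-class chance level
#'
#' The accuracy of always predicting the majority class, as a percentage,
#' at the subject or run level.
#'
#' @param samples tibble with `group` (and `subject_id` for
#'   `unit = "subject"`), or a bare vector of group labels.
#' @param unit counting unit.
#' @return Percentage in `[0, 100]`.
#' @export
chance_level <- function(samples, unit = c("subject", "run")) {
  unit <- match.arg(unit)
  if (is.data.frame(samples)) {
    g <- if (unit == "subject") {
      dplyr::distinct(samples, .data$subject_id, .data$group)$group
    } else samples$group
  } else g <- samples
  if (length(g) == 0) stop("labels are empty")
  100 * max(table(g)) / length(g)
}
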