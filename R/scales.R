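#' Univariate feature--scale Spearman correlations
#'
#' Spearman rank correlation between every link-weight feature and a
#' symptom scale, over patient runs with a non-missing scale value.
#'
#' @param fm a [conn_features] object or numeric matrix (patient rows).
#' @param scale_values numeric vector of per-sample scale scores, or (for
#'   `conn_features` input) the name of a scale column in `fm$samples`.
#' @return Tibble `feature`, `rho`, sorted views are up to the caller;
#'   attribute `flagged` is `TRUE` when the scale is constant (all rho
#'   undefined, returned as `NA`).
#' @export
scale_correlations <- function(fm, scale_values) {
  if (inherits(fm, "conn_features")) {
    if (is.character(scale_values) && length(scale_values) == 1)
      scale_values <- fm$samples[[scale_values]]
    keep <- fm$samples$group == "patient" & !is.na(scale_values)
    x <- fm$values[keep, , drop = FALSE]
    y <- scale_values[keep]
  } else {
    x <- as.matrix(fm)
    y <- scale_values
    keep <- !is.na(y)
    x <- x[keep, , drop = FALSE]; y <- y[keep]
  }
  flagged <- length(unique(y)) < 2
  rho <- if (flagged) rep(NA_real_, ncol(x)) else
    suppressWarnings(as.numeric(cor(x, y, method = "spearman")))
  out <- tibble::tibble(feature = seq_len(ncol(x)), rho = rho)
  attr(out, "flagged") <- flagged
  out
}

#' Elastic net with a target support size
#'
#' Fits an elastic net `lambda1 * |beta|_1 + lambda2 * |beta|_2^2` at a
#' fixed ridge penalty `lambda2`, searching `lambda1` (bisection on the
#' log scale, warm-started paths) for the solution whose support
#' (non-zero coefficient count) is the largest available not exceeding
#' `target_nonzero`. The search makes the result invariant to the
#' solver's internal penalty scaling.
#'
#' @param x numeric predictor matrix (columns should be standardized on
#'   the training rows).
#' @param y numeric response (centered or not; an intercept is fit).
#' @param target_nonzero desired support size.
#' @param lambda2 ridge penalty.
#' @param n_steps bisection steps.
#' @return List with `coef` (full-length coefficient vector), `intercept`,
#'   `support` (indices of non-zero coefficients), `lambda1`, `empty`
#'   (flag: no `lambda1` achieved a non-empty support), and `path`
#'   (tibble of the `(lambda1, support_size)` pairs visited, for
#'   monotonicity diagnostics).
#' @export
fit_en_target_sparsity <- function(x, y, target_nonzero, lambda2 = 0.1,
                                   n_steps = 30L) {
  x <- as.matrix(x)
  stopifnot(length(y) == nrow(x), target_nonzero >= 1)
  n <- nrow(x)

  fit_at <- function(l1) {
    # glmnet's penalty lambda*[(1-a)/2 |b|^2 + a |b|_1] matches
    # l1|b|_1 + l2|b|^2 at lambda = l1 + 2*l2, a = l1/(l1 + 2*l2)
    lam <- l1 + 2 * lambda2
    a <- l1 / lam
    lam_path <- exp(seq(log(lam * 64), log(lam), length.out = 12))
    fit <- glmnet::glmnet(x, y, alpha = a, lambda = lam_path / 1,
                          standardize = FALSE, intercept = TRUE,
                          thresh = 1e-10)
    b <- as.numeric(coef(fit, s = lam, exact = FALSE))
    list(intercept = b[1], beta = b[-1])
  }

  l1_hi <- max(abs(crossprod(x, y - mean(y)))) / n * 1.05 + 1e-12
  l1_lo <- l1_hi * 1e-6
  visited <- list()
  eval_support <- function(l1) {
    f <- fit_at(l1)
    s <- sum(f$beta != 0)
    visited[[length(visited) + 1L]] <<- tibble::tibble(lambda1 = l1,
                                                       support_size = s)
    list(fit = f, size = s)
  }

  best <- NULL; best_size <- -1L; best_l1 <- NA_real_
  lo <- eval_support(l1_lo)
  if (lo$size <= target_nonzero) {
    best <- lo$fit; best_size <- lo$size; best_l1 <- l1_lo
  } else {
    hi <- eval_support(l1_hi)
    if (hi$size > 0 && hi$size <= target_nonzero) {
      best <- hi$fit; best_size <- hi$size; best_l1 <- l1_hi
    }
    a <- log(l1_lo); b <- log(l1_hi)
    for (i in seq_len(n_steps)) {
      mid <- (a + b) / 2
      ev <- eval_support(exp(mid))
      if (ev$size > target_nonzero) a <- mid else {
        if (ev$size > best_size) {
          best <- ev$fit; best_size <- ev$size; best_l1 <- exp(mid)
        }
        b <- mid
      }
    }
  }
  path <- dplyr::arrange(dplyr::bind_rows(visited), .data$lambda1)
  if (is.null(best) || best_size == 0) {
    return(list(coef = rep(0, ncol(x)), intercept = mean(y),
                support = integer(0), lambda1 = best_l1, empty = TRUE,
                path = path))
  }
  list(coef = best$beta, intercept = best$intercept,
       support = which(best$beta != 0),
       lambda1 = best_l1, empty = FALSE, path = path)
}

#' Leave-one-subject-out elastic-net scale prediction
#'
#' For each elastic-net configuration (target support size x ridge
#' penalty), trains on all but one patient's runs (predictors
#' standardized on the training rows, response centered), predicts the
#' held-out subject's runs, and pools all held-out predictions. Reported
#' per configuration: Spearman rho and p of pooled predictions vs. the
#' true integer scores, mean absolute error, per-fold supports, and the
#' stable (all-folds) support. Constant pooled predictions make rho
#' undefined: the configuration is flagged with `p = 1`.
#'
#' @param fm a [conn_features] object over link-weight features.
#' @param scale name of a scale column in `fm$samples` (or a numeric
#'   per-sample vector).
#' @param target_grid support sizes (capped at the feature count).
#' @param lambda2_grid ridge penalties.
#' @return A `conn_scalepred` tibble, one row per configuration:
#'   `scale`, `target_nonzero`, `lambda2`, `rho`, `p`, `mae`,
#'   `n_stable`, `flagged`, list-columns `supports` (per fold) and
#'   `stable_support`; attribute `predictions` holds the pooled per-run
#'   predictions of each configuration.
#' @export
predict_scales_loso <- function(fm, scale, target_grid = c(50, 100, 300, 500, 700),
                                lambda2_grid = c(0.01, 0.1, 1.0)) {
  stopifnot(inherits(fm, "conn_features"))
  scale_name <- if (is.character(scale)) scale else "scale"
  y_all <- if (is.character(scale)) fm$samples[[scale]] else scale
  stopifnot(!is.null(y_all), length(y_all) == nrow(fm$values))

  keep <- fm$samples$group == "patient"
  miss <- keep & is.na(y_all)
  if (any(miss)) {
    warning("excluding ", length(unique(fm$samples$subject_id[miss])),
            " subject(s) with missing scale values")
    keep <- keep & !is.na(y_all)
  }
  x <- fm$values[keep, , drop = FALSE]
  y <- as.numeric(y_all[keep])
  samples <- fm$samples[keep, , drop = FALSE]
  folds <- make_loso_folds(samples)
  target_grid <- pmin(as.integer(target_grid), ncol(x))

  configs <- tidyr::expand_grid(target_nonzero = unique(target_grid),
                                lambda2 = lambda2_grid)
  preds_list <- list()
  rows <- vector("list", nrow(configs))
  for (ci in seq_len(nrow(configs))) {
    tgt <- configs$target_nonzero[ci]; l2 <- configs$lambda2[ci]
    pred <- rep(NA_real_, nrow(x))
    supports <- vector("list", nrow(folds))
    for (f in seq_len(nrow(folds))) {
      tr <- folds$train_rows[[f]]; te <- folds$test_rows[[f]]
      mu <- colMeans(x[tr, , drop = FALSE])
      sdv <- apply(x[tr, , drop = FALSE], 2, sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sdv, "/")
      en <- fit_en_target_sparsity(xtr, y[tr], tgt, l2)
      pred[te] <- en$intercept + as.numeric(xte %*% en$coef)
      supports[[f]] <- en$support
    }
    stable <- if (nrow(folds) > 0) sort(Reduce(intersect, supports))
      else integer(0)
    flagged <- length(unique(round(pred, 12))) < 2
    if (flagged) {
      rho <- NA_real_; pval <- 1
    } else {
      ct <- suppressWarnings(cor.test(pred, y, method = "spearman",
                                      exact = FALSE))
      rho <- unname(ct$estimate); pval <- ct$p.value
    }
    preds_list[[ci]] <- tibble::tibble(
      target_nonzero = tgt, lambda2 = l2,
      subject_id = samples$subject_id, run_id = samples$run_id,
      truth = y, prediction = pred)
    rows[[ci]] <- tibble::tibble(
      scale = scale_name, target_nonzero = tgt, lambda2 = l2,
      rho = rho, p = pval, mae = mean(abs(pred - y)),
      n_stable = length(stable), flagged = flagged,
      supports = list(supports), stable_support = list(stable))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "predictions") <- dplyr::bind_rows(preds_list)
  attr(out, "n_subjects") <- nrow(folds)
  class(out) <- c("conn_scalepred", class(out))
  out
}

#' Multiple-comparison correction over the configuration grid
#'
#' Bonferroni and Benjamini--Hochberg flags computed jointly over all
#' (scale x configuration) entries, plus the per-scale best (largest rho)
#' configuration with its flags.
#'
#' @param results a `conn_scalepred` table, typically row-bound over
#'   scales (default 9 scales x 5 supports x 3 lambda2 = 135 entries).
#' @param alpha false-positive rate threshold.
#' @return List with `table` (the input plus `bonferroni` and `fdr`
#'   columns) and `best_per_scale` (one row per scale: best rho with its
#'   p, MAE and flags).
#' @export
correct_over_configs <- function(results, alpha = 0.05) {
  p <- ifelse(is.na(results$p), 1, results$p)
  tbl <- results
  tbl$bonferroni <- bonferroni_mask(p, alpha)
  tbl$fdr <- bh_fdr_mask(p, alpha)
  best <- tbl |>
    dplyr::group_by(.data$scale) |>
    dplyr::slice_max(.data$rho, n = 1, with_ties = FALSE, na_rm = TRUE) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::any_of(c("scale", "target_nonzero", "lambda2",
                                  "rho", "p", "mae", "bonferroni", "fdr")))
  list(table = tbl, best_per_scale = best)
}

#' Parsimonious model selection for one scale
#'
#' Among the significant (FDR-surviving) configurations whose rho is
#' within 5% of the highest significant rho, picks the smallest support
#' size; ties are broken by the smallest ridge penalty.
#'
#' @param tbl corrected configuration table for one scale (rows of
#'   `correct_over_configs()$table`).
#' @return One-row tibble (the chosen configuration), or a zero-row
#'   tibble with attribute `flagged = TRUE` when nothing is significant.
#' @export
select_parsimonious <- function(tbl) {
  sig <- tbl[tbl$fdr & !is.na(tbl$rho), , drop = FALSE]
  if (nrow(sig) == 0) {
    out <- tbl[0, , drop = FALSE]
    attr(out, "flagged") <- TRUE
    return(out)
  }
  rho_max <- max(sig$rho)
  cand <- sig[sig$rho >= 0.95 * rho_max, , drop = FALSE]
  cand <- cand[order(cand$target_nonzero, cand$lambda2), , drop = FALSE]
  out <- cand[1, , drop = FALSE]
  attr(out, "flagged") <- FALSE
  out
}

#' Stable elastic-net support
#'
#' Features selected (non-zero coefficient) in every fold of a
#' configuration, with link descriptors attached when available.
#'
#' @param supports list of per-fold support index vectors.
#' @param descriptors optional per-feature descriptor tibble with a
#'   `feature` column.
#' @return Tibble of stable features; attribute `indices` is the raw set.
#' @export
stable_en_support <- function(supports, descriptors = NULL) {
  idx <- sort(Reduce(intersect, supports))
  out <- if (!is.null(descriptors)) {
    dplyr::semi_join(descriptors, tibble::tibble(feature = idx),
                     by = "feature")
  } else tibble::tibble(feature = idx)
  attr(out, "indices") <- idx
  out
}

#' Scale-prediction table over all scales
#'
#' Runs [predict_scales_loso()] for every scale column and applies
#' [correct_over_configs()], producing the per-scale summary (one row per
#' scale: best rho, p, MAE, correction flags).
#'
#' @inheritParams predict_scales_loso
#' @param scales character vector of scale column names in `fm$samples`
#'   (default: all `scale_*` columns).
#' @param alpha correction threshold.
#' @return List with `table` (all configurations, flagged),
#'   `best_per_scale`, and `chosen` (parsimonious pick per scale).
#' @export
scale_prediction_report <- function(fm, scales = NULL,
                                    target_grid = c(50, 100, 300, 500, 700),
                                    lambda2_grid = c(0.01, 0.1, 1.0),
                                    alpha = 0.05) {
  scales <- scales %||% grep("^scale_", names(fm$samples), value = TRUE)
  res <- dplyr::bind_rows(lapply(scales, function(s)
    predict_scales_loso(fm, s, target_grid, lambda2_grid)))
  corr <- correct_over_configs(res, alpha)
  chosen <- dplyr::bind_rows(lapply(scales, function(s) {
    sub <- corr$table[corr$table$scale == s, , drop = FALSE]
    select_parsimonious(sub)
  }))
  list(table = corr$table, best_per_scale = corr$best_per_scale,
       chosen = chosen)
}
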