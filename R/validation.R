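#' Inverse-variance-weighted Pearson correlation
#'
#' Pearson correlation between observed and predicted values in which each
#' pair is weighted by the precision of its prediction, `w_i = 1 / sigma2_i`
#' (normalized to sum to 1; the correlation is invariant to rescaling all
#' weights by a positive constant). The p-value is the F-test of the
#' weighted-least-squares slope being zero, with 1 and n - 2 degrees of
#' freedom. Zero variances are replaced by the smallest positive variance
#' in the set (with a message); a constant observed or predicted vector has
#' no defined correlation and is flagged rather than propagating NaN.
#'
#' @param observed,predicted numeric vectors of equal length >= 3.
#' @param sigma2 prediction variances (> 0) of the same length; NULL for
#'   uniform weights (plain Pearson).
#' @return tibble with `r`, `p_value`, `n`, `undefined` (TRUE when the
#'   correlation does not exist).
#' @export
weighted_pearson <- function(observed, predicted, sigma2 = NULL) {
  n <- length(observed)
  if (length(predicted) != n || (!is.null(sigma2) && length(sigma2) != n)) {
    abort("inputs must have equal length", class = "vsp_shape_error")
  }
  if (n < 3) abort("need at least 3 pairs", class = "vsp_insufficient_data")
  if (is.null(sigma2)) sigma2 <- rep(1, n)
  if (any(sigma2 < 0)) abort("variances must be non-negative",
                             class = "vsp_domain_error")
  if (any(sigma2 == 0)) {
    pos <- sigma2[sigma2 > 0]
    if (!length(pos)) {
      sigma2 <- rep(1, n)
    } else {
      inform(sprintf(
        "%d zero prediction variance(s) replaced by the smallest positive (%.3g)",
        sum(sigma2 == 0), min(pos)))
      sigma2[sigma2 == 0] <- min(pos)
    }
  }
  w <- (1 / sigma2) / sum(1 / sigma2)
  mo <- sum(w * observed); mp <- sum(w * predicted)
  vo <- sum(w * (observed - mo)^2); vp <- sum(w * (predicted - mp)^2)
  if (vo <= 0 || vp <= 0) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = n,
                          undefined = TRUE))
  }
  covop <- sum(w * (observed - mo) * (predicted - mp))
  r <- covop / sqrt(vo * vp)
  r <- max(min(r, 1), -1)
  # F-test of the WLS slope: F = r^2 (n-2) / (1 - r^2) on (1, n-2) df
  if (abs(r) >= 1) {
    p <- 0
  } else {
    f <- r^2 * (n - 2) / (1 - r^2)
    p <- pf(f, 1, n - 2, lower.tail = FALSE)
  }
  tibble::tibble(r = r, p_value = p, n = n, undefined = FALSE)
}

# shared engine: predict each hold-out set from the rest under a fixed
# variogram model (the model is fitted once on all data unless supplied)
.cv_predict_folds <- function(dataset, folds, model, policy) {
  purrr::map(folds, function(test_idx) {
    train <- dataset[-test_idx, , drop = FALSE]
    attributes(train)[c("protein_length", "axes", "class")] <-
      attributes(dataset)[c("protein_length", "axes", "class")]
    purrr::map(test_idx, function(i) {
      u <- c(dataset$x[i], dataset$y[i])
      pr <- predict_point(u, train, model, policy)
      tibble::tibble(index = i, observed = dataset$z[i],
                     predicted = pr[["z_hat"]], sigma2 = pr[["sigma2"]])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

# fit the all-data variogram used as the fixed CV model
.cv_fit_model <- function(dataset, family, n_bins, active_lag) {
  pr <- pairwise_semivariances(dataset)
  emp <- empirical_variogram(pr, n_bins = n_bins, active_lag = active_lag)
  fit_variogram(emp, family)
}

#' Leave-one-out cross-validation of the Kriging predictor
#'
#' The variogram model is fitted once on the full dataset; each observation
#' is then removed in turn and predicted from the remaining observations
#' under that fixed model. Performance is summarized by the
#' inverse-variance-weighted Pearson correlation between observed and
#' predicted values. `refit_per_fold = TRUE` switches to the stricter
#' protocol in which the variogram is refitted without the held-out point.
#'
#' @param dataset a `variant_tbl`.
#' @param family variogram family fitted to all data (ignored when `model`
#'   is given).
#' @param policy a [neighborhood_policy()].
#' @param n_bins,active_lag binning for the variogram fit (see
#'   [empirical_variogram()]).
#' @param model optional pre-fitted `variogram_model` to hold fixed.
#' @param refit_per_fold refit the variogram without each held-out point.
#' @return `vsp_cv` object; see [tidy.vsp_cv()] / [glance.vsp_cv()].
#' @export
loo_cv <- function(dataset, family = "spherical",
                   policy = neighborhood_policy(), n_bins = 12,
                   active_lag = NULL, model = NULL,
                   refit_per_fold = FALSE) {
  n <- nrow(dataset)
  if (n < policy$min_n + 1) {
    abort("need at least min_n + 1 observations for leave-one-out",
          class = "vsp_insufficient_data")
  }
  if (is.null(model)) model <- .cv_fit_model(dataset, family, n_bins,
                                             active_lag)
  folds <- as.list(seq_len(n))
  per_point <- if (refit_per_fold) {
    purrr::map(folds, function(idx) {
      sub <- dataset[-idx, , drop = FALSE]
      attributes(sub)[c("protein_length", "axes", "class")] <-
        attributes(dataset)[c("protein_length", "axes", "class")]
      m <- .cv_fit_model(sub, family, n_bins, active_lag)
      .cv_predict_folds(dataset, list(idx), m, policy)
    }) |> dplyr::bind_rows()
  } else {
    .cv_predict_folds(dataset, folds, model, policy)
  }
  per_point <- dplyr::arrange(per_point, .data$index)
  wp <- weighted_pearson(per_point$observed, per_point$predicted,
                         per_point$sigma2)
  structure(list(per_point = per_point, weighted_r = wp$r,
                 p_value = wp$p_value, undefined = wp$undefined,
                 k = n, repeats = 1L, seed = NA_integer_, model = model),
            class = "vsp_cv")
}

#' k-fold cross-validation of the Kriging predictor
#'
#' Observations are randomly partitioned into k near-equal folds (sizes
#' differ by at most one, assigned by seeded shuffle); each fold is
#' predicted from the other k - 1 under the all-data variogram model. For
#' k < n the partitioning is repeated (default 5 times) and the reported
#' correlation and p-value are means across repeats. `k = n` is exactly
#' leave-one-out. Results are deterministic for a fixed seed.
#'
#' @inheritParams loo_cv
#' @param k number of folds, 2 <= k <= n.
#' @param repeats partition repetitions (forced to 1 when k = n).
#' @param seed integer seed for the partition shuffle.
#' @return `vsp_cv` object; `per_point` stacks all repeats with a `repeat_id`
#'   column.
#' @export
kfold_cv <- function(dataset, k, repeats = 5L, seed = 1L,
                     family = "spherical", policy = neighborhood_policy(),
                     n_bins = 12, active_lag = NULL, model = NULL) {
  n <- nrow(dataset)
  if (k > n) abort("k cannot exceed the number of observations",
                   class = "vsp_config_error")
  if (k < 2) abort("k must be at least 2", class = "vsp_config_error")
  if (is.null(model)) model <- .cv_fit_model(dataset, family, n_bins,
                                             active_lag)
  if (k == n) repeats <- 1L
  reps <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(repeats), function(r) {
      fold_id <- sample(rep_len(seq_len(k), n))
      folds <- split(seq_len(n), fold_id)
      pp <- .cv_predict_folds(dataset, folds, model, policy)
      pp$repeat_id <- r
      pp
    })
  })
  per_point <- dplyr::bind_rows(reps)
  stats_by_rep <- purrr::map(reps, function(pp) {
    weighted_pearson(pp$observed, pp$predicted, pp$sigma2)
  }) |> dplyr::bind_rows()
  structure(list(per_point = per_point,
                 weighted_r = mean(stats_by_rep$r),
                 p_value = mean(stats_by_rep$p_value),
                 undefined = any(stats_by_rep$undefined),
                 k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed), model = model),
            class = "vsp_cv")
}

#' @export
print.vsp_cv <- function(x, ...) {
  cat(sprintf(
    "Kriging cross-validation: k = %d, repeats = %d, n = %d\n",
    x$k, x$repeats, length(unique(x$per_point$index))))
  if (isTRUE(x$undefined)) {
    cat("  weighted Pearson r: undefined (constant observed or predicted)\n")
  } else {
    cat(sprintf("  weighted Pearson r = %.3f (p = %.3g)\n",
                x$weighted_r, x$p_value))
  }
  invisible(x)
}

#' Per-held-out-point cross-validation records
#' @param x a `vsp_cv`.
#' @param ... unused.
#' @return tibble with `index`, `observed`, `predicted`, `sigma2` (and
#'   `repeat_id` for repeated k-fold).
#' @method tidy vsp_cv
#' @export
tidy.vsp_cv <- function(x, ...) tibble::as_tibble(x$per_point)

#' One-row cross-validation summary
#' @param x a `vsp_cv`.
#' @param ... unused.
#' @return tibble with `weighted_r`, `p_value`, `k`, `repeats`, `seed`,
#'   `undefined`.
#' @method glance vsp_cv
#' @export
glance.vsp_cv <- function(x, ...) {
  tibble::tibble(weighted_r = x$weighted_r, p_value = x$p_value,
                 k = x$k, repeats = x$repeats, seed = x$seed,
                 undefined = x$undefined)
}

#' Observed-versus-predicted plot for a cross-validation
#'
#' @param object a `vsp_cv`.
#' @param ... unused.
#' @return a ggplot with 1-sd prediction error bars and the identity line.
#' @method autoplot vsp_cv
#' @export
autoplot.vsp_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$predicted - sqrt(.data$sigma2),
                   ymax = .data$predicted + sqrt(.data$sigma2)),
      width = 0, alpha = 0.5) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "observed z", y = "predicted z*") +
    ggplot2::theme_minimal()
}
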