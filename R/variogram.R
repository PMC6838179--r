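#' Pairwise separation distances and semivariances
#'
#' For every unordered pair (i < j) of observations, computes the Euclidean
#' separation in the (x, y) plane, `h = sqrt((x_i - x_j)^2 + (y_i - y_j)^2)`,
#' and the semivariance of the response, `gamma = (z_i - z_j)^2 / 2`. With n
#' observations the result has exactly n(n-1)/2 rows.
#'
#' @param dataset a `variant_tbl` or any data frame with `x`, `y`, `z`.
#' @return tibble with columns `i`, `j`, `h`, `gamma`.
#' @export
pairwise_semivariances <- function(dataset) {
  n <- nrow(dataset)
  if (n < 2L) {
    abort("need at least 2 observations to form pairs",
          class = "vsp_insufficient_data")
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  h <- sqrt((dataset$x[i] - dataset$x[j])^2 + (dataset$y[i] - dataset$y[j])^2)
  gamma <- 0.5 * (dataset$z[i] - dataset$z[j])^2
  tibble::tibble(i = i, j = j, h = h, gamma = gamma)
}

#' Lag-binned empirical variogram
#'
#' Averages pair semivariances within uniform distance intervals (lags) up
#' to `active_lag`; pairs separated farther are excluded. Bin means are
#' plain arithmetic means of member gammas; empty bins carry NA gamma and a
#' zero count.
#'
#' @param pairs tibble from [pairwise_semivariances()].
#' @param n_bins number of uniform lag bins (default 12).
#' @param active_lag maximum distance considered; default half the maximum
#'   pair distance.
#' @return `empirical_variogram` tibble with `bin_lo`, `bin_hi`,
#'   `bin_center`, `gamma`, `n_pairs`; the active lag is an attribute.
#' @export
empirical_variogram <- function(pairs, n_bins = 12, active_lag = NULL) {
  if (is.null(active_lag)) active_lag <- max(pairs$h) / 2
  if (n_bins < 2) abort("`n_bins` must be at least 2")
  if (active_lag <= 0) abort("`active_lag` must be positive")
  keep <- pairs[pairs$h <= active_lag, ]
  if (!nrow(keep)) {
    abort("no pairs fall within the active lag; variogram is empty",
          class = "vsp_empty_variogram")
  }
  edges <- seq(0, active_lag, length.out = n_bins + 1L)
  bin <- pmin(findInterval(keep$h, edges, rightmost.closed = TRUE), n_bins)
  # h == 0 pairs land in bin 0 under left-open intervals; fold into bin 1
  bin[bin < 1L] <- 1L
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, gamma = keep$gamma), .data$bin),
    gamma = mean(.data$gamma), n_pairs = dplyr::n(), .groups = "drop")
  out <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    bin_center = (edges[-length(edges)] + edges[-1]) / 2,
    gamma = NA_real_,
    n_pairs = 0L)
  out$gamma[agg$bin] <- agg$gamma
  out$n_pairs[agg$bin] <- agg$n_pairs
  structure(out, active_lag = active_lag,
            class = c("empirical_variogram", class(out)))
}

#' Construct a variogram model
#'
#' @param family one of "spherical", "linear", "exponential", "gaussian".
#' @param nugget micro-scale variance c0 (>= 0), the semivariance reached as
#'   h approaches 0 from above; the model still evaluates to exactly 0 at
#'   h = 0 (exact interpolation convention).
#' @param psill partial sill c (>= 0); the sill (plateau) is `nugget + psill`.
#' @param range distance a (> 0) at which the model flattens; for the
#'   exponential and gaussian families this is the effective range at which
#'   95% of the sill is reached.
#' @param rss residual sum of squares of the fit, if fitted.
#' @return `variogram_model` object.
#' @export
variogram_model <- function(family = c("spherical", "linear", "exponential",
                                       "gaussian"),
                            nugget, psill, range, rss = NA_real_) {
  family <- match.arg(family)
  if (nugget < 0 || psill < 0 || range <= 0) {
    abort("require nugget >= 0, psill >= 0, range > 0",
          class = "vsp_domain_error")
  }
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range, rss = rss),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "Variogram model (%s): nugget %.4g, partial sill %.4g, sill %.4g, range %.4g",
    x$family, x$nugget, x$psill, x$nugget + x$psill, x$range))
  if (is.finite(x$rss)) cat(sprintf(", rss %.3g", x$rss))
  cat("\n")
  invisible(x)
}

#' Sill (plateau) of a variogram model
#' @param model a `variogram_model`.
#' @return `nugget + psill`, the zero-distance covariance C(0).
#' @export
sill <- function(model) model$nugget + model$psill

#' Evaluate a variogram model
#'
#' Semivariance gamma(h) of the model at distances `h`. gamma(0) is exactly
#' 0 by the exact-interpolation convention; for any h > 0 the nugget
#' applies. Families: spherical `c0 + c (1.5 t - 0.5 t^3)` with `t = h/a`
#' capped at the sill beyond `a`; linear rises linearly to the sill at `a`;
#' exponential `c0 + c (1 - exp(-3 h / a))`; gaussian
#' `c0 + c (1 - exp(-3 (h/a)^2))` (effective-range convention).
#'
#' @param model a `variogram_model`.
#' @param h non-negative distances.
#' @return semivariances, same length as `h`.
#' @export
model_gamma <- function(model, h) {
  if (any(h < 0)) abort("distances must be non-negative",
                        class = "vsp_domain_error")
  c0 <- model$nugget; c1 <- model$psill; a <- model$range
  t <- h / a
  g <- switch(model$family,
    spherical = c0 + c1 * ifelse(t >= 1, 1, 1.5 * t - 0.5 * t^3),
    linear = c0 + c1 * pmin(t, 1),
    exponential = c0 + c1 * (1 - exp(-3 * t)),
    gaussian = c0 + c1 * (1 - exp(-3 * t^2)))
  g[h == 0] <- 0
  g
}

#' Spatial covariance implied by a variogram model
#'
#' `C(h) = C(0) - gamma(h)` with `C(0) = nugget + psill` (the plateau).
#' Between distinct points the nugget discontinuity applies as h tends to
#' 0+, while `C(0)` itself is the full sill.
#'
#' @inheritParams model_gamma
#' @return covariances, same length as `h`.
#' @export
model_covariance <- function(model, h) {
  sill(model) - model_gamma(model, h)
}

# Residual sum of squares of a parameter triplet against binned gammas.
# Vectorized over rows of the (c0, c, a) matrix for the grid stage.
.vario_rss <- function(family, par, h, gamma) {
  m <- variogram_model(family, max(par[1], 0), max(par[2], 0),
                       max(par[3], 1e-12))
  sum((gamma - model_gamma(m, h))^2)
}

#' Fit a variogram model to an empirical variogram
#'
#' Least-squares fit of the chosen family to the populated bins: parameters
#' `(nugget, psill, range)` minimize the residual sum of squares of the bin
#' means against the model curve. The optimizer is deterministic: a fixed
#' 10 x 10 x 10 multi-start grid spanning the empirical gamma scale and lag
#' span, followed by bounded Levenberg-Marquardt refinement from the best
#' starts. Degenerate input (all bin gammas equal) yields a pure-nugget
#' model with a warning.
#'
#' @param emp an `empirical_variogram`.
#' @param family model family to fit (default spherical).
#' @param n_starts number of best grid nodes carried into local refinement.
#' @return fitted `variogram_model` with `rss` recorded.
#' @export
fit_variogram <- function(emp, family = c("spherical", "linear",
                                          "exponential", "gaussian"),
                          n_starts = 5L) {
  family <- match.arg(family)
  ok <- !is.na(emp$gamma)
  if (sum(ok) < 3) abort("need at least 3 populated bins to fit",
                         class = "vsp_insufficient_data")
  h <- emp$bin_center[ok]; g <- emp$gamma[ok]
  lag <- attr(emp, "active_lag") %||% max(emp$bin_hi)
  if (diff(range(g)) < .Machine$double.eps * max(1, max(g))) {
    warn("all bin semivariances equal; returning pure-nugget model",
         class = "vsp_degenerate_fit")
    m <- variogram_model(family, nugget = g[1], psill = 0, range = lag)
    m$rss <- 0
    return(m)
  }
  gmax <- max(g)
  # fixed multi-start grid: nugget and partial sill span the gamma scale,
  # range spans (0, 1.5 * active lag]
  c0_grid <- seq(0, gmax, length.out = 10)
  c_grid <- seq(gmax / 20, 1.5 * gmax, length.out = 10)
  a_grid <- seq(lag / 20, 1.5 * lag, length.out = 10)
  starts <- expand.grid(c0 = c0_grid, c = c_grid, a = a_grid,
                        KEEP.OUT.ATTRS = FALSE)
  rss_grid <- vapply(seq_len(nrow(starts)), function(k) {
    .vario_rss(family, as.numeric(starts[k, ]), h, g)
  }, 0)
  ord <- order(rss_grid, starts$c0, starts$c, starts$a)
  best_par <- NULL; best_rss <- Inf
  lower <- c(0, 0, lag / 1e4)
  upper <- c(2 * gmax, 3 * gmax, 3 * lag)
  resid_fn <- function(p) {
    m <- variogram_model(family, p[1], p[2], p[3])
    g - model_gamma(m, h)
  }
  for (k in head(ord, n_starts)) {
    p0 <- pmin(pmax(as.numeric(starts[k, ]), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (rss < best_rss - 1e-18 ||
        (abs(rss - best_rss) <= 1e-18 && is.null(best_par))) {
      best_rss <- rss; best_par <- fit$par
    }
  }
  if (is.null(best_par)) {
    warn("variogram fit did not converge; returning pure-nugget model",
         class = "vsp_degenerate_fit")
    m <- variogram_model(family, nugget = mean(g), psill = 0, range = lag)
    m$rss <- sum((g - mean(g))^2)
    return(m)
  }
  variogram_model(family, best_par[1], best_par[2], best_par[3],
                  rss = best_rss)
}

#' Fit all four families and pick the best by leave-one-out error
#'
#' Fits spherical, linear, exponential and gaussian models to the same
#' empirical variogram and scores each by leave-one-out cross-validated
#' weighted correlation on the dataset; returns the fits ranked by that
#' score.
#'
#' @param dataset a `variant_tbl`.
#' @param emp an `empirical_variogram` computed from `dataset`.
#' @param policy a [neighborhood_policy()].
#' @return tibble with one row per family: the fitted model (list column),
#'   rss, and LOO weighted r.
#' @export
compare_variogram_families <- function(dataset, emp,
                                       policy = neighborhood_policy()) {
  fams <- c("spherical", "linear", "exponential", "gaussian")
  rows <- purrr::map(fams, function(f) {
    m <- fit_variogram(emp, f)
    cv <- loo_cv(dataset, model = m, policy = policy)
    tibble::tibble(family = f, model = list(m), rss = m$rss,
                   loo_weighted_r = glance(cv)$weighted_r)
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$loo_weighted_r))
}

#' @method tidy variogram_model
#' @export
tidy.variogram_model <- function(x, ...) {
  tibble::tibble(term = c("nugget", "psill", "sill", "range"),
                 estimate = c(x$nugget, x$psill, sill(x), x$range))
}

#' @method glance variogram_model
#' @export
glance.variogram_model <- function(x, ...) {
  tibble::tibble(family = x$family, nugget = x$nugget, psill = x$psill,
                 sill = sill(x), range = x$range, rss = x$rss)
}

#' Plot an empirical variogram with an optional fitted model curve
#'
#' @param object an `empirical_variogram`.
#' @param model optional `variogram_model` overlay.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot empirical_variogram
#' @export
autoplot.empirical_variogram <- function(object, model = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df[!is.na(df$gamma), ],
                       ggplot2::aes(.data$bin_center, .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "separation distance h",
                  y = expression(gamma(h)), size = "pairs") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    hseq <- seq(1e-9, max(df$bin_hi), length.out = 200)
    curve <- tibble::tibble(h = hseq, gamma = model_gamma(model, hseq))
    p <- p +
      ggplot2::geom_line(data = curve, ggplot2::aes(.data$h, .data$gamma),
                         colour = "firebrick") +
      ggplot2::geom_vline(xintercept = model$range, linetype = 2) +
      ggplot2::geom_hline(yintercept = sill(model), linetype = 3)
  }
  p
}
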