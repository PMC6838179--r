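#' Local neighborhood policy for Kriging
#'
#' Prediction at each target uses only nearby observations: the `max_n`
#' nearest within `search_radius`; when fewer than `min_n` fall inside the
#' radius, the `min_n` nearest overall are used regardless of radius.
#' Defaults follow the published practice of averaging over a minimum of 5
#' and a maximum of about 20 nearby variants.
#'
#' @param min_n minimum neighbors (default 5).
#' @param max_n maximum neighbors (default 20).
#' @param search_radius search distance; NULL means "use the variogram
#'   range", resolved at prediction time.
#' @return a `neighborhood_policy` list.
#' @export
neighborhood_policy <- function(min_n = 5L, max_n = 20L,
                                search_radius = NULL) {
  if (min_n < 1 || max_n < min_n) {
    abort("require 1 <= min_n <= max_n", class = "vsp_domain_error")
  }
  structure(list(min_n = as.integer(min_n), max_n = as.integer(max_n),
                 search_radius = search_radius),
            class = "neighborhood_policy")
}

# x/y with the duplicate-coordinate jitter applied: the second and later
# members of each exact (x, y) duplicate get +1e-9 * k added to x, only for
# matrix assembly / distance computation.
.jittered_xy <- function(dataset) {
  x <- dataset$x; y <- dataset$y
  key <- paste(x, y)
  dup_rank <- stats::ave(seq_along(key), key, FUN = seq_along) - 1L
  x <- x + 1e-9 * dup_rank
  cbind(x = x, y = y)
}

#' Select the Kriging neighborhood for a target coordinate
#'
#' @param u numeric length-2 target `(x, y)`.
#' @param dataset a `variant_tbl`.
#' @param policy a [neighborhood_policy()]; a NULL `search_radius` here
#'   means no radius cut (the `max_n` nearest are used).
#' @return integer observation indices ordered by (distance, index).
#' @export
select_neighbors <- function(u, dataset, policy = neighborhood_policy()) {
  n <- nrow(dataset)
  if (n < policy$min_n) {
    abort(sprintf("dataset has %d observations but min_n is %d",
                  n, policy$min_n),
          class = "vsp_insufficient_data")
  }
  xy <- .jittered_xy(dataset)
  d <- sqrt((xy[, 1] - u[1])^2 + (xy[, 2] - u[2])^2)
  ord <- order(d, seq_len(n))
  if (!is.null(policy$search_radius)) {
    inside <- ord[d[ord] <= policy$search_radius]
    if (length(inside) >= policy$min_n) {
      return(head(inside, policy$max_n))
    }
    return(head(ord, policy$min_n))
  }
  head(ord, policy$max_n)
}

#' Solve the ordinary-Kriging system for one target
#'
#' Builds the spatial covariance matrix `C` among the neighbors and the
#' covariance vector `c_u` to the target from the variogram model
#' (`C(h) = C(0) - gamma(h)`), and solves the augmented system
#' `[C 1; 1' 0] [w; mu] = [c_u; 1]` by dense LU factorization. The weights
#' sum to 1 (unbiasedness), the prediction is `z* = sum(w z)`, and the
#' Kriging variance is `sigma2 = C(0) - (sum(w c_u) + mu)`. Tiny negative
#' variances from round-off (|sigma2| < 1e-12) are clamped to zero; larger
#' negatives raise an internal-consistency error.
#'
#' @param u numeric length-2 target `(x, y)`.
#' @param neighbors integer observation indices (from [select_neighbors()]).
#' @param model a `variogram_model`.
#' @param dataset a `variant_tbl`.
#' @return `kriging_solution` list: `neighbor_indices`, `weights`,
#'   `lagrange`, `prediction`, `variance`.
#' @export
solve_kriging <- function(u, neighbors, model, dataset) {
  k <- length(neighbors)
  if (!k) abort("empty neighborhood", class = "vsp_insufficient_data")
  xy <- .jittered_xy(dataset)[neighbors, , drop = FALSE]
  z <- dataset$z[neighbors]
  if (sill(model) == 0) {
    # zero-variance field: every linear unbiased predictor is the mean
    return(structure(list(neighbor_indices = neighbors,
                          weights = rep(1 / k, k), lagrange = 0,
                          prediction = mean(z), variance = 0),
                     class = "kriging_solution"))
  }
  dmat <- as.matrix(dist(xy))
  C <- matrix(model_covariance(model, as.numeric(dmat)), k, k)
  du <- sqrt((xy[, 1] - u[1])^2 + (xy[, 2] - u[2])^2)
  cu <- model_covariance(model, du)
  A <- rbind(cbind(C, 1), c(rep(1, k), 0))
  b <- c(cu, 1)
  sol <- tryCatch(solve(A, b), error = function(e) {
    coincident <- which(dmat < 1e-12 & upper.tri(dmat), arr.ind = TRUE)
    labs <- if (nrow(coincident)) {
      paste(dataset$label[neighbors[coincident[, 1]]],
            dataset$label[neighbors[coincident[, 2]]],
            sep = "/", collapse = ", ")
    } else "none detected"
    abort(paste0("singular Kriging system; coincident observations: ", labs),
          class = "vsp_singular_system")
  })
  w <- sol[seq_len(k)]; mu <- sol[k + 1L]
  s2 <- sill(model) - (sum(w * cu) + mu)
  if (s2 < 0) {
    if (s2 > -1e-12) {
      s2 <- 0
    } else {
      abort(sprintf("negative Kriging variance %.3g: inconsistent model", s2),
            class = "vsp_internal_error")
    }
  }
  structure(list(neighbor_indices = neighbors, weights = w, lagrange = mu,
                 prediction = sum(w * z), variance = s2),
            class = "kriging_solution")
}

#' Predict the response at one target coordinate
#'
#' Composition of [select_neighbors()] and [solve_kriging()]. With a zero
#' nugget the predictor interpolates exactly: at an observation coordinate
#' it returns the observed z with zero variance.
#'
#' @inheritParams solve_kriging
#' @param policy a [neighborhood_policy()]; a NULL `search_radius` is
#'   resolved to the model range.
#' @return named numeric: `z_hat`, `sigma2`, `n_neighbors`.
#' @export
predict_point <- function(u, dataset, model,
                          policy = neighborhood_policy()) {
  if (is.null(policy$search_radius)) policy$search_radius <- model$range
  nb <- select_neighbors(u, dataset, policy)
  sol <- solve_kriging(u, nb, model, dataset)
  c(z_hat = sol$prediction, sigma2 = sol$variance,
    n_neighbors = length(nb))
}

#' Predict at many target coordinates
#'
#' Vectorized wrapper over [predict_point()].
#'
#' @param targets data frame with columns `x`, `y`.
#' @inheritParams predict_point
#' @return `targets` with `z_hat`, `sigma2`, `n_neighbors` columns added.
#' @export
kriging_predict <- function(targets, dataset, model,
                            policy = neighborhood_policy()) {
  if (is.null(policy$search_radius)) policy$search_radius <- model$range
  res <- purrr::map(seq_len(nrow(targets)), function(r) {
    predict_point(c(targets$x[r], targets$y[r]), dataset, model, policy)
  })
  out <- tibble::as_tibble(targets)
  out$z_hat <- vapply(res, `[[`, 0, "z_hat")
  out$sigma2 <- vapply(res, `[[`, 0, "sigma2")
  out$n_neighbors <- as.integer(vapply(res, `[[`, 0, "n_neighbors"))
  out
}
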