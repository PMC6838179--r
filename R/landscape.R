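#' Build a dense phenotype landscape
#'
#' Evaluates the ordinary-Kriging predictor on a regular grid over the
#' (x, y) plane: x spans [0, 1] (the normalized sequence axis) and y spans
#' the observed functional range padded by 5% on each side, unless explicit
#' limits are given. Each grid cell carries the prediction `z_hat` and the
#' Kriging variance `sigma2`.
#'
#' @param dataset a `variant_tbl`.
#' @param model a fitted `variogram_model`.
#' @param policy a [neighborhood_policy()].
#' @param grid_res cells per axis (default 100).
#' @param xlim,ylim optional numeric length-2 axis limits.
#' @return `phenotype_landscape` tibble in long format (`x`, `y`, `z_hat`,
#'   `sigma2`, `n_neighbors`) with grid axes, the model and a provenance
#'   fingerprint stored as attributes.
#' @export
build_landscape <- function(dataset, model, policy = neighborhood_policy(),
                            grid_res = 100L, xlim = c(0, 1), ylim = NULL) {
  if (grid_res < 2) abort("`grid_res` must be at least 2")
  if (is.null(ylim)) {
    yr <- range(dataset$y)
    pad <- 0.05 * max(diff(yr), .Machine$double.eps)
    ylim <- c(yr[1] - pad, yr[2] + pad)
  }
  gx <- seq(xlim[1], xlim[2], length.out = grid_res)
  gy <- seq(ylim[1], ylim[2], length.out = grid_res)
  grid <- tidyr::expand_grid(x = gx, y = gy)
  out <- kriging_predict(grid, dataset, model, policy)
  structure(out,
            grid_x = gx, grid_y = gy, model = model,
            provenance = landscape_fingerprint(dataset, model, policy,
                                               grid_res),
            class = c("phenotype_landscape", class(out)))
}

# short provenance string: dataset size/hash-ish summary + model + config
landscape_fingerprint <- function(dataset, model, policy, grid_res) {
  sprintf("n=%d;len=%d;fam=%s;c0=%.6g;c=%.6g;a=%.6g;nb=%d-%d;grid=%d",
          nrow(dataset), protein_length(dataset), model$family,
          model$nugget, model$psill, model$range,
          policy$min_n, policy$max_n, grid_res)
}

#' Confidence mask at a variance quantile
#'
#' Marks the grid cells whose Kriging variance lies at or below the
#' empirical q-quantile of variance over the whole grid — the "top q
#' confidence" region (q = 0.25 reproduces a top-25%-confidence quartile
#' contour). Ties at the threshold are included, so a degenerate constant
#' variance field masks every cell.
#'
#' @param landscape a `phenotype_landscape`.
#' @param q confidence fraction in (0, 1].
#' @return the landscape with a logical column `in_confidence` added (the
#'   quantile threshold is returned as attribute `sigma2_threshold`).
#' @export
confidence_mask <- function(landscape, q = 0.25) {
  if (q <= 0 || q > 1) abort("`q` must lie in (0, 1]",
                             class = "vsp_domain_error")
  thr <- as.numeric(quantile(landscape$sigma2, q, type = 7))
  out <- landscape
  out$in_confidence <- landscape$sigma2 <= thr
  attr(out, "sigma2_threshold") <- thr
  attr(out, "confidence_q") <- q
  out
}

#' Difference between two phenotype landscapes
#'
#' Cell-wise delta `b - a` of the predictions, for comparing conditions
#' (e.g. drug-treated versus control runs of the same variants). The
#' variance of the delta is taken as `a.sigma2 + b.sigma2`
#' (independent-error convention).
#'
#' @param a,b `phenotype_landscape`s on identical grids.
#' @return `phenotype_landscape` of the delta.
#' @export
delta_landscape <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !isTRUE(all.equal(a$x, b$x)) || !isTRUE(all.equal(a$y, b$y))) {
    abort("landscapes must share an identical grid", class = "vsp_shape_error")
  }
  out <- a
  out$z_hat <- b$z_hat - a$z_hat
  out$sigma2 <- a$sigma2 + b$sigma2
  attr(out, "provenance") <- paste0("delta[", attr(a, "provenance"), " -> ",
                                    attr(b, "provenance"), "]")
  out
}

#' Write a landscape grid to TSV
#'
#' @param landscape a `phenotype_landscape` (optionally with a confidence
#'   mask column).
#' @param path output TSV path.
#' @return `path`, invisibly. The provenance fingerprint is written as a
#'   leading `#`-comment line.
#' @export
write_landscape <- function(landscape, path) {
  writeLines(paste0("# vsprofiler ", utils::packageVersion("vsprofiler"),
                    " | ", attr(landscape, "provenance")), path)
  readr::write_tsv(tibble::as_tibble(landscape), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Heatmap of a phenotype landscape
#'
#' Prediction heatmap with the observations overplotted; if the landscape
#' carries a confidence mask, its boundary is drawn as a contour.
#'
#' @param object a `phenotype_landscape`.
#' @param dataset optional `variant_tbl` to overplot as points.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot phenotype_landscape
#' @export
autoplot.phenotype_landscape <- function(object, dataset = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z_hat)) +
    ggplot2::scale_fill_viridis_c(name = "z*") +
    ggplot2::labs(x = "sequence position (normalized)",
                  y = "functional coordinate") +
    ggplot2::theme_minimal()
  if ("in_confidence" %in% names(object)) {
    p <- p + ggplot2::geom_contour(
      ggplot2::aes(z = as.numeric(.data$in_confidence)),
      breaks = 0.5, colour = "black", linewidth = 0.7)
  }
  if (!is.null(dataset)) {
    p <- p + ggplot2::geom_point(
      data = tibble::as_tibble(dataset),
      ggplot2::aes(.data$x, .data$y), shape = 21, fill = "white",
      colour = "black", size = 1.6)
  }
  p
}
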