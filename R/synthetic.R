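#' Simulate a Gaussian random field with a known variogram
#'
#' Draws n points in the unit (x, y) plane and a response z from a
#' mean-plus-Gaussian-field model whose spatial covariance is implied by
#' the supplied variogram model: `C_ij = C(0) - gamma(h_ij)` off the
#' diagonal and `C(0) = nugget + psill` on it, so the nugget acts as
#' independent micro-scale noise. z is `mean + L' e` where `L` is the
#' Cholesky factor of the covariance matrix (jittered by 1e-10 I) and `e`
#' is standard normal. Deterministic for a fixed seed.
#'
#' @param model a `variogram_model` describing the field.
#' @param n_points number of observations (>= 2).
#' @param mean baseline response level.
#' @param sampler "uniform" scatters coordinates independently;
#'   "clustered" draws them around a few seeded cluster centers, mimicking
#'   the uneven sequence coverage of real variant panels.
#' @param protein_length nominal protein length used to back out integer
#'   residue positions from x.
#' @param seed integer seed.
#' @param condition condition tag for the resulting dataset.
#' @return a `variant_tbl`.
#' @export
simulate_field <- function(model, n_points = 100, mean = 0,
                           sampler = c("uniform", "clustered"),
                           protein_length = 1278L, seed = 1L,
                           condition = "CTL") {
  sampler <- match.arg(sampler)
  if (n_points < 2) abort("need n_points >= 2", class = "vsp_domain_error")
  withr::with_seed(as.integer(seed), {
    if (sampler == "uniform") {
      x <- runif(n_points); y <- runif(n_points)
    } else {
      ncl <- max(3L, round(n_points / 15))
      cx <- runif(ncl); cy <- runif(ncl)
      pick <- sample(ncl, n_points, replace = TRUE)
      x <- pmin(pmax(rnorm(n_points, cx[pick], 0.05), 0), 1)
      y <- pmin(pmax(rnorm(n_points, cy[pick], 0.05), 0), 1)
    }
    z <- mean + .grf_draw(x, y, model, rnorm(n_points))
    df <- tibble::tibble(
      label = paste0("s", seq_len(n_points)),
      position = pmax(1L, pmin(protein_length,
                               as.integer(round(x * protein_length)))),
      y = y, z = z, condition = condition, is_null = FALSE)
    ds <- variant_dataset(df, protein_length)
    ds$x <- x  # keep the exact simulated coordinate, not position/length
    ds
  })
}

# Gaussian field draw at given coordinates from standard-normal eps
.grf_draw <- function(x, y, model, eps) {
  n <- length(x)
  if (sill(model) == 0) return(rep(0, n))
  d <- as.matrix(dist(cbind(x, y)))
  C <- matrix(model_covariance(model, as.numeric(d)), n, n)
  diag(C) <- sill(model)
  L <- tryCatch(chol(C + diag(1e-10, n)), error = function(e) {
    abort("covariance matrix not positive semi-definite after jitter",
          class = "vsp_spec_error")
  })
  as.numeric(crossprod(L, eps))
}

#' Paired control/treated variant fixtures with NPC1-like shape
#'
#' Generates a control and a treated dataset shaped like a real
#' disease-variant panel: `n_variants` variants scattered over a
#' `protein_length`-residue protein, a trafficking-index response TrIdx in
#' [0, 1] drawn from a spherical Gaussian field over the (sequence
#' position, cholesterol score) plane, and a cholesterol score with a
#' configurable negative correlation to TrIdx. Control defaults match the
#' spatial scale estimated for NPC1 trafficking (spherical range 0.19,
#' sill 0.05, mean TrIdx 0.35 so that clipping to [0, 1] is negligible).
#' The treated condition reuses the same standard-normal draw with the
#' range and sill both multiplied by `condition_effect`, emulating a
#' proteostasis modulator that shrinks both the correlation length and the
#' plateau variance; `condition_effect = 1` reproduces the control
#' exactly. The treated mean TrIdx is raised by `treated_shift`
#' (drug-corrected trafficking).
#'
#' @param n_variants number of variants (>= 10; default 48).
#' @param protein_length residues (default 1278).
#' @param condition_effect multiplier in (0, 1] applied to the treated
#'   range and sill (default 0.6).
#' @param treated_shift additive TrIdx shift in the treated condition
#'   (default 0.15).
#' @param range,sill_z control spherical range and sill of the TrIdx field.
#' @param chol_range,chol_sill spherical parameters of the 1-d cholesterol
#'   field along the sequence axis.
#' @param target_cor target TrIdx-cholesterol correlation in the control
#'   condition (default -0.36).
#' @param mean_tridx control mean TrIdx.
#' @param seed integer seed.
#' @return named list of two `variant_tbl`s: `ctl` and `treated`.
#' @export
make_npc1_like_fixture <- function(n_variants = 48L, protein_length = 1278L,
                                   condition_effect = 0.6,
                                   treated_shift = 0.15,
                                   range = 0.19, sill_z = 0.05,
                                   chol_range = 0.08, chol_sill = 0.02,
                                   target_cor = -0.36, mean_tridx = 0.35,
                                   seed = 1L) {
  if (n_variants < 10) abort("need at least 10 variants",
                             class = "vsp_domain_error")
  if (condition_effect <= 0 || condition_effect > 1) {
    abort("`condition_effect` must lie in (0, 1]", class = "vsp_domain_error")
  }
  withr::with_seed(as.integer(seed), {
    positions <- sort(sample(protein_length, n_variants))
    x <- positions / protein_length
    # cholesterol score: smooth 1-d field along the sequence, centred on 1
    # (reference-normalized scale)
    chol_model <- variogram_model("spherical", nugget = 0,
                                  psill = chol_sill, range = chol_range)
    chol <- 1 + .grf_draw(x, rep(0, n_variants), chol_model,
                          rnorm(n_variants))
    # TrIdx: spherical field over the (x, chol) plane, then blended with
    # the cholesterol axis to hit the target correlation
    z_model <- variogram_model("spherical", nugget = 0, psill = sill_z,
                               range = range)
    eps <- rnorm(n_variants)
    t_raw <- .grf_draw(x, chol, z_model, eps)
    t_std <- as.numeric(scale(t_raw))
    c_std <- as.numeric(scale(chol))
    resid <- as.numeric(scale(t_std - c_std * sum(t_std * c_std) /
                                sum(c_std^2)))
    t_mix <- target_cor * c_std + sqrt(1 - target_cor^2) * resid
    tridx_ctl <- pmin(pmax(mean_tridx + sqrt(sill_z) * t_mix, 0), 1)
    ctl <- variant_dataset(tibble::tibble(
      label = paste0("V", positions),
      position = positions, y = chol, z = tridx_ctl,
      condition = "CTL", is_null = FALSE), protein_length,
      axes = list(y = "Chol", z = "TrIdx", normalize = "reference",
                  reference = "synthetic"))
    # treated: same standard-normal draw, shrunk covariance
    zt_model <- variogram_model("spherical", nugget = 0,
                                psill = sill_z * condition_effect,
                                range = range * condition_effect)
    if (condition_effect == 1) {
      tridx_trt <- tridx_ctl
      shift <- 0
    } else {
      t_raw_t <- .grf_draw(x, chol, zt_model, eps)
      t_std_t <- as.numeric(scale(t_raw_t))
      resid_t <- as.numeric(scale(t_std_t - c_std * sum(t_std_t * c_std) /
                                    sum(c_std^2)))
      t_mix_t <- target_cor * c_std + sqrt(1 - target_cor^2) * resid_t
      tridx_trt <- pmin(pmax(mean_tridx + treated_shift +
                               sqrt(sill_z * condition_effect) * t_mix_t,
                             0), 1)
      shift <- treated_shift
    }
    treated <- variant_dataset(tibble::tibble(
      label = paste0("V", positions),
      position = positions, y = chol, z = tridx_trt,
      condition = "treated", is_null = FALSE), protein_length,
      axes = list(y = "Chol", z = "TrIdx", normalize = "reference",
                  reference = "synthetic", treated_shift = shift))
    list(ctl = ctl, treated = treated)
  })
}
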