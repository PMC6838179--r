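test_that("pairwise semivariances follow the distance/semivariance formulas", {
  ds <- variant_dataset(
    tibble::tibble(position = c(1, 2), y = c(0, 0.4), z = c(1, 1)),
    protein_length = 10)
  ds$x <- c(0, 0.3)  # 3-4-5 triangle
  pr <- pairwise_semivariances(ds)
  expect_equal(pr$h, 0.5)
  expect_equal(pr$gamma, 0)  # equal z

  ds5 <- toy_dataset()
  pr5 <- pairwise_semivariances(ds5)
  expect_equal(nrow(pr5), 5 * 4 / 2)
  expect_equal(pr5$gamma[1], 0.5 * (0.1 - 0.4)^2)

  expect_error(pairwise_semivariances(ds5[1, ]),
               class = "vsp_insufficient_data")
})

test_that("semivariances are translation invariant and scale as s^2", {
  ds <- toy_dataset()
  pr <- pairwise_semivariances(ds)

  shifted <- ds; shifted$z <- ds$z + 5
  expect_equal(pairwise_semivariances(shifted)$gamma, pr$gamma)

  scaled <- ds; scaled$z <- ds$z * 3
  expect_equal(pairwise_semivariances(scaled)$gamma, pr$gamma * 9)
})

test_that("empirical variogram bins reproduce hand-computed means", {
  # 4 collinear points, z alternating 0/1; hand enumeration of the six
  # pairs: h = .1 three times (gamma .5 each), h = .2 twice (z equal both
  # times, gamma 0), h = .3 once (gamma .5)
  ds <- variant_dataset(
    tibble::tibble(position = c(1, 2, 3, 4), y = 0, z = c(0, 1, 0, 1)),
    protein_length = 10)
  ds$x <- c(0, 0.1, 0.2, 0.3)
  pr <- pairwise_semivariances(ds)
  emp <- empirical_variogram(pr, n_bins = 2, active_lag = 0.3)
  expect_equal(emp$n_pairs, c(3L, 3L))
  expect_equal(emp$gamma, c(mean(c(0.5, 0.5, 0.5)), mean(c(0, 0, 0.5))))

  # constant z field: every populated bin has zero semivariance
  const <- toy_dataset(z = rep(0.4, 5))
  empc <- empirical_variogram(pairwise_semivariances(const), n_bins = 3)
  expect_true(all(empc$gamma[empc$n_pairs > 0] == 0))

  # pairs beyond the active lag are excluded
  emp_cut <- empirical_variogram(pr, n_bins = 2, active_lag = 0.15)
  expect_equal(sum(emp_cut$n_pairs), 3L)
  expect_error(
    empirical_variogram(pr[pr$h > 0.2, ], n_bins = 2, active_lag = 0.05),
    class = "vsp_empty_variogram")
})

test_that("variogram families evaluate to their closed forms", {
  sph <- variogram_model("spherical", nugget = 0, psill = 1, range = 1)
  expect_equal(model_gamma(sph, 0), 0)       # exact-interpolation convention
  expect_equal(model_gamma(sph, 0.5), 0.6875)
  expect_equal(model_gamma(sph, c(1, 2, 10)), rep(1, 3))  # plateau

  with_nug <- variogram_model("spherical", 0.2, 0.8, 0.5)
  expect_equal(model_gamma(with_nug, 0), 0)
  expect_gt(model_gamma(with_nug, 1e-9), 0.2)  # nugget jump at h -> 0+
  expect_equal(model_covariance(with_nug, 0), 1)

  lin <- variogram_model("linear", 0, 1, 2)
  expect_equal(model_gamma(lin, 1), 0.5)
  expect_equal(model_gamma(lin, 3), 1)

  ex <- variogram_model("exponential", 0, 1, 1)
  expect_equal(model_gamma(ex, 1), 1 - exp(-3))
  ga <- variogram_model("gaussian", 0, 1, 1)
  expect_equal(model_gamma(ga, 0.5), 1 - exp(-0.75))

  expect_error(model_gamma(sph, -0.1), class = "vsp_domain_error")
  # covariance consistency: C(0) - gamma(h) >= 0, exactly 0 beyond range
  h <- seq(0, 2, by = 0.01)
  for (m in list(sph, with_nug, lin, ex, ga)) {
    expect_true(all(model_covariance(m, h) >= -1e-12))
  }
  expect_equal(model_covariance(sph, c(1, 1.5)), c(0, 0))
})

test_that("noiseless spherical bins are recovered to 1e-6 relative error", {
  true <- variogram_model("spherical", 0.01, 0.04, 0.19)
  h <- seq(0.015, 0.33, length.out = 12)
  emp <- structure(
    tibble::tibble(bin_lo = h - 0.01, bin_hi = h + 0.01, bin_center = h,
                   gamma = model_gamma(true, h), n_pairs = 50L),
    active_lag = 0.34, class = c("empirical_variogram", "tbl_df", "tbl",
                                 "data.frame"))
  fit <- fit_variogram(emp, "spherical")
  expect_equal(fit$nugget, true$nugget, tolerance = 1e-6)
  expect_equal(fit$psill, true$psill, tolerance = 1e-6)
  expect_equal(fit$range, true$range, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("fitted parameters scale with z^2 while the range is unchanged", {
  ds <- simulate_field(variogram_model("spherical", 0, 0.05, 0.2),
                       n_points = 120, mean = 0.4, seed = 11)
  emp <- empirical_variogram(pairwise_semivariances(ds))
  fit <- fit_variogram(emp)

  scaled <- ds; scaled$z <- ds$z * 2
  emp2 <- empirical_variogram(pairwise_semivariances(scaled))
  fit2 <- fit_variogram(emp2)
  expect_equal(fit2$nugget, 4 * fit$nugget, tolerance = 1e-4)
  expect_equal(fit2$psill, 4 * fit$psill, tolerance = 1e-4)
  expect_equal(fit2$range, fit$range, tolerance = 1e-4)

  shifted <- ds; shifted$z <- ds$z + 3
  fit3 <- fit_variogram(empirical_variogram(pairwise_semivariances(shifted)))
  expect_equal(glance(fit3), glance(fit), tolerance = 1e-6)
})

test_that("degenerate all-equal bins yield a pure-nugget model with warning", {
  emp <- structure(
    tibble::tibble(bin_lo = c(0, .1, .2), bin_hi = c(.1, .2, .3),
                   bin_center = c(.05, .15, .25), gamma = rep(0.3, 3),
                   n_pairs = 10L),
    active_lag = 0.3, class = c("empirical_variogram", "tbl_df", "tbl",
                                "data.frame"))
  expect_warning(fit <- fit_variogram(emp), class = "vsp_degenerate_fit")
  expect_equal(fit$psill, 0)
  expect_equal(fit$nugget, 0.3)
})

test_that("simulated empirical variograms track the generating model", {
  true <- variogram_model("spherical", 0, 1, 0.3)
  ds <- simulate_field(true, n_points = 400, seed = 5)
  emp <- empirical_variogram(pairwise_semivariances(ds), n_bins = 10,
                             active_lag = 0.5)
  expected <- model_gamma(true, emp$bin_center)
  # Monte-Carlo wiggle: bin means within a generous band of the true curve
  expect_true(all(abs(emp$gamma - expected) < 0.35))
  expect_lt(mean(abs(emp$gamma - expected)), 0.12)
})

test_that("broom-style accessors expose the fit", {
  m <- variogram_model("spherical", 0.01, 0.04, 0.19, rss = 1e-4)
  td <- tidy(m)
  expect_equal(td$estimate[td$term == "sill"], 0.05)
  gl <- glance(m)
  expect_equal(gl$range, 0.19)
  expect_equal(gl$family, "spherical")
  p <- autoplot(
    empirical_variogram(pairwise_semivariances(toy_dataset()), n_bins = 3),
    model = m)
  expect_s3_class(p, "ggplot")
})
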