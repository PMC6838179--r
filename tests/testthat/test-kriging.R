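test_that("neighbor selection honours radius, caps, floor and ties", {
  ds <- toy_dataset()
  pol <- neighborhood_policy(min_n = 5, max_n = 20, search_radius = 0.01)
  # min_n floor: only 5 observations, radius excludes all, still get 5
  nb <- select_neighbors(c(0.5, 0.5), ds, pol)
  expect_equal(sort(nb), 1:5)

  # a target coincident with an observation sorts that observation first
  nb2 <- select_neighbors(c(ds$x[3], ds$y[3]), ds,
                          neighborhood_policy(1, 3))
  expect_equal(nb2[1], 3L)

  expect_error(select_neighbors(c(0, 0), ds[1:3, ],
                                neighborhood_policy(5, 20)),
               class = "vsp_insufficient_data")
})

test_that("neighbor selection matches a brute-force distance sort", {
  withr::with_seed(42, {
    n <- 100
    ds <- variant_dataset(
      tibble::tibble(position = sample(1000, n), y = runif(n),
                     z = runif(n)),
      protein_length = 1000)
    ds$x <- runif(n)
    u <- c(0.4, 0.6)
    d <- sqrt((ds$x - u[1])^2 + (ds$y - u[2])^2)
    radius <- sort(d)[30]  # radius covering 30 points
    pol <- neighborhood_policy(5, 20, radius)
    nb <- select_neighbors(u, ds, pol)
    expect_length(nb, 20)
    expect_equal(nb, order(d)[1:20])
  })
})

test_that("the ordinary-Kriging system satisfies its structural identities", {
  model <- variogram_model("spherical", 0, 0.05, 0.3)
  ds <- toy_dataset()

  # single neighbor: weight 1, prediction equals that z
  sol1 <- solve_kriging(c(0.2, 0.3), 2L, model, ds)
  expect_equal(sol1$weights, 1)
  expect_equal(sol1$prediction, ds$z[2])

  # two neighbors symmetric about the target share the weight equally
  sym <- variant_dataset(
    tibble::tibble(position = c(25, 75), y = c(0.5, 0.5), z = c(0, 1)),
    protein_length = 100)
  sol2 <- solve_kriging(c(0.5, 0.5), 1:2, model, sym)
  expect_equal(sol2$weights, c(0.5, 0.5))
  expect_equal(sol2$prediction, 0.5)

  # weights sum to one for arbitrary targets
  for (u in list(c(0.1, 0.9), c(0.7, 0.2), c(0.44, 0.55))) {
    sol <- solve_kriging(u, 1:5, model, ds)
    expect_lt(abs(sum(sol$weights) - 1), 1e-10)
    expect_gte(sol$variance, 0)
  }

  # coincident duplicated observations are named in the singularity error
  dup <- suppressWarnings(variant_dataset(
    tibble::tibble(label = c("d1", "d2", "e3"),
                   position = c(10, 10, 50), y = c(0.1, 0.1, 0.9),
                   z = c(0, 1, 2)),
    protein_length = 100))
  # jitter makes the duplicate solvable rather than singular
  sol_dup <- solve_kriging(c(0.3, 0.3), 1:3, model, dup)
  expect_lt(abs(sum(sol_dup$weights) - 1), 1e-10)
})

test_that("prediction matches the independent dense semivariogram oracle", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      k <- sample(5:10, 1)
      x <- runif(k); y <- runif(k); z <- runif(k)
      ds <- variant_dataset(
        tibble::tibble(position = seq_len(k), y = y, z = z),
        protein_length = 1000)
      ds$x <- x
      model <- variogram_model("spherical", runif(1, 0, 0.02),
                               runif(1, 0.02, 0.1), runif(1, 0.1, 0.5))
      u <- runif(2)
      got <- solve_kriging(u, seq_len(k), model, ds)
      want <- dense_ok_oracle(u, x, y, z, model)
      expect_equal(got$prediction, want$z_hat, tolerance = 1e-10)
      expect_equal(got$variance, want$sigma2, tolerance = 1e-8)
      expect_equal(got$weights, as.numeric(want$weights), tolerance = 1e-8)
    }
  })
})

test_that("Kriging interpolates exactly and is unbiased for constants", {
  model <- variogram_model("spherical", 0, 0.05, 0.3)
  ds <- toy_dataset()
  # exact interpolation at an observation with zero nugget
  p <- predict_point(c(ds$x[2], ds$y[2]), ds, model,
                     neighborhood_policy(3, 5))
  expect_equal(p[["z_hat"]], ds$z[2], tolerance = 1e-9)
  expect_lt(p[["sigma2"]], 1e-10)

  # constant field predicts the constant everywhere
  const <- toy_dataset(z = rep(0.7, 5))
  for (u in list(c(0.05, 0.1), c(0.5, 0.5), c(0.95, 0.2))) {
    pc <- predict_point(u, const, model, neighborhood_policy(3, 5))
    expect_equal(pc[["z_hat"]], 0.7, tolerance = 1e-10)
  }

  # far beyond the range: variance approaches the sill, prediction the
  # neighborhood mean (all covariances vanish, weights equalize)
  far <- predict_point(c(25, 25), ds, model, neighborhood_policy(5, 5))
  expect_equal(far[["z_hat"]], mean(ds$z), tolerance = 1e-9)
  expect_equal(far[["sigma2"]], sill(model) * (1 + 1 / 5), tolerance = 1e-9)
})

test_that("prediction is equivariant under translation and scaling of z", {
  model <- variogram_model("spherical", 0.002, 0.05, 0.3)
  ds <- toy_dataset()
  u <- c(0.45, 0.55)
  pol <- neighborhood_policy(3, 5)
  base <- predict_point(u, ds, model, pol)

  shifted <- ds; shifted$z <- ds$z + 2.5
  ps <- predict_point(u, shifted, model, pol)
  expect_equal(ps[["z_hat"]], base[["z_hat"]] + 2.5, tolerance = 1e-10)
  expect_equal(ps[["sigma2"]], base[["sigma2"]], tolerance = 1e-12)

  # scaling z by s requires scaling the variogram by s^2; prediction then
  # scales by s and the Kriging variance by s^2
  s <- 3
  scaled <- ds; scaled$z <- ds$z * s
  model_s <- variogram_model("spherical", model$nugget * s^2,
                             model$psill * s^2, model$range)
  psc <- predict_point(u, scaled, model_s, pol)
  expect_equal(psc[["z_hat"]], base[["z_hat"]] * s, tolerance = 1e-10)
  expect_equal(psc[["sigma2"]], base[["sigma2"]] * s^2, tolerance = 1e-10)
})

test_that("local prediction with max_n >= n equals the global solve", {
  withr::with_seed(13, {
    model <- variogram_model("spherical", 0.001, 0.04, 0.25)
    n <- 30
    ds <- variant_dataset(
      tibble::tibble(position = sample(500, n), y = runif(n), z = runif(n)),
      protein_length = 500)
    ds$x <- runif(n)
    u <- c(0.5, 0.5)
    local <- predict_point(u, ds, model,
                           neighborhood_policy(5, n, search_radius = Inf))
    global <- solve_kriging(u, seq_len(n), model, ds)
    expect_equal(local[["z_hat"]], global$prediction, tolerance = 1e-12)
    expect_equal(local[["sigma2"]], global$variance, tolerance = 1e-12)
  })
})

test_that("standardized LOO residuals are calibrated on simulated fields", {
  true <- variogram_model("spherical", 0.005, 0.05, 0.25)
  ds <- simulate_field(true, n_points = 300, mean = 0.5, seed = 3)
  cv <- loo_cv(ds, model = true, policy = neighborhood_policy(5, 20))
  pp <- tidy(cv)
  std <- (pp$observed - pp$predicted) / sqrt(pp$sigma2)
  expect_lt(abs(mean(std)), 0.15)
  expect_lt(abs(stats::var(std) - 1), 0.15)
})
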