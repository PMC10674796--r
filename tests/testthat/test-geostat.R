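test_that("spherical_gamma matches its closed form and is monotone", {
  m <- variogram_model(0.19, 0.54, 130.4)
  expect_equal(spherical_gamma(m, 0), 0)
  expect_equal(spherical_gamma(m, 65.2), 0.19 + 0.54 * 0.6875)
  expect_equal(spherical_gamma(m, 130.4), 0.73)
  expect_equal(spherical_gamma(m, 500), 0.73)
  h <- seq(0.1, 400, by = 0.5)
  g <- spherical_gamma(m, h)
  expect_true(all(diff(g) >= -1e-12))
  expect_true(all(g[h > 130.4] == 0.73))
  expect_error(spherical_gamma(m, -1), "negative")
})

test_that("nugget_sill_ratio classifies spatial dependence", {
  m <- variogram_model(0.19, 0.54, 130.4)
  r <- nugget_sill_ratio(m)
  expect_equal(r$percent, 100 * 0.19 / 0.73)
  expect_equal(nugget_sill_ratio(variogram_model(0, 1, 10))$percent, 0)
  expect_equal(nugget_sill_ratio(variogram_model(0, 1, 10))$dependence_class, "strong")
  pure <- nugget_sill_ratio(variogram_model(1, 0, 10))
  expect_equal(pure$percent, 100)
  expect_equal(pure$dependence_class, "weak")
  expect_error(nugget_sill_ratio(variogram_model(0, 0, 10)), "zero total sill")
})

test_that("empirical variogram matches definition and brute-force enumeration", {
  # two points, distance 10, values 0 and 2: one bin, gamma = 2
  s <- point_survey(c(0, 10), c(0, 0), c(0, 2))
  ev <- empirical_variogram(s, lag_width = 5, max_lag = 20)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$gamma, 2)
  expect_equal(ev$n_pairs, 1L)

  # constant survey: zero semivariance everywhere
  set.seed(5)
  sc <- point_survey(runif(30, 0, 100), runif(30, 0, 100), rep(7, 30))
  evc <- empirical_variogram(sc, lag_width = 10, max_lag = 60)
  expect_true(all(evc$gamma == 0))

  # 200 points vs O(n^2) oracle
  set.seed(11)
  x <- runif(200, 0, 100); y <- runif(200, 0, 100); v <- rnorm(200)
  sp <- point_survey(x, y, v)
  breaks <- seq(0, 60, by = 10)
  ev2 <- empirical_variogram(sp, lag_width = 10, max_lag = 60)
  bf <- brute_variogram(x, y, v, breaks)
  expect_equal(ev2$n_pairs, bf$n)
  expect_equal(ev2$gamma, bf$gamma, tolerance = 1e-12)

  expect_error(empirical_variogram(s, lag_width = 1, max_lag = 5), "no point pair")
})

test_that("fit_variogram recovers noiseless and noisy spherical parameters", {
  truth <- variogram_model(0.19, 0.54, 130.4)
  h <- seq(10, 260, by = 10)
  emp <- tibble::tibble(lag = h, gamma = spherical_gamma(truth, h),
                        n_pairs = rep(100L, length(h)))
  class(emp) <- c("empirical_variogram", class(emp))
  fit <- fit_variogram(emp)
  expect_lt(abs(fit$nugget - 0.19) / 0.19, 0.01)
  expect_lt(abs(fit$psill - 0.54) / 0.54, 0.01)
  expect_lt(abs(fit$range_m - 130.4) / 130.4, 0.01)

  # flat (pure nugget) variogram: no identifiable range
  flat <- tibble::tibble(lag = h, gamma = rep(0.5, length(h)),
                         n_pairs = rep(50L, length(h)))
  class(flat) <- c("empirical_variogram", class(flat))
  ffit <- fit_variogram(flat)
  expect_false(attr(ffit, "range_identifiable"))
  expect_lt(ffit$psill, 1e-4)

  # 5% multiplicative noise, 50 replicates: median relative range error < 15%
  rel_err <- vapply(0:49, function(seed) {
    set.seed(seed)
    gn <- spherical_gamma(truth, h) * (1 + rnorm(length(h), 0, 0.05))
    en <- tibble::tibble(lag = h, gamma = pmax(gn, 1e-6),
                         n_pairs = rep(100L, length(h)))
    class(en) <- c("empirical_variogram", class(en))
    fn <- fit_variogram(en)
    abs(fn$range_m - 130.4) / 130.4
  }, numeric(1))
  expect_lt(median(rel_err), 0.15)
})

test_that("anisotropy ratio is near 1 for isotropic and near 2 for stretched fields", {
  tpl <- small_template(60, 60, 10)
  truth <- variogram_model(0.1, 0.9, 40)
  field <- simulate_gaussian_field(tpl, truth, mean = 0, sd = 1, seed = 7)
  sv <- simulate_survey(field, transect_spacing = 15, along_step = 10, seed = 7)
  iso <- anisotropy_ratio(sv, n_directions = 4, lag_width = 12, max_lag = 150)
  expect_gte(iso$ratio, 1)
  expect_lt(iso$ratio, 1.2)

  # geometric anisotropy: stretch x by 2 => range ratio ~ 2
  sx <- point_survey(sv$x * 2, sv$y, sv$value)
  an <- anisotropy_ratio(sx, n_directions = 4, lag_width = 15, max_lag = 250)
  expect_gt(an$ratio, 1.7)
  expect_lt(an$ratio, 2.5)
  expect_equal(an$major_azimuth_deg, 90)  # E-W after stretching x

  expect_error(anisotropy_ratio(point_survey(1:20, 20:1, rep(3, 20))),
               "no spatial structure")
})

test_that("kriging honours unbiasedness, symmetry and data points", {
  m <- variogram_model(0.2, 0.8, 50)
  # single data point: weight 1, estimate = datum
  one <- krige_points(point_survey(0, 0, 7), m, tibble::tibble(x = 3, y = 4),
                      max_neighbors = 4, search_radius = 100)
  expect_equal(one$estimate, 7)
  expect_equal(one$weight_sum, 1, tolerance = 1e-10)
  expect_equal(one$se, sqrt(2 * spherical_gamma(m, 5)))

  # midpoint of two equidistant points: weights (0.5, 0.5)
  two <- point_survey(c(0, 10), c(0, 0), c(5, 9))
  mid <- krige_points(two, m, tibble::tibble(x = 5, y = 0),
                      max_neighbors = 4, search_radius = 100)
  expect_equal(mid$estimate, 7)

  # exact interpolation at a data location, even with a nugget
  atdat <- krige_points(two, m, tibble::tibble(x = 0, y = 0),
                        max_neighbors = 4, search_radius = 100)
  expect_equal(atdat$estimate, 5, tolerance = 1e-10)
  expect_equal(atdat$se, 0, tolerance = 1e-6)
})

test_that("neighbourhood kriging equals the full-system solve when all points are used", {
  set.seed(3)
  n <- 20
  x <- runif(n, 0, 100); y <- runif(n, 0, 100); z <- rnorm(n, 10, 3)
  pts <- point_survey(x, y, z)
  m <- variogram_model(0.2, 0.8, 50)
  tpl <- raster_grid(matrix(0, 5, 5), cell_size = 20)
  kr <- ordinary_kriging(pts, m, tpl, max_neighbors = n, search_radius = 1e6)
  cells <- raster_to_tibble(tpl)
  bf <- brute_krige(x, y, z, m, cells$x, cells$y)
  est <- kr$estimate$values[cbind(cells$row, cells$col)]
  expect_lt(max(abs(est - bf)), 1e-8)

  # weights sum to one at every estimated location
  kp <- krige_points(pts, m, cells, max_neighbors = 8, search_radius = 1e6)
  expect_true(all(abs(kp$weight_sum - 1) < 1e-8))
})

test_that("LOO cross-validation returns calibrated, hand-checkable diagnostics", {
  m <- variogram_model(0.1, 0.9, 50)
  # constant field: zero errors
  set.seed(8)
  sc <- point_survey(runif(20, 0, 100), runif(20, 0, 100), rep(5, 20))
  cvc <- loo_cross_validation(sc, m, max_neighbors = 10)
  expect_equal(cvc$rmse, 0, tolerance = 1e-10)
  expect_equal(cvc$mean_error, 0, tolerance = 1e-10)

  # 3 + a few points: statistics equal explicit per-point LOO solves
  set.seed(12)
  x <- runif(12, 0, 50); y <- runif(12, 0, 50); z <- rnorm(12, 10, 2)
  s <- point_survey(x, y, z)
  cv <- loo_cross_validation(s, m, max_neighbors = 11, search_radius = 1e6)
  pred <- vapply(1:12, function(i) {
    brute_krige(x[-i], y[-i], z[-i], m, x[i], y[i])
  }, numeric(1))
  expect_equal(cv$rmse, sqrt(mean((pred - z)^2)), tolerance = 1e-8)
  expect_equal(cv$mean_error, mean(pred - z), tolerance = 1e-8)
  expect_equal(cv$data_sd, sd(z))

  # calibration on a field simulated from the model itself
  tpl <- small_template(35, 35, 10)
  truth <- variogram_model(0.26, 0.74, 130)
  f <- simulate_gaussian_field(tpl, truth, mean = 50, sd = 10, seed = 11)
  sv <- simulate_survey(f, transect_spacing = 10, along_step = 20, seed = 11)
  mdl <- variogram_model(0.26 * 100, 0.74 * 100, 130)  # data-unit scaling
  cvf <- loo_cross_validation(sv, mdl, max_neighbors = 16)
  expect_lt(abs(cvf$mean_standardised_error), 0.1)
  expect_gt(cvf$mean_sq_standardised_error, 0.7)
  expect_lt(cvf$mean_sq_standardised_error, 1.3)
  expect_true(cvf$effective)
})

test_that("summary_stats agrees with direct textbook formulas", {
  s <- point_survey(1:3, 1:3, c(1, 2, 3))
  st <- summary_stats(s)
  expect_equal(st$mean, 2)
  expect_equal(st$median, 2)
  expect_equal(st$skewness, 0)

  sall <- summary_stats(point_survey(1:4, 1:4, rep(5, 4)))
  expect_equal(sall$cv_percent, 0)

  set.seed(3)
  v <- rlnorm(1000, 0, 0.5)
  st2 <- summary_stats(point_survey(seq_along(v), seq_along(v), v))
  n <- length(v); mu <- mean(v)
  m2 <- mean((v - mu)^2); m3 <- mean((v - mu)^3); m4 <- mean((v - mu)^4)
  expect_equal(st2$sd, sd(v), tolerance = 1e-10)
  expect_equal(st2$cv_percent, 100 * sd(v) / mu, tolerance = 1e-10)
  expect_equal(st2$skewness, sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5,
               tolerance = 1e-10)
  expect_equal(st2$kurtosis, m4 / m2^2, tolerance = 1e-10)
})
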