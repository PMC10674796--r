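test_that("categorize bins values with polarity and scheme options", {
  tb <- tibble::tibble(id = 1:5, prop = c(0, 25, 50, 75, 100))
  cm <- categorize(tb, items = "prop", m = 5)
  expect_equal(as.vector(unclass(cm)), c(1L, 2L, 3L, 4L, 5L))

  cmr <- categorize(tb, items = "prop", m = 5, polarity = c(prop = -1))
  expect_equal(as.vector(unclass(cmr)), c(5L, 4L, 3L, 2L, 1L))

  # quantile scheme on uniform draws: ~equal occupancy, matching a direct cut
  set.seed(2)
  tb2 <- tibble::tibble(id = 1:100, u = runif(100))
  cmq <- categorize(tb2, items = "u", m = 5, scheme = "quantile")
  counts <- tabulate(unclass(cmq), 5)
  expect_true(all(counts == 20))
  qs <- quantile(tb2$u, seq(0, 1, 0.2), names = FALSE)
  direct <- findInterval(tb2$u, qs, rightmost.closed = TRUE, all.inside = TRUE)
  expect_equal(as.vector(unclass(cmq)), direct)

  expect_error(categorize(tibble::tibble(id = 1:3, k = rep(1, 3)), items = "k"),
               "constant")
  # injected breaks override the scheme
  cmb <- categorize(tb, items = "prop", m = 2,
                    breaks = list(prop = c(-1, 60, 101)))
  expect_equal(as.vector(unclass(cmb)), c(1L, 1L, 1L, 2L, 2L))
})

test_that("dichotomous probability matches the logistic closed form", {
  expect_equal(dichotomous_probability(1.3, 1.3), 0.5)
  expect_equal(dichotomous_probability(log(3), 0), 0.75)
  expect_equal(dichotomous_probability(2, 0), plogis(2))
  expect_equal(dichotomous_probability(2, 0), exp(2) / (1 + exp(2)))
  # log-odds identity
  p <- dichotomous_probability(0.7, -0.4)
  expect_equal(log(p / (1 - p)), 1.1)
})

test_that("category probabilities normalise, nest the dichotomous case, and saturate", {
  set.seed(1)
  for (rep in 1:200) {
    m <- sample(2:7, 1)
    p <- category_probabilities(rnorm(1, 0, 2), rnorm(1), rnorm(m - 1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  # m = 2 with tau = 0 reduces exactly to the dichotomous model
  for (B in c(-2, 0, 1.5)) {
    p2 <- category_probabilities(B, 0.3, 0)
    expect_equal(p2[2], dichotomous_probability(B, 0.3), tolerance = 1e-12)
  }
  # B -> +inf pushes all mass to the top category
  ptop <- category_probabilities(30, 0, c(-1, 0, 1))
  expect_gt(ptop[4], 1 - 1e-9)
})

test_that("JMLE matches a brute-force grid search on a dichotomous toy matrix", {
  X01 <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 0), c(0, 1, 1))
  oracle <- oracle_jmle_grid(X01)
  fit <- fit_rating_scale(X01 + 1L, m = 2)
  expect_true(fit$convergence$converged)
  expect_lt(max(abs(fit$persons$measure - oracle$B)), 0.02)
  expect_lt(max(abs(fit$items$difficulty - oracle$d)), 0.02)
})

test_that("raw score and measure are strictly monotone within a calibration", {
  X <- draw_rsm_matrix(rnorm(40, 0, 1.5), c(-0.5, 0, 0.5, 1), c(-1, 0, 1), seed = 3)
  fit <- fit_rating_scale(X, m = 4)
  ne <- !fit$persons$extreme
  ord <- order(fit$persons$score_0based[ne])
  sc <- fit$persons$score_0based[ne][ord]
  ms <- fit$persons$measure[ne][ord]
  # equal scores -> equal measures; higher score -> strictly higher measure
  for (i in seq_len(length(sc) - 1)) {
    if (sc[i + 1] > sc[i]) expect_gt(ms[i + 1], ms[i])
    if (sc[i + 1] == sc[i]) expect_equal(ms[i + 1], ms[i], tolerance = 1e-6)
  }
})

test_that("JMLE recovers generating parameters on a 300 x 9 rating-scale design", {
  set.seed(42)
  d <- seq(-1, 1, length.out = 9); d <- d - mean(d)
  tau <- c(-1.2, -0.4, 0.4, 1.2)
  B <- rnorm(300, 0, 1.2)
  X <- draw_rsm_matrix(B, d, tau, seed = 42)
  fit <- fit_rating_scale(X, m = 5)
  expect_true(fit$convergence$converged)
  ne <- !fit$persons$extreme
  expect_gte(cor(B[ne], fit$persons$measure[ne]), 0.9)
  expect_lte(sqrt(mean((fit$items$difficulty - d)^2)), 0.25)
  expect_equal(mean(fit$items$difficulty), 0, tolerance = 1e-6)

  # estimating equations hold at convergence: observed = expected scores
  expect_lt(fit$convergence$max_score_residual, 0.01)
})

test_that("fit is invariant to person and item reordering", {
  X <- draw_rsm_matrix(rnorm(60), c(-0.8, -0.2, 0.3, 0.7), c(-0.9, 0, 0.9), seed = 6)
  colnames(X) <- paste0("it", 1:4)
  fit <- fit_rating_scale(X, m = 4)
  pp <- sample(nrow(X)); ii <- sample(ncol(X))
  fit2 <- fit_rating_scale(X[pp, ii], m = 4)
  expect_equal(fit2$persons$measure, fit$persons$measure[pp], tolerance = 1e-4)
  expect_equal(fit2$items$difficulty, fit$items$difficulty[ii], tolerance = 1e-4)
  expect_equal(fit2$thresholds, fit$thresholds, tolerance = 1e-4)
})

test_that("extreme scores get inward-adjusted finite measures, flagged", {
  X <- draw_rsm_matrix(rnorm(30), c(-0.5, 0, 0.5), c(-1, 0, 1), seed = 9)
  X[1, ] <- 1L   # minimum possible
  X[2, ] <- 4L   # maximum possible
  fit <- fit_rating_scale(X, m = 4)
  expect_true(all(fit$persons$extreme[1:2]))
  expect_true(all(is.finite(fit$persons$measure)))
  expect_lt(fit$persons$measure[1], min(fit$persons$measure[!fit$persons$extreme]))
  expect_gt(fit$persons$measure[2], max(fit$persons$measure[!fit$persons$extreme]))
})

test_that("infit/outfit sit near 1 under the model and flag a noise item", {
  set.seed(5)
  d <- seq(-1, 1, length.out = 6); d <- d - mean(d)
  tau <- c(-1, -0.3, 0.3, 1)
  B <- rnorm(400, 0, 1.2)
  X <- draw_rsm_matrix(B, d, tau, seed = 5)
  fit <- fit_rating_scale(X, m = 5)
  fs <- fit_statistics(X, fit)
  expect_true(all(fs$items$infit_mnsq > 0.8 & fs$items$infit_mnsq < 1.2))
  expect_true(all(fs$items$outfit_mnsq > 0.8 & fs$items$outfit_mnsq < 1.2))
  expect_true(all(fs$items$acceptable))

  # replace one item by pure noise: its outfit blows past 1.5
  set.seed(5)
  Xn <- X
  Xn[, 3] <- sample.int(5, nrow(X), replace = TRUE)
  fit2 <- fit_rating_scale(Xn, m = 5)
  fs2 <- fit_statistics(Xn, fit2)
  expect_gt(fs2$items$outfit_mnsq[3], 1.5)
  expect_false(fs2$items$acceptable[3])
})

test_that("extreme response strings do not influence item fit statistics", {
  X <- draw_rsm_matrix(rnorm(50), c(-0.5, 0, 0.5), c(-1, 0, 1), seed = 10)
  Xe <- rbind(X, rep(4L, 3))     # an all-maximum person
  fit_a <- fit_rating_scale(X, m = 4)
  fit_b <- fit_rating_scale(Xe, m = 4)
  fs_a <- fit_statistics(X, fit_a)
  fs_b <- fit_statistics(Xe, fit_b)
  expect_equal(fs_b$items$infit_mnsq, fs_a$items$infit_mnsq, tolerance = 1e-4)
  expect_equal(fs_b$items$outfit_mnsq, fs_a$items$outfit_mnsq, tolerance = 1e-4)
})

test_that("measures_by_zone averages person measures per zone", {
  X <- draw_rsm_matrix(rnorm(12), c(-0.5, 0.5), c(-1, 1), seed = 4)
  fit <- fit_rating_scale(X, m = 4)
  tb <- tibble::tibble(id = 1:12, zone = rep(1:3, each = 4))
  mz <- measures_by_zone(fit, tb)
  expect_equal(mz$n, rep(4L, 3))
  expect_equal(mz$mean_measure[1], mean(fit$persons$measure[1:4]))
  # permutation of the table leaves zone means unchanged
  mz2 <- measures_by_zone(fit, tb[sample(12), ])
  expect_equal(mz2, mz)
  # single-sample zone: mean equals the measure
  tb1 <- tibble::tibble(id = 1:12, zone = c(1, rep(2, 11)))
  mz1 <- measures_by_zone(fit, tb1)
  expect_equal(mz1$mean_measure[1], fit$persons$measure[1])
})

test_that("single-category items are dropped with a warning", {
  X <- draw_rsm_matrix(rnorm(20), c(-0.5, 0, 0.5), c(-1, 0, 1), seed = 11)
  colnames(X) <- c("a", "b", "c")
  X[, 2] <- 3L
  expect_warning(fit <- fit_rating_scale(X, m = 4), "single observed category")
  expect_equal(fit$items$item, c("a", "c"))
})

test_that("tidy and glance expose the fit in broom conventions", {
  X <- draw_rsm_matrix(rnorm(25), c(-0.5, 0, 0.5), c(-1, 0, 1), seed = 12)
  fit <- fit_rating_scale(X, m = 4)
  ti <- tidy(fit, "items")
  expect_named(ti, c("term", "estimate", "std.error"))
  expect_equal(nrow(ti), 3)
  gl <- glance(fit)
  expect_equal(gl$n_persons, 25)
  expect_true(gl$converged)
})
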