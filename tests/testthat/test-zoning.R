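test_that("stack_and_standardize z-scores layers and propagates masks", {
  g <- raster_grid(matrix(c(1, 2, 3), 1, 3), cell_size = 1)
  stk <- stack_and_standardize(list(g), "a")
  # population SD of (1,2,3) is sqrt(2/3)
  expect_equal(as.vector(stk$layers[[1]]$values),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(stk$standardization$mean, 2)

  # identical layers standardize identically
  stk2 <- stack_and_standardize(list(g, g), c("a", "b"))
  expect_equal(stk2$layers[[1]]$values, stk2$layers[[2]]$values)

  # nodata in one layer invalidates the cell in the stack
  g2 <- raster_grid(matrix(c(1, NA, 3), 1, 3), cell_size = 1)
  stk3 <- stack_and_standardize(list(g, g2), c("a", "b"))
  expect_equal(sum(stk3$valid), 2)
  expect_true(is.na(stk3$layers[[1]]$values[1, 2]))

  gbad <- raster_grid(matrix(0, 2, 2), cell_size = 2)
  expect_error(stack_and_standardize(list(g, gbad)), "geometries differ")
  gconst <- raster_grid(matrix(5, 1, 3), cell_size = 1)
  expect_error(stack_and_standardize(list(gconst)), "zero variance")
})

test_that("isodata clustering recovers separated clouds and rejects degenerate input", {
  bs <- blob_stack(small_template(30, 30, 10), k = 2, seed = 0)
  zm <- isodata_cluster(bs$stack, k = 2, seed = 0)
  # cluster means (standardized units) sit near the generating blob centres
  sm <- sort(zm$means[, "eca"])
  truth_means <- sort(tapply(
    bs$stack$layers[[1]]$values[bs$stack$valid],
    bs$truth$values[bs$stack$valid], mean
  ))
  expect_lt(max(abs(sm - truth_means)), 0.05)

  const <- raster_grid(matrix(7, 10, 10), cell_size = 1)
  noise <- raster_grid(matrix(rnorm(100), 10, 10), cell_size = 1)
  expect_error(isodata_cluster(stack_and_standardize(list(const)), k = 2))

  # k = 1: single signature = global mean/covariance of the standardized stack
  stk1 <- stack_and_standardize(list(noise))
  one <- isodata_cluster(stk1, k = 1, seed = 0)
  expect_equal(one$k, 1)
  zvals <- stk1$layers[[1]]$values[stk1$valid]
  expect_equal(as.vector(one$means), mean(zvals), tolerance = 1e-10)
  expect_equal(one$covs[[1]][1, 1], var(zvals), tolerance = 1e-10)
})

test_that("mlc_classify follows Gaussian likelihoods with deterministic ties", {
  # build a 2-feature stack manually: means at (0,0); covariances s2*I vs 4 s2*I
  vals1 <- matrix(c(0, 3, 0.1, -3), 2, 2)
  g1 <- raster_grid(vals1, cell_size = 1)
  stk <- list(
    layers = list(g1), layer_names = "f1",
    valid = !is.na(vals1),
    standardization = tibble::tibble(layer = "f1", mean = 0, sd = 1),
    geometry = g1
  )
  class(stk) <- "feature_stack"
  model <- structure(list(
    k = 2, means = matrix(c(0, 0), 2, 1), covs = list(matrix(1), matrix(4)),
    priors = c(0.5, 0.5), sizes = c(1, 1), layer_names = "f1"
  ), class = "zone_model")
  zm <- mlc_classify(stk, model)
  # near the shared mean the narrow class wins; in the tails the wide one
  expect_equal(zm$values[1, 1], 1)  # value 0
  expect_equal(zm$values[1, 2], 1)  # value 0.1
  expect_equal(zm$values[2, 1], 2)  # value 3
  expect_equal(zm$values[2, 2], 2)  # value -3
  # crossover where densities are equal: |x| = sqrt(8/3 log 2)
  xc <- sqrt(8 / 3 * log(2))
  g2 <- raster_grid(matrix(c(xc - 0.01, xc + 0.01), 1, 2), cell_size = 1)
  stk$layers[[1]] <- g2; stk$valid <- !is.na(g2$values); stk$geometry <- g2
  zm2 <- mlc_classify(stk, model)
  expect_equal(as.vector(zm2$values[1, ]), c(1, 2))
})

test_that("classification of separated blobs agrees with clustering and truth", {
  for (seed in 0:4) {
    bs <- blob_stack(small_template(40, 40, 10), k = 3, seed = seed)
    zm <- isodata_cluster(bs$stack, k = 3, seed = seed)
    zmap <- mlc_classify(bs$stack, zm)
    # MLC agrees with the training assignment on separated blobs
    agree <- mean(zmap$values[zm$cell_idx] == zm$assignment)
    expect_gte(agree, 0.95)
    ordered <- order_zones(zmap, bs$eca)
    expect_gte(ari(ordered$values, bs$truth$values), 0.95)
  }
})

test_that("order_zones relabels by zone-mean ECa and is idempotent", {
  lab <- raster_grid(matrix(c(1, 1, 2, 2), 2, 2), cell_size = 1)
  attr(lab, "k") <- 2
  class(lab) <- c("zone_map", class(lab))
  eca <- raster_grid(matrix(c(50, 50, 10, 10), 2, 2), cell_size = 1)
  oz <- order_zones(lab, eca)
  expect_equal(as.vector(oz$values), c(2, 2, 1, 1))
  # idempotence on an already-ordered map
  oz2 <- order_zones(oz, eca)
  expect_equal(oz2$values, oz$values)

  # ordering matches brute-force per-zone means on a simulated map
  bs <- blob_stack(small_template(20, 20, 10), k = 3, seed = 2)
  zm <- isodata_cluster(bs$stack, k = 3, seed = 2)
  zmap <- mlc_classify(bs$stack, zm)
  ordered <- order_zones(zmap, bs$eca)
  mm <- tapply(bs$eca$values[!is.na(ordered$values)],
               ordered$values[!is.na(ordered$values)], mean)
  expect_true(all(diff(mm) > 0))
  # relabeling preserves the partition
  expect_gte(ari(ordered$values, zmap$values), 0.999)
})

test_that("allocate_samples apportions by largest remainder with floor 1", {
  expect_equal(largest_remainder(c(0.35, 0.45, 0.20), 20), c(7L, 9L, 4L))
  expect_equal(largest_remainder(c(1, 1, 1), 3), c(1L, 1L, 1L))
  expect_equal(largest_remainder(c(0.50, 0.30, 0.20), 7), c(4L, 2L, 1L))

  # zone raster with areas 35%, 45%, 20%
  lab <- c(rep(1, 35), rep(2, 45), rep(3, 20))
  zg <- raster_grid(matrix(lab, 10, 10), cell_size = 5)
  attr(zg, "k") <- 3
  class(zg) <- c("zone_map", class(zg))
  plan <- allocate_samples(zg, 20, seed = 1)
  expect_equal(attr(plan, "counts"), c(7L, 9L, 4L))
  expect_equal(nrow(plan), 20)
  expect_equal(as.vector(table(plan$zone)), c(7, 9, 4))
  # sampled coordinates fall inside their zone's cells
  idx <- raster_cell_index(zg, plan$x, plan$y)
  expect_equal(zg$values[cbind(idx$row, idx$col)], as.numeric(plan$zone))
  expect_error(allocate_samples(zg, 2), "at least")
})
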