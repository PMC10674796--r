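# Independent oracles and shared fixture builders. Oracles are deliberately
# naive (O(n^2) enumeration, grid search, direct formulas) and never share
# code with the implementation they check.

# brute-force semivariogram: enumerate all pairs, bin with cut()
brute_variogram <- function(x, y, v, breaks) {
  n <- length(x)
  pairs <- t(utils::combn(n, 2))
  d <- sqrt((x[pairs[, 1]] - x[pairs[, 2]])^2 + (y[pairs[, 1]] - y[pairs[, 2]])^2)
  sq <- (v[pairs[, 1]] - v[pairs[, 2]])^2
  bin <- cut(d, breaks, labels = FALSE)
  keep <- !is.na(bin)
  g <- tapply(sq[keep], bin[keep], function(s) sum(s) / (2 * length(s)))
  cnt <- tapply(sq[keep], bin[keep], length)
  list(bin = as.integer(names(g)), gamma = as.numeric(g), n = as.integer(cnt))
}

# full-system ordinary kriging solve (all points, one linear system per target)
brute_krige <- function(x, y, z, model, x0, y0) {
  n <- length(x)
  D <- as.matrix(dist(cbind(x, y)))
  G <- matrix(spherical_gamma(model, as.vector(D)), n, n)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  vapply(seq_along(x0), function(i) {
    d0 <- sqrt((x - x0[i])^2 + (y - y0[i])^2)
    sol <- solve(A, c(spherical_gamma(model, d0), 1))
    sum(sol[1:n] * z)
  }, numeric(1))
}

# coordinate-wise grid search maximising the joint dichotomous Rasch
# likelihood on a 0.01-logit grid; reported with mean-centred difficulties
oracle_jmle_grid <- function(X01, step = 0.01, lim = 5) {
  grid <- seq(-lim, lim, by = step)
  N <- nrow(X01); I <- ncol(X01)
  B <- rep(0, N); d <- rep(0, I)
  total_ll <- function(B, d) {
    eta <- outer(B, d, "-")
    sum(X01 * eta - log1p(exp(eta)))
  }
  for (sweep in 1:400) {
    changed <- FALSE
    for (n in seq_len(N)) {
      eta <- outer(grid, d, "-")
      ll <- as.vector((eta %*% X01[n, ]) - rowSums(log1p(exp(eta))))
      best <- grid[which.max(ll)]
      if (abs(best - B[n]) > 1e-12) changed <- TRUE
      B[n] <- best
    }
    for (i in seq_len(I)) {
      eta <- outer(B, grid, "-")
      ll <- as.vector((X01[, i] %*% eta) - colSums(log1p(exp(eta))))
      best <- grid[which.max(ll)]
      if (abs(best - d[i]) > 1e-12) changed <- TRUE
      d[i] <- best
    }
    if (!changed) break
  }
  shift <- mean(d)
  list(B = B - shift, d = d - shift, ll = total_ll(B, d))
}

# direct mean-rank Dunn z for one pair (textbook formula, recomputed)
brute_dunn_z <- function(values, groups, a, b) {
  groups <- as.character(groups)
  rk <- rank(values)
  N <- length(values)
  ties <- table(rk)
  tt <- sum(ties^3 - ties) / (12 * (N - 1))
  ra <- mean(rk[groups == a]); rb <- mean(rk[groups == b])
  na <- sum(groups == a); nb <- sum(groups == b)
  (ra - rb) / sqrt((N * (N + 1) / 12 - tt) * (1 / na + 1 / nb))
}

# rating-scale category draw used by tests (direct, not via the package)
draw_rsm_matrix <- function(B, d, tau, seed) {
  set.seed(seed)
  m <- length(tau) + 1L
  X <- matrix(NA_integer_, length(B), length(d))
  for (n in seq_along(B)) {
    for (i in seq_along(d)) {
      expo <- c(0, cumsum(B[n] - d[i] - tau))
      p <- exp(expo - max(expo)); p <- p / sum(p)
      X[n, i] <- sample.int(m, 1, prob = p)
    }
  }
  X
}

small_template <- function(nr = 10, nc = 10, cell = 10) {
  raster_grid(matrix(0, nr, nc), cell_size = cell)
}

# separated-blob stack: k zones, both layers well separated (blob sd small
# relative to the zone-mean steps), iid within-zone noise
blob_stack <- function(template, k = 3, seed = 0) {
  zt <- simulate_zone_truth(template, k = k, seed = seed)
  nug <- variogram_model(1, 0, 50)
  eca <- simulate_gaussian_field(template, nug, mean = 46.8, sd = 5, seed = seed,
                                 zone_offsets = seq(-25 * (k - 1) / 2, 25 * (k - 1) / 2, by = 25),
                                 zone_labels = zt)
  elev <- simulate_gaussian_field(template, nug, mean = 240, sd = 0.5, seed = seed + 100,
                                  zone_offsets = seq(-2.5 * (k - 1) / 2, 2.5 * (k - 1) / 2, by = 2.5),
                                  zone_labels = zt)
  list(stack = stack_and_standardize(list(eca, elev), c("eca", "elevation")),
       truth = zt, eca = eca)
}

# adjusted Rand index (mclust's implementation is the independent reference)
ari <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  mclust::adjustedRandIndex(a[ok], b[ok])
}
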