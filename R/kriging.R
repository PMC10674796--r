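# Ordinary kriging in semivariance form. Per prediction location the system
#   [ Gamma  1 ] [ w  ]   [ g ]
#   [ 1'     0 ] [ mu ] = [ 1 ]
# is solved on the local neighbourhood, where Gamma_ij = gamma(|x_i - x_j|)
# (zero diagonal) and g_i = gamma(|x_i - x0|). The unknown constant local
# mean m(x) is eliminated by the sum-to-one constraint on the weights, which
# is what makes the estimator unbiased without knowing the mean. The kriging
# variance is w'g + mu.

krige_solve_one <- function(xs, ys, zs, model, x0, y0, max_neighbors,
                            search_radius) {
  d0 <- sqrt((xs - x0)^2 + (ys - y0)^2)
  cand <- which(d0 <= search_radius)
  if (length(cand) == 0) return(NULL)
  if (length(cand) > max_neighbors) {
    cand <- cand[order(d0[cand])[seq_len(max_neighbors)]]
  }
  nn <- length(cand)
  xi <- xs[cand]; yi <- ys[cand]; zi <- zs[cand]
  dmat <- sqrt(outer(xi, xi, "-")^2 + outer(yi, yi, "-")^2)
  G <- matrix(spherical_gamma(model, as.vector(dmat)), nn, nn)
  A <- rbind(cbind(G, 1), c(rep(1, nn), 0))
  b <- c(spherical_gamma(model, d0[cand]), 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol)) {
    # regularise a (numerically) singular system
    dA <- diag(A)
    dA[seq_len(nn)] <- dA[seq_len(nn)] + 1e-10
    diag(A) <- dA
    sol <- solve(A, b)
  }
  w <- sol[seq_len(nn)]
  mu <- sol[nn + 1]
  est <- sum(w * zi)
  kv <- sum(w * b[seq_len(nn)]) + mu
  c(estimate = est, variance = max(kv, 0), weight_sum = sum(w),
    n_used = nn, raw_variance = kv, lagrange = mu)
}

#' Ordinary kriging of point data at arbitrary locations
#'
#' Local-neighbourhood ordinary kriging: each target location is estimated
#' from its `max_neighbors` nearest data points within `search_radius`.
#' Weights sum to one (unbiasedness); the standard error is the square root
#' of the kriging variance (clipped at zero with a warning if the solve
#' returns a tiny negative value). Duplicate data coordinates are averaged
#' before solving, as coincident points make the kriging matrix singular.
#'
#' @param points A `point_survey`.
#' @param model A [variogram_model()].
#' @param locations Tibble/data frame with columns `x`, `y`.
#' @param max_neighbors Maximum data points per local system.
#' @param search_radius Neighbourhood radius (m); default 1.5 x model range.
#' @return A tibble: `x`, `y`, `estimate`, `se`, `n_used`, `weight_sum`.
#' @export
krige_points <- function(points, model, locations, max_neighbors = 16,
                         search_radius = NULL) {
  points <- average_duplicates(points)
  if (is.null(search_radius)) search_radius <- 1.5 * model$range_m
  xs <- points$x; ys <- points$y; zs <- points$value
  res <- matrix(NA_real_, nrow(locations), 6)
  clipped <- 0L
  for (i in seq_len(nrow(locations))) {
    s <- krige_solve_one(xs, ys, zs, model, locations$x[i], locations$y[i],
                         max_neighbors, search_radius)
    if (!is.null(s)) {
      res[i, ] <- s
      if (s["raw_variance"] < -1e-8) clipped <- clipped + 1L
    }
  }
  if (clipped > 0) {
    warning(clipped, " kriging variance(s) were negative and clipped to 0")
  }
  tibble::tibble(
    x = locations$x, y = locations$y,
    estimate = res[, 1], se = sqrt(res[, 2]),
    n_used = as.integer(res[, 4]), weight_sum = res[, 3]
  )
}

#' Ordinary kriging onto a raster grid
#'
#' Runs [krige_points()] at every cell centre of the template geometry and
#' returns the estimate and standard-error surfaces. Cells with no data
#' point within the search radius are `NA`.
#'
#' @inheritParams krige_points
#' @param template A [raster_grid()] giving the output geometry.
#' @return A list with [raster_grid()]s `estimate` and `se`.
#' @export
ordinary_kriging <- function(points, model, template, max_neighbors = 16,
                             search_radius = NULL) {
  cells <- raster_to_tibble(template)
  kr <- krige_points(points, model, cells, max_neighbors, search_radius)
  if (all(is.na(kr$estimate))) stop("no cell has data within the search radius", call. = FALSE)
  est <- matrix(NA_real_, template$n_rows, template$n_cols)
  sem <- est
  est[cbind(cells$row, cells$col)] <- kr$estimate
  sem[cbind(cells$row, cells$col)] <- kr$se
  g <- function(m) raster_grid(m, template$x_origin, template$y_origin,
                               template$cell_size, template$nodata)
  list(estimate = g(est), se = g(sem))
}

#' Leave-one-out cross-validation of a kriging model
#'
#' Predicts each datum from the remaining points and summarises the
#' prediction errors: RMSE, mean error, mean kriging standard error, mean
#' standardised error (mean of (Z* - Z)/SE) and the standard deviation of
#' the data. `effective` flags RMSE below the data standard deviation,
#' the usual check that kriging beats the field mean as a predictor.
#'
#' @inheritParams krige_points
#' @return A one-row tibble of class `crossval_stats`; the per-point table
#'   is attached as attribute `details`.
#' @export
loo_cross_validation <- function(points, model, max_neighbors = 16,
                                 search_radius = NULL) {
  points <- average_duplicates(points)
  n <- nrow(points)
  if (n < max(10, max_neighbors + 1)) {
    stop("need at least max(10, max_neighbors + 1) points", call. = FALSE)
  }
  if (is.null(search_radius)) search_radius <- 1.5 * model$range_m
  est <- se <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- krige_solve_one(points$x[-i], points$y[-i], points$value[-i], model,
                         points$x[i], points$y[i], max_neighbors, search_radius)
    if (is.null(s)) stop("empty neighbourhood for point ", i, call. = FALSE)
    est[i] <- s["estimate"]
    se[i] <- sqrt(s["variance"])
  }
  err <- est - points$value
  zstd <- ifelse(se > 0, err / se, 0)
  out <- tibble::tibble(
    n = n,
    rmse = sqrt(mean(err^2)),
    mean_error = mean(err),
    mean_standard_error = mean(se),
    mean_standardised_error = mean(zstd),
    mean_sq_standardised_error = mean(zstd^2),
    data_sd = sd(points$value)
  )
  out$effective <- out$rmse < out$data_sd
  attr(out, "details") <- tibble::tibble(
    x = points$x, y = points$y, observed = points$value,
    predicted = est, se = se, error = err, std_error = zstd
  )
  class(out) <- c("crossval_stats", class(out))
  out
}
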