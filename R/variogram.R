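#' Spherical variogram model
#'
#' @param nugget Nugget variance c0 >= 0 (semivariance at lag 0+).
#' @param psill Partial sill c >= 0; total sill = nugget + psill.
#' @param range_m Range a in metres, > 0: the lag beyond which the variogram
#'   is flat.
#' @param family Model family; only `"spherical"` (and the degenerate pure
#'   nugget it contains) is supported.
#' @return A `variogram_model` object.
#' @export
variogram_model <- function(nugget, psill, range_m, family = "spherical") {
  stopifnot(family == "spherical", nugget >= 0, psill >= 0, range_m > 0)
  structure(
    list(family = family, nugget = nugget, psill = psill, range_m = range_m),
    class = "variogram_model"
  )
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "<variogram_model> %s: nugget %.4g, partial sill %.4g, range %.4g m (total sill %.4g)\n",
    x$family, x$nugget, x$psill, x$range_m, x$nugget + x$psill
  ))
  invisible(x)
}

#' Spherical semivariance
#'
#' gamma(0) = 0; for 0 < h <= a, c0 + c (1.5 h/a - 0.5 (h/a)^3); beyond the
#' range, the total sill c0 + c.
#'
#' @param model A [variogram_model()].
#' @param h Nonnegative lag distances (m).
#' @return Semivariances, same length as `h`.
#' @export
spherical_gamma <- function(model, h) {
  if (any(h < 0)) stop("negative lag distance", call. = FALSE)
  r <- pmin(h / model$range_m, 1)
  g <- model$nugget + model$psill * (1.5 * r - 0.5 * r^3)
  g[h == 0] <- 0
  g
}

#' Nugget-to-sill ratio and spatial-dependence class
#'
#' 100 * c0 / (c0 + c), classified by the conventional thresholds: <= 25%
#' strong spatial dependence, (25%, 75%] moderate, > 75% weak.
#'
#' @param model A [variogram_model()].
#' @param strong,weak Class boundaries (percent), configurable.
#' @return A list with `percent` and `dependence_class`.
#' @export
nugget_sill_ratio <- function(model, strong = 25, weak = 75) {
  total <- model$nugget + model$psill
  if (total <= 0) stop("zero total sill", call. = FALSE)
  pct <- 100 * model$nugget / total
  cls <- if (pct <= strong) "strong" else if (pct <= weak) "moderate" else "weak"
  list(percent = pct, dependence_class = cls)
}

# pairwise (distance, squared difference, azimuth) accumulation done in
# row-chunks to avoid materialising the full n^2 pair set
pair_bins <- function(x, y, v, breaks, direction = NULL, tolerance = 22.5) {
  n <- length(x)
  nb <- length(breaks) - 1L
  cnt <- numeric(nb)
  ssq <- numeric(nb)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    dx <- x[j] - x[i]
    dy <- y[j] - y[i]
    d <- sqrt(dx^2 + dy^2)
    keep <- d > 0 & d <= breaks[nb + 1L]
    if (!is.null(direction)) {
      az <- (atan2(dx, dy) * 180 / pi) %% 180
      diffaz <- pmin(abs(az - direction %% 180), 180 - abs(az - direction %% 180))
      keep <- keep & diffaz <= tolerance
    }
    if (!any(keep)) next
    d <- d[keep]
    sq <- (v[j][keep] - v[i])^2
    b <- findInterval(d, breaks, left.open = TRUE, all.inside = FALSE)
    b[b < 1L] <- 1L
    ok <- b <= nb
    cnt <- cnt + tabulate(b[ok], nb)
    if (any(ok)) {
      rs <- rowsum(sq[ok], b[ok])
      ssq[as.integer(rownames(rs))] <- ssq[as.integer(rownames(rs))] + rs[, 1]
    }
  }
  list(count = cnt, ssq = ssq)
}

#' Experimental (empirical) semivariogram
#'
#' Method-of-moments estimator: gamma(h_k) = sum over pairs in lag bin k of
#' (z_i - z_j)^2 / (2 N_k). Bins with no pairs are dropped. Optionally
#' directional: only pairs whose azimuth (degrees clockwise from north,
#' undirected) is within `tolerance` of `direction` are used.
#'
#' @param points A `point_survey`.
#' @param lag_width Bin width in metres; default twice the mean
#'   nearest-neighbour distance.
#' @param max_lag Largest lag considered; default half the maximum pairwise
#'   distance.
#' @param direction Optional azimuth (degrees) for a directional variogram.
#' @param tolerance Angular tolerance (degrees) around `direction`.
#' @return A tibble of class `empirical_variogram` with columns `lag`
#'   (bin centre), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(points, lag_width = NULL, max_lag = NULL,
                                direction = NULL, tolerance = 22.5) {
  points <- average_duplicates(points)
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  x <- points$x; y <- points$y; v <- points$value
  ext <- sqrt(diff(range(x))^2 + diff(range(y))^2)
  if (is.null(max_lag)) max_lag <- ext / 2
  if (is.null(lag_width)) lag_width <- 2 * mean_nn_distance(x, y)
  stopifnot(lag_width > 0, max_lag > lag_width)
  breaks <- seq(0, max_lag, by = lag_width)
  if (breaks[length(breaks)] < max_lag) breaks <- c(breaks, max_lag)
  acc <- pair_bins(x, y, v, breaks, direction, tolerance)
  keep <- acc$count > 0
  if (!any(keep)) stop("no point pair within max_lag", call. = FALSE)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  out <- tibble::tibble(
    lag = centers[keep],
    gamma = acc$ssq[keep] / (2 * acc$count[keep]),
    n_pairs = as.integer(acc$count[keep])
  )
  attr(out, "direction") <- direction
  attr(out, "tolerance") <- if (is.null(direction)) NULL else tolerance
  attr(out, "lag_width") <- lag_width
  attr(out, "max_lag") <- max_lag
  class(out) <- c("empirical_variogram", class(out))
  out
}

mean_nn_distance <- function(x, y, sample_cap = 2000L) {
  n <- length(x)
  idx <- if (n > sample_cap) seq(1L, n, length.out = sample_cap) else seq_len(n)
  nn <- vapply(idx, function(i) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    d2[i] <- Inf
    sqrt(min(d2))
  }, numeric(1))
  mean(nn)
}

#' Fit a spherical model to an experimental variogram
#'
#' Weighted least squares with Cressie weights, minimising
#' sum_k N_k (gamma_k - gamma_model(h_k))^2 / gamma_model(h_k)^2 over
#' nonnegative (nugget, partial sill) and positive range, with a small
#' multistart to escape local minima. A near-flat variogram is reported as
#' pure nugget with `range_identifiable = FALSE`.
#'
#' @param emp An [empirical_variogram()].
#' @param family Only `"spherical"`.
#' @param n_starts Number of multistart initialisations.
#' @return A [variogram_model()] with attributes `wsse` (weighted SSE at the
#'   optimum) and `range_identifiable`.
#' @export
fit_variogram <- function(emp, family = "spherical", n_starts = 5) {
  stopifnot(family == "spherical")
  if (nrow(emp) < 4) stop("need at least 4 variogram bins", call. = FALSE)
  h <- emp$lag; g <- emp$gamma; w <- emp$n_pairs
  gmax <- max(g); hmax <- max(h)
  obj <- function(p) {
    m <- list(nugget = p[1], psill = p[2], range_m = p[3])
    gm <- m$nugget + m$psill * (1.5 * pmin(h / m$range_m, 1) -
                                  0.5 * pmin(h / m$range_m, 1)^3)
    gm <- pmax(gm, 1e-12)
    sum(w * (g - gm)^2 / gm^2)
  }
  sill0 <- mean(g[h >= stats::quantile(h, 0.7)])
  starts <- list(
    c(0.0 * sill0, sill0, hmax / 3),
    c(0.3 * sill0, 0.7 * sill0, hmax / 2),
    c(0.1 * sill0, 0.9 * sill0, hmax / 5),
    c(0.5 * sill0, 0.5 * sill0, hmax * 0.8),
    c(min(g), max(gmax - min(g), 1e-8), hmax / 4)
  )[seq_len(n_starts)]
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(pmax(p0, c(0, 1e-8, 1e-6)), obj, method = "L-BFGS-B",
            lower = c(0, 0, hmax * 1e-4), upper = c(2 * gmax, 4 * gmax, 10 * hmax)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("variogram fit failed to converge", call. = FALSE)
  p <- best$par
  # identifiability: flat (pure nugget) variograms carry no range information
  flat <- p[2] < 1e-6 * max(p[1] + p[2], 1e-12) ||
    (sd(g) < 1e-3 * mean(g) && mean(g) > 0)
  if (flat) {
    p[1] <- p[1] + p[2] * 1  # fold unidentifiable structure into nugget
    p[2] <- 0
  }
  out <- variogram_model(nugget = p[1], psill = p[2],
                         range_m = max(p[3], hmax * 1e-4))
  attr(out, "wsse") <- best$value
  attr(out, "range_identifiable") <- !flat
  out
}

#' Anisotropy ratio from directional variograms
#'
#' Fits spherical models to directional variograms over `n_directions`
#' evenly spaced azimuths and returns the ratio of the largest to the
#' smallest fitted range (>= 1), with the azimuth of the major direction.
#' Ratios below about 1.5 are conventionally taken as compatible with
#' isotropy.
#'
#' @param points A `point_survey`.
#' @param n_directions Number of azimuths spanning [0, 180).
#' @param lag_width,max_lag Passed to [empirical_variogram()].
#' @return A list with `ratio`, `major_azimuth_deg`, `minor_azimuth_deg`,
#'   and the per-direction fitted ranges.
#' @export
anisotropy_ratio <- function(points, n_directions = 4,
                             lag_width = NULL, max_lag = NULL) {
  if (sd(points$value) == 0) stop("constant survey: no spatial structure", call. = FALSE)
  az <- seq(0, 180, length.out = n_directions + 1)[seq_len(n_directions)]
  tol <- 90 / n_directions
  ranges <- vapply(az, function(a) {
    emp <- empirical_variogram(points, lag_width = lag_width, max_lag = max_lag,
                               direction = a, tolerance = tol)
    fit <- fit_variogram(emp)
    if (!isTRUE(attr(fit, "range_identifiable"))) {
      stop("directional variogram at azimuth ", a, " has no structure", call. = FALSE)
    }
    fit$range_m
  }, numeric(1))
  list(
    ratio = max(ranges) / min(ranges),
    major_azimuth_deg = az[which.max(ranges)],
    minor_azimuth_deg = az[which.min(ranges)],
    ranges = setNames(ranges, paste0("az", az))
  )
}

#' Plot an experimental variogram (with optional fitted model)
#'
#' @param object An [empirical_variogram()].
#' @param model Optional [variogram_model()] to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.empirical_variogram <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::scale_size_continuous(name = "pairs") +
    ggplot2::labs(x = "Lag distance h (m)", y = expression(gamma(h))) +
    ggplot2::expand_limits(y = 0)
  if (!is.null(model)) {
    hh <- seq(0, max(object$lag), length.out = 200)
    line_df <- tibble::tibble(lag = hh, gamma = spherical_gamma(model, hh))
    p <- p + ggplot2::geom_line(data = line_df, colour = "firebrick")
  }
  p
}
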