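#' Stack rasters into a standardized feature stack
#'
#' Layers (e.g. kriged ECa in mS/m and a DEM in m) are z-scored over their
#' valid cells so that clustering distances are commensurable across units.
#' A cell is valid only where every layer is valid. The per-layer mean/SD
#' (population SD) are stored so the transform is invertible.
#'
#' @param layers List of [raster_grid()]s with identical geometry.
#' @param layer_names Optional character names.
#' @return A `feature_stack`: standardized layers, the shared validity mask
#'   and the standardization table.
#' @export
stack_and_standardize <- function(layers, layer_names = NULL) {
  stopifnot(length(layers) >= 1)
  g0 <- layers[[1]]
  for (l in layers) {
    if (!same_geometry(g0, l)) stop("layer geometries differ", call. = FALSE)
  }
  if (is.null(layer_names)) layer_names <- paste0("layer", seq_along(layers))
  valid <- Reduce(`&`, lapply(layers, function(l) !is.na(l$values)))
  std <- vector("list", length(layers))
  stats_tbl <- tibble::tibble(layer = layer_names, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(layers)) {
    v <- layers[[i]]$values
    vv <- v[valid]
    m <- mean(vv)
    s <- sqrt(mean((vv - m)^2))
    if (s == 0) stop("layer '", layer_names[i], "' has zero variance", call. = FALSE)
    z <- (v - m) / s
    z[!valid] <- NA_real_
    std[[i]] <- raster_grid(z, g0$x_origin, g0$y_origin, g0$cell_size, g0$nodata)
    stats_tbl$mean[i] <- m
    stats_tbl$sd[i] <- s
  }
  structure(
    list(layers = std, layer_names = layer_names, valid = valid,
         standardization = stats_tbl, geometry = g0),
    class = "feature_stack"
  )
}

# valid-cell feature matrix (cells x layers) plus cell indices
stack_matrix <- function(stack) {
  idx <- which(stack$valid)
  m <- vapply(stack$layers, function(l) l$values[idx], numeric(length(idx)))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(stack$layers))
  colnames(m) <- stack$layer_names
  list(features = m, cell_idx = idx)
}

#' ISODATA-style clustering of a feature stack
#'
#' Iterative self-organising means with the split/merge phase disabled (the
#' number of zones is fixed a priori, as is usual when delineating a small
#' number of management zones): a k-means core started from deterministic
#' seeds spread along the per-feature quantiles, followed by computation of
#' per-class mean vectors and covariance matrices ("signatures") for the
#' maximum-likelihood classification step.
#'
#' @param stack A [stack_and_standardize()] result.
#' @param k Number of zones (>= 1).
#' @param max_iter Maximum Lloyd iterations.
#' @param seed RNG seed; only consumed if an empty cluster forces one random
#'   re-seed.
#' @return A `zone_model` with elements `k`, `means` (k x p), `covs` (list of
#'   p x p), `priors`, `sizes`, plus the clustering assignment.
#' @export
isodata_cluster <- function(stack, k = 3, max_iter = 100, seed = 0) {
  sm <- stack_matrix(stack)
  X <- sm$features
  if (nrow(X) < 10 * k) stop("too few valid cells for ", k, " clusters", call. = FALSE)
  if (all(apply(X, 2, function(c) max(c) - min(c)) == 0)) {
    stop("all cells identical: zero variance", call. = FALSE)
  }
  if (k == 1) {
    assign <- rep(1L, nrow(X))
  } else {
    probs <- (2 * seq_len(k) - 1) / (2 * k)
    centers <- apply(X, 2, function(col) quantile(col, probs, names = FALSE))
    centers <- matrix(centers, nrow = k)
    if (anyDuplicated(centers)) {
      centers <- centers + outer(seq_len(k) - (k + 1) / 2, rep(1e-6, ncol(X)))
    }
    km <- tryCatch(
      kmeans(X, centers = centers, iter.max = max_iter, algorithm = "Lloyd"),
      warning = function(w) suppressWarnings(
        kmeans(X, centers = centers, iter.max = max_iter, algorithm = "Lloyd")
      ),
      error = function(e) NULL
    )
    if (is.null(km) || length(unique(km$cluster)) < k) {
      # empty cluster: one random re-seed, then give up
      set.seed(seed)
      km <- tryCatch(
        suppressWarnings(kmeans(X, centers = k, iter.max = max_iter,
                                nstart = 5, algorithm = "Lloyd")),
        error = function(e) NULL
      )
      if (is.null(km) || length(unique(km$cluster)) < k) {
        stop("empty cluster after re-seed", call. = FALSE)
      }
    }
    assign <- km$cluster
  }
  p <- ncol(X)
  means <- matrix(NA_real_, k, p)
  covs <- vector("list", k)
  for (c in seq_len(k)) {
    Xi <- X[assign == c, , drop = FALSE]
    means[c, ] <- colMeans(Xi)
    cv <- if (nrow(Xi) > p) cov(Xi) else diag(1e-6, p)
    covs[[c]] <- regularize_cov(cv)
  }
  colnames(means) <- stack$layer_names
  structure(
    list(k = k, means = means, covs = covs,
         priors = rep(1 / k, k), sizes = tabulate(assign, k),
         assignment = assign, cell_idx = sm$cell_idx,
         layer_names = stack$layer_names),
    class = "zone_model"
  )
}

regularize_cov <- function(cv, eps = 1e-8) {
  cv <- (cv + t(cv)) / 2
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < eps) {
    warning("singular class covariance regularised")
    cv <- cv + diag(eps + abs(min(ev)), nrow(cv))
  }
  cv
}

#' Maximum-likelihood classification of a feature stack
#'
#' Assigns each valid cell to the class with the highest Gaussian
#' log-likelihood (log prior + log density under the class signature);
#' ties go to the lowest class index. Deterministic given the model.
#'
#' @param stack A [stack_and_standardize()] result.
#' @param model A `zone_model` from [isodata_cluster()].
#' @return A `zone_map`: a [raster_grid()] of integer labels 1..k with
#'   attribute `k`.
#' @export
mlc_classify <- function(stack, model) {
  sm <- stack_matrix(stack)
  X <- sm$features
  if (ncol(X) != ncol(model$means)) {
    stop("signature dimension does not match stack depth", call. = FALSE)
  }
  k <- model$k
  ll <- matrix(-Inf, nrow(X), k)
  for (c in seq_len(k)) {
    S <- model$covs[[c]]
    ld <- determinant(S, logarithm = TRUE)$modulus
    md <- mahalanobis(X, model$means[c, ], S)
    ll[, c] <- log(model$priors[c]) - 0.5 * (ld + md)
  }
  lab <- max.col(ll, ties.method = "first")
  g0 <- stack$geometry
  m <- matrix(NA_real_, g0$n_rows, g0$n_cols)
  m[sm$cell_idx] <- lab
  out <- raster_grid(m, g0$x_origin, g0$y_origin, g0$cell_size, g0$nodata)
  attr(out, "k") <- k
  class(out) <- c("zone_map", class(out))
  out
}

#' Order zone labels by productivity proxy
#'
#' Relabels the classes by ascending zone-mean ECa, so that label 1 is the
#' least productive zone ("Zone_less") and label k the most productive
#' ("Zone_more"). Pure relabelling: the cell partition is unchanged.
#'
#' @param zones A `zone_map`.
#' @param eca A [raster_grid()] of ECa on the same geometry (original units).
#' @return The relabelled `zone_map`, with attribute `zone_mean_eca`.
#' @export
order_zones <- function(zones, eca) {
  if (!same_geometry(zones, eca)) stop("geometries differ", call. = FALSE)
  k <- attr(zones, "k")
  if (is.null(k)) k <- max(zones$values, na.rm = TRUE)
  lab <- zones$values
  means <- vapply(seq_len(k), function(c) {
    v <- eca$values[!is.na(lab) & lab == c]
    if (length(v) == 0 || all(is.na(v))) {
      stop("zone ", c, " is empty or has no ECa cells", call. = FALSE)
    }
    mean(v, na.rm = TRUE)
  }, numeric(1))
  perm <- order(means)                 # perm[new] = old
  relabel <- integer(k)
  relabel[perm] <- seq_len(k)          # relabel[old] = new
  newlab <- matrix(NA_real_, nrow(lab), ncol(lab))
  ok <- !is.na(lab)
  newlab[ok] <- relabel[lab[ok]]
  out <- raster_grid(newlab, zones$x_origin, zones$y_origin,
                     zones$cell_size, zones$nodata)
  attr(out, "k") <- k
  attr(out, "zone_mean_eca") <- sort(means)
  class(out) <- c("zone_map", class(out))
  out
}

#' Allocate validation samples to zones proportionally to area
#'
#' Largest-remainder apportionment of `n_total` sample sites over the zone
#' areas (cell counts), with every zone receiving at least one site, then
#' uniform random placement within each zone's cells.
#'
#' @param zones A `zone_map`.
#' @param n_total Total number of samples (>= number of zones).
#' @param seed RNG seed for the in-zone placement.
#' @return A tibble: `sample_id`, `zone`, `x`, `y` (cell centres); the
#'   per-zone counts are attached as attribute `counts`.
#' @export
allocate_samples <- function(zones, n_total, seed = 0) {
  k <- attr(zones, "k")
  if (is.null(k)) k <- max(zones$values, na.rm = TRUE)
  if (n_total < k) stop("n_total must be at least the number of zones", call. = FALSE)
  areas <- tabulate(zones$values[!is.na(zones$values)], k)
  if (any(areas < 1)) stop("zone with no cells", call. = FALSE)
  counts <- largest_remainder(areas / sum(areas), n_total)
  # every zone >= 1: move from the largest allocation
  while (any(counts == 0)) {
    counts[which.max(counts)] <- max(counts) - 1L
    counts[which(counts == 0)[1]] <- 1L
  }
  cells <- raster_to_tibble(zones, drop_na = TRUE)
  set.seed(seed)
  picks <- purrr::map_dfr(seq_len(k), function(z) {
    zc <- cells[cells$value == z, ]
    zc[sample.int(nrow(zc), counts[z], replace = counts[z] > nrow(zc)), ]
  })
  out <- tibble::tibble(
    sample_id = seq_len(nrow(picks)),
    zone = as.integer(picks$value), x = picks$x, y = picks$y
  )
  attr(out, "counts") <- counts
  out
}

#' Largest-remainder apportionment
#'
#' @param fractions Nonnegative shares (normalised internally).
#' @param n Total count to apportion.
#' @return Integer vector summing to `n`.
#' @export
largest_remainder <- function(fractions, n) {
  fractions <- fractions / sum(fractions)
  quota <- fractions * n
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Plot a zone map
#'
#' @param object A `zone_map`.
#' @param ... Unused.
#' @return A ggplot with a discrete zone fill.
#' @export
autoplot.zone_map <- function(object, ...) {
  df <- raster_to_tibble(object, drop_na = TRUE)
  df$zone <- factor(df$value)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$zone)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)", fill = "Zone")
}
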