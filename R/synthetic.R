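# Synthetic inputs with stored ground truth. The study system being
# emulated: a small (few-ha) vineyard surveyed by a mobile EM-induction
# sensor along parallel transects, giving a dense ECa point cloud with
# spherical spatial structure (range on the order of 130 m, nugget/sill
# around a quarter), a gently undulating DEM, a small number of
# productivity zones, and 20-odd soil samples whose nine properties express
# a zone-dependent latent fertility.

# spherical correlation (unit sill, no nugget)
spherical_corr <- function(h, range_m) {
  r <- pmin(h / range_m, 1)
  1 - (1.5 * r - 0.5 * r^3)
}

#' Simulate a Gaussian random field with spherical structure
#'
#' Generates a stationary Gaussian field on the raster geometry whose
#' variogram matches the given model up to scaling: the nugget fraction
#' c0/(c0+c) is realised as iid noise, the remainder as a spatially
#' correlated component with spherical correlation of the given range. The
#' unit-variance field is then scaled to (`mean`, `sd`). Grids up to
#' `max_chol_cells` use an exact Cholesky factorisation of the correlation
#' matrix; larger grids use circulant embedding on a padded torus (FFT),
#' with small negative embedding eigenvalues clipped.
#'
#' @param template A [raster_grid()] giving the geometry.
#' @param model A [variogram_model()]; only the range and the nugget/sill
#'   *proportion* matter, the scale is set by `sd`.
#' @param mean,sd Target field mean and standard deviation (e.g. mS/m).
#' @param seed RNG seed.
#' @param max_chol_cells Threshold between the exact and FFT paths.
#' @param zone_offsets Optional per-zone mean offsets (field units) added
#'   after simulation, so that clustering has a recoverable signal.
#' @param zone_labels A `zone_map` matching the geometry; required with
#'   `zone_offsets`.
#' @return A [raster_grid()].
#' @export
simulate_gaussian_field <- function(template, model, mean = 46.8, sd = 27.13,
                                    seed = 1, max_chol_cells = 10000,
                                    zone_offsets = NULL, zone_labels = NULL) {
  set.seed(seed)
  nug_frac <- model$nugget / (model$nugget + model$psill)
  cells <- raster_to_tibble(template)
  n <- nrow(cells)
  if (sd == 0) {
    z <- rep(0, n)
  } else if (model$psill == 0) {
    z <- rnorm(n)
  } else if (n <= max_chol_cells) {
    D <- as.matrix(dist(cbind(cells$x, cells$y)))
    C <- spherical_corr(D, model$range_m)
    L <- tryCatch(chol(C + diag(1e-8, n)), error = function(e) {
      chol(C + diag(1e-4, n))
    })
    smooth <- drop(rnorm(n) %*% L)
    z <- sqrt(1 - nug_frac) * smooth + sqrt(nug_frac) * rnorm(n)
  } else {
    sm <- circulant_field(template, model$range_m)
    smv <- sm[cbind(cells$row, cells$col)]
    z <- sqrt(1 - nug_frac) * smv + sqrt(nug_frac) * rnorm(n)
  }
  vals <- mean + sd * z
  m <- matrix(NA_real_, template$n_rows, template$n_cols)
  m[cbind(cells$row, cells$col)] <- vals
  out <- raster_grid(m, template$x_origin, template$y_origin,
                     template$cell_size, template$nodata)
  if (!is.null(zone_offsets) && !is.null(zone_labels)) {
    off <- matrix(0, template$n_rows, template$n_cols)
    ok <- !is.na(zone_labels$values)
    off[ok] <- zone_offsets[zone_labels$values[ok]]
    out$values <- out$values + off
  }
  out
}

# standard-normal field on the grid via circulant embedding of the
# spherical correlation on a 2x-padded torus
circulant_field <- function(template, range_m) {
  nr <- template$n_rows; nc <- template$n_cols
  cs <- template$cell_size
  Mr <- stats::nextn(2 * nr, 2); Mc <- stats::nextn(2 * nc, 2)
  dr <- pmin(0:(Mr - 1), Mr - 0:(Mr - 1)) * cs
  dc <- pmin(0:(Mc - 1), Mc - 0:(Mc - 1)) * cs
  H <- sqrt(outer(dr^2, dc^2, "+"))
  C <- spherical_corr(H, range_m)
  lam <- Re(stats::fft(C))
  neg <- lam < 0
  if (any(lam < -1e-3 * max(lam))) {
    stop("circulant embedding not positive definite; enlarge padding", call. = FALSE)
  }
  lam[neg] <- 0
  eps <- matrix(stats::rnorm(Mr * Mc), Mr, Mc) +
    1i * matrix(stats::rnorm(Mr * Mc), Mr, Mc)
  f <- stats::fft(sqrt(lam / (Mr * Mc)) * eps, inverse = FALSE)
  Re(f)[seq_len(nr), seq_len(nc)]
}

#' Simulate a transect-style mobile survey of a field
#'
#' Samples the field along parallel transects (constant x spacing, constant
#' along-transect step), as a towed EM sensor logging at fixed time
#' intervals does, adds iid measurement noise, and corrupts a fraction of
#' records (negated or x10, mimicking metal interference) while logging
#' their indices so cleaning can be verified exactly.
#'
#' @param field A [raster_grid()].
#' @param transect_spacing Distance between transects (m).
#' @param along_step Sampling step along a transect (m).
#' @param noise_sd Measurement noise SD (survey units).
#' @param erroneous_fraction Fraction of records corrupted.
#' @param seed RNG seed.
#' @return A `point_survey` with attribute `corrupted_idx` (integer indices
#'   of corrupted records).
#' @export
simulate_survey <- function(field, transect_spacing = 10, along_step = NULL,
                            noise_sd = 0, erroneous_fraction = 0, seed = 1) {
  set.seed(seed)
  cs <- field$cell_size
  if (is.null(along_step)) along_step <- cs
  width <- field$n_cols * cs
  height <- field$n_rows * cs
  tx <- seq(field$x_origin + cs / 2, field$x_origin + width - cs / 2,
            by = transect_spacing)
  ty <- seq(field$y_origin + cs / 2, field$y_origin + height - cs / 2,
            by = along_step)
  if (length(tx) == 0 || length(ty) == 0) stop("no sample points in extent", call. = FALSE)
  pts <- expand.grid(x = tx, y = ty)
  idx <- raster_cell_index(field, pts$x, pts$y)
  v <- field$values[cbind(idx$row, idx$col)]
  ok <- !is.na(v)
  pts <- pts[ok, ]; v <- v[ok]
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  corrupted <- integer(0)
  if (erroneous_fraction > 0) {
    n_bad <- round(erroneous_fraction * length(v))
    corrupted <- sort(sample.int(length(v), n_bad))
    mode_neg <- runif(n_bad) < 0.5
    v[corrupted[mode_neg]] <- -abs(v[corrupted[mode_neg]]) - 1
    v[corrupted[!mode_neg]] <- abs(v[corrupted[!mode_neg]]) * 10 + 400
  }
  out <- point_survey(pts$x, pts$y, v, variable_name = "ECa",
                      depth_window = "0-0.30 m")
  attr(out, "corrupted_idx") <- corrupted
  out
}

#' Simulate a gently undulating DEM
#'
#' Planar trend plus a smooth sinusoidal undulation: the kind of low-relief
#' topography on which management-zone studies in flat vineyard terrain
#' operate.
#'
#' @param template A [raster_grid()] geometry.
#' @param base Elevation offset (m).
#' @param slope Length-2 vector: metres of rise per metre in x and y.
#' @param amplitude Undulation amplitude (m), >= 0.
#' @param wavelength Undulation wavelength (m).
#' @param seed RNG seed (phase of the undulation).
#' @return A [raster_grid()] of elevations.
#' @export
simulate_dem <- function(template, base = 240, slope = c(0.01, 0.02),
                         amplitude = 1, wavelength = 200, seed = 1) {
  stopifnot(amplitude >= 0)
  set.seed(seed)
  phase <- runif(2, 0, 2 * pi)
  cells <- raster_to_tibble(template)
  z <- base + slope[1] * (cells$x - template$x_origin) +
    slope[2] * (cells$y - template$y_origin) +
    amplitude * sin(2 * pi * cells$x / wavelength + phase[1]) *
      sin(2 * pi * cells$y / wavelength + phase[2])
  m <- matrix(NA_real_, template$n_rows, template$n_cols)
  m[cbind(cells$row, cells$col)] <- z
  raster_grid(m, template$x_origin, template$y_origin,
              template$cell_size, template$nodata)
}

#' Simulate banded true zones on a grid
#'
#' Partitions the geometry into `k` zones by thresholding a smooth spatial
#' score (diagonal trend plus undulation) at its equal-area quantiles,
#' giving contiguous, roughly equal zones to serve as ground truth.
#'
#' @param template A [raster_grid()] geometry.
#' @param k Number of zones.
#' @param seed RNG seed (undulation phase).
#' @return A `zone_map` with labels 1..k.
#' @export
simulate_zone_truth <- function(template, k = 3, seed = 1) {
  set.seed(seed)
  phase <- runif(1, 0, 2 * pi)
  cells <- raster_to_tibble(template)
  width <- template$n_cols * template$cell_size
  height <- template$n_rows * template$cell_size
  score <- (cells$x - template$x_origin) / width +
    0.8 * (cells$y - template$y_origin) / height +
    0.25 * sin(4 * pi * (cells$x - template$x_origin) / width + phase)
  qs <- quantile(score, probs = seq_len(k - 1) / k, names = FALSE)
  lab <- findInterval(score, qs) + 1L
  m <- matrix(NA_real_, template$n_rows, template$n_cols)
  m[cbind(cells$row, cells$col)] <- lab
  out <- raster_grid(m, template$x_origin, template$y_origin,
                     template$cell_size, template$nodata)
  attr(out, "k") <- k
  class(out) <- c("zone_map", class(out))
  out
}

# per-item raw-value ranges used when back-constructing soil chemistry from
# drawn categories; units follow the usual lab reports
soil_item_ranges <- function() {
  tibble::tribble(
    ~item,   ~lo,   ~hi,  ~polarity,
    "sand",   15,    75,  -1,
    "clay",    3,    23,   1,
    "silt",    2,    82,   1,
    "om",    0.2,   3.2,   1,
    "ph",    4.5,   8.0,   1,
    "p2o5",   10,   210,   1,
    "k2o",    30,   330,   1,
    "seb",     2,    22,   1,
    "cec",     4,    29,   1
  )
}

#' Simulate soil samples with zone-dependent latent fertility
#'
#' Places `n_total` samples over the zones proportionally to area (largest
#' remainder), draws a true fertility measure per sample from
#' Normal(shift of its zone, `person_sd`) logits, draws 5-category item
#' responses from the rating-scale model with the given item difficulties
#' and thresholds, and back-constructs continuous soil-property values so
#' that [categorize()] at the stored cut points reproduces the drawn
#' categories. The texture triple is made to sum to 100 by deriving silt as
#' the remainder; silt's category is therefore recomputed from its
#' constructed value rather than drawn (noted in the returned truth).
#'
#' @param zones A `zone_map`.
#' @param n_total Number of samples.
#' @param zone_fertility_shifts Numeric vector, one mean fertility (logits)
#'   per zone label.
#' @param item_difficulties Named numeric vector over the nine soil items
#'   (mean-centred recommended); default evenly spread in [-1, 1].
#' @param thresholds Rating-scale thresholds (length m - 1, mean zero).
#' @param person_sd SD of true fertility within a zone (logits).
#' @param seed RNG seed.
#' @return A list: `table` (a soil-sample tibble with id, x, y, zone and
#'   nine property columns), `categories` (the `category_matrix`), and
#'   `truth` (true measures, difficulties, thresholds, cut points, seed).
#' @export
simulate_soil_samples <- function(zones, n_total = 20,
                                  zone_fertility_shifts = c(-1, 0, 1),
                                  item_difficulties = NULL,
                                  thresholds = c(-1.2, -0.4, 0.4, 1.2),
                                  person_sd = 0.5, seed = 1) {
  k <- attr(zones, "k")
  if (is.null(k)) k <- max(zones$values, na.rm = TRUE)
  stopifnot(length(zone_fertility_shifts) == k)
  ranges <- soil_item_ranges()
  items <- ranges$item
  if (is.null(item_difficulties)) {
    item_difficulties <- setNames(
      seq(-1, 1, length.out = length(items)), items
    )
    item_difficulties <- item_difficulties - mean(item_difficulties)
  }
  stopifnot(all(items %in% names(item_difficulties)))
  m <- length(thresholds) + 1L

  plan <- allocate_samples(zones, n_total, seed = seed)
  set.seed(seed + 1)
  N <- nrow(plan)
  B_true <- rnorm(N, zone_fertility_shifts[plan$zone], person_sd)

  # draw categories from the rating-scale model
  X <- matrix(NA_integer_, N, length(items), dimnames = list(NULL, items))
  for (i in seq_along(items)) {
    for (n in seq_len(N)) {
      p <- category_probabilities(B_true[n], item_difficulties[[items[i]]],
                                  thresholds)
      X[n, i] <- sample.int(m, 1, prob = p)
    }
  }

  # back-construct continuous values inside the category's cut-point bin
  breaks <- lapply(seq_len(nrow(ranges)), function(i) {
    seq(ranges$lo[i], ranges$hi[i], length.out = m + 1)
  })
  names(breaks) <- items
  vals <- matrix(NA_real_, N, length(items), dimnames = list(NULL, items))
  for (i in seq_along(items)) {
    br <- breaks[[items[i]]]
    pol <- ranges$polarity[i]
    raw_bin <- if (pol < 0) m + 1L - X[, i] else X[, i]
    u <- runif(N, 0.15, 0.85)   # stay clear of bin edges
    vals[, i] <- br[raw_bin] + u * (br[raw_bin + 1] - br[raw_bin])
  }
  # texture closure: silt is the remainder; its category follows its value
  vals[, "silt"] <- 100 - vals[, "sand"] - vals[, "clay"]
  silt_bin <- findInterval(vals[, "silt"], breaks[["silt"]],
                           rightmost.closed = TRUE, all.inside = TRUE)
  X[, "silt"] <- as.integer(silt_bin)   # silt polarity is +1

  table <- tibble::tibble(
    id = plan$sample_id, x = plan$x, y = plan$y, zone = plan$zone
  )
  for (i in seq_along(items)) table[[items[i]]] <- vals[, i]

  polarity <- setNames(ranges$polarity, items)
  cm <- categorize(table, items = items, m = m, polarity = polarity,
                   breaks = breaks)
  stopifnot(all(unclass(cm) == X))

  truth <- list(
    B = B_true, zone = plan$zone,
    item_difficulties = item_difficulties,
    thresholds = thresholds,
    polarity = polarity, breaks = breaks,
    zone_fertility_shifts = zone_fertility_shifts,
    person_sd = person_sd, seed = seed
  )
  list(table = table, categories = cm, truth = truth)
}
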