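#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected rank-based H statistic with a chi-square reference on
#' k - 1 degrees of freedom (via [stats::kruskal.test()]). If all values
#' are identical the statistic is 0 and p = 1.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coercible to factor), >= 2 groups.
#' @return A one-row tibble: `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2, length(values) == length(groups))
  if (length(unique(values)) == 1) {
    return(tibble::tibble(H = 0, df = nlevels(groups) - 1L, p_value = 1))
  }
  kt <- kruskal.test(values, groups)
  tibble::tibble(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value)
}

#' Dunn post-hoc pairwise comparisons
#'
#' Rank-based z tests on all group pairs following a Kruskal-Wallis
#' omnibus: z_ab = (Rbar_a - Rbar_b) / sqrt((N(N+1)/12 - T) (1/n_a + 1/n_b))
#' with the tie term T = sum(t^3 - t) / (12 (N - 1)). Two-sided p values
#' with optional multiplicity adjustment. For two groups, z^2 equals the
#' tie-corrected H.
#'
#' @inheritParams kruskal_wallis
#' @param adjustment `"none"` (default), `"bonferroni"` or `"holm"`.
#' @return A tibble: `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(values, groups, adjustment = c("none", "bonferroni", "holm")) {
  adjustment <- match.arg(adjustment)
  groups <- factor(groups)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  meanrank <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(seq_along(lv), 2)
  z <- p <- numeric(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    a <- pairs[1, q]; b <- pairs[2, q]
    sd_ab <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[a] + 1 / ns[b]))
    z[q] <- if (sd_ab > 0) (meanrank[a] - meanrank[b]) / sd_ab else 0
    p[q] <- 2 * pnorm(-abs(z[q]))
  }
  tibble::tibble(
    group1 = lv[pairs[1, ]], group2 = lv[pairs[2, ]],
    z = z, p_value = p,
    p_adjusted = p.adjust(p, method = adjustment)
  )
}

#' Compact letter display from pairwise comparisons
#'
#' Insert-and-absorb algorithm: groups that are *not* significantly
#' different share at least one letter; the letter set is minimal and the
#' result deterministic given the group order.
#'
#' @param pairwise A tibble as returned by [dunn_test()] (columns `group1`,
#'   `group2`, `p_adjusted`).
#' @param alpha Significance level.
#' @param group_order Optional character vector fixing the display order.
#' @return A tibble: `group`, `letters`.
#' @export
letter_display <- function(pairwise, alpha = 0.01, group_order = NULL) {
  gs <- if (is.null(group_order)) {
    unique(c(pairwise$group1, pairwise$group2))
  } else {
    group_order
  }
  k <- length(gs)
  sig <- matrix(FALSE, k, k, dimnames = list(gs, gs))
  for (q in seq_len(nrow(pairwise))) {
    a <- pairwise$group1[q]; b <- pairwise$group2[q]
    s <- pairwise$p_adjusted[q] < alpha
    sig[a, b] <- s; sig[b, a] <- s
  }
  # columns of `cols` are letter groups (logical membership vectors)
  cols <- list(rep(TRUE, k))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      if (!sig[a, b]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[a] && col[b]) {
          c1 <- col; c1[a] <- FALSE
          c2 <- col; c2[b] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1]] <- c2
        }
      }
      # absorb columns that are subsets of others
      keep <- rep(TRUE, length(cols))
      for (i in seq_along(cols)) {
        for (j in seq_along(cols)) {
          if (i != j && keep[i] && keep[j] &&
              all(cols[[i]] | !cols[[j]]) && !identical(cols[[i]], cols[[j]])) {
            keep[j] <- FALSE   # j subset of i
          }
        }
      }
      # deduplicate identical columns
      sig_keys <- vapply(cols, function(c) paste(c, collapse = ""), character(1))
      keep <- keep & !duplicated(sig_keys)
      cols <- cols[keep]
    }
  }
  # stable letter assignment: order columns by first member
  first_member <- vapply(cols, function(c) which(c)[1], numeric(1))
  cols <- cols[order(first_member)]
  letters_out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(c) c[g], logical(1)))], collapse = "")
  }, character(1))
  tibble::tibble(group = gs, letters = letters_out)
}

#' Per-zone soil-property means with significance letters
#'
#' For each soil property, computes per-zone arithmetic means and appends
#' compact letters from a Dunn test at `alpha`; the standard per-zone
#' validation table for delineated management zones.
#'
#' @param table Data frame with a `zone` column and numeric property columns.
#' @param properties Property columns to summarise; default all numeric
#'   except id/coordinates/zone.
#' @param alpha Significance level for the letters.
#' @param adjustment Passed to [dunn_test()].
#' @return A tibble: `property`, one `mean` and one `letters` value per zone
#'   (long format: columns `zone`, `mean`, `letters`).
#' @export
zone_property_means <- function(table, properties = NULL, alpha = 0.01,
                                adjustment = "none") {
  stopifnot("zone" %in% names(table))
  if (is.null(properties)) {
    properties <- setdiff(
      names(table)[vapply(table, is.numeric, logical(1))],
      c("id", "sample_id", "x", "y", "zone")
    )
  }
  zones <- sort(unique(table$zone))
  if (any(table(table$zone) < 1)) stop("empty zone", call. = FALSE)
  purrr::map_dfr(properties, function(pr) {
    v <- table[[pr]]
    means <- tapply(v, table$zone, mean)
    pw <- dunn_test(v, table$zone, adjustment = adjustment)
    lt <- letter_display(pw, alpha = alpha, group_order = as.character(zones))
    tibble::tibble(
      property = pr, zone = zones,
      mean = as.numeric(means[as.character(zones)]),
      letters = lt$letters
    )
  })
}

#' Normalised difference vegetation index
#'
#' NDVI = (NIR - Red) / (NIR + Red), bounded in [-1, 1] for nonnegative
#' reflectances (Sentinel-2: band 8 as NIR, band 4 as Red).
#'
#' @param nir,red Nonnegative reflectances (vectors or matrices).
#' @return NDVI, same shape as the inputs.
#' @export
ndvi <- function(nir, red) {
  if (any(nir < 0, na.rm = TRUE) || any(red < 0, na.rm = TRUE)) {
    stop("reflectances must be nonnegative", call. = FALSE)
  }
  denom <- nir + red
  if (any(denom == 0, na.rm = TRUE)) stop("zero denominator (NIR + Red = 0)", call. = FALSE)
  (nir - red) / denom
}

#' Per-zone NDVI means across dates
#'
#' Aggregates NDVI rasters by management zone for a set of dates; the zone
#' raster is resampled to each NDVI grid by nearest neighbour if geometries
#' differ. A per-zone flag reports whether the mean declines monotonically
#' across the date order, the pattern expected as the vine vegetative cycle
#' advances past peak vigour.
#'
#' @param ndvi_rasters Named list of [raster_grid()]s, one per date (list
#'   order = date order).
#' @param zones A `zone_map`.
#' @return A tibble: `date`, `zone`, `mean_ndvi`, `n_cells`; attribute
#'   `declining` gives the per-zone monotone-decline flag.
#' @export
ndvi_by_zone <- function(ndvi_rasters, zones) {
  if (is.null(names(ndvi_rasters))) {
    names(ndvi_rasters) <- paste0("date", seq_along(ndvi_rasters))
  }
  k <- attr(zones, "k")
  if (is.null(k)) k <- max(zones$values, na.rm = TRUE)
  out <- purrr::imap_dfr(ndvi_rasters, function(r, date) {
    zlab <- if (same_geometry(r, zones)) {
      zones$values
    } else {
      cells <- raster_to_tibble(r)
      idx <- raster_cell_index(zones, cells$x, cells$y)
      zl <- matrix(NA_real_, r$n_rows, r$n_cols)
      ok <- !is.na(idx$row)
      zl[cbind(cells$row[ok], cells$col[ok])] <-
        zones$values[cbind(idx$row[ok], idx$col[ok])]
      zl
    }
    purrr::map_dfr(seq_len(k), function(z) {
      v <- r$values[!is.na(zlab) & zlab == z & !is.na(r$values)]
      tibble::tibble(date = date, zone = z,
                     mean_ndvi = if (length(v)) mean(v) else NA_real_,
                     n_cells = length(v))
    })
  })
  decl <- vapply(seq_len(k), function(z) {
    s <- out$mean_ndvi[out$zone == z]
    all(!is.na(s)) && all(diff(s) < 0)
  }, logical(1))
  attr(out, "declining") <- setNames(decl, paste0("zone", seq_len(k)))
  out
}
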