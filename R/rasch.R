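# Polytomous Rasch measurement of latent soil fertility.
#
# The dichotomous Rasch model gives the probability that sample n "passes"
# soil-property item i as P = exp(B_n - d_i) / (1 + exp(B_n - d_i)), where
# B_n is the sample's fertility measure and d_i the item difficulty, both in
# logits. For ordered rating categories 1..m the Andrich rating-scale
# extension is used: categories share a set of m-1 thresholds tau_k across
# items, and
#   P(X = k) = exp(sum_{j<k} (B - d - tau_j)) / normaliser.
# Estimation is joint maximum likelihood (JMLE): Newton updates alternately
# equate each person's, item's and category's observed and expected scores.
# Identification: item difficulties are centred to mean 0 and thresholds to
# mean 0 (for m = 2 the single threshold is fixed at 0, recovering the
# dichotomous model exactly).

#' Dichotomous Rasch probability
#'
#' @param B Person measure (logits).
#' @param d Item difficulty (logits).
#' @return P = exp(B - d)/(1 + exp(B - d)); the logit of P is B - d.
#' @export
dichotomous_probability <- function(B, d) {
  stats::plogis(B - d)
}

#' Rating-scale category probabilities
#'
#' @param B Person measure (logits), scalar.
#' @param d Item difficulty (logits), scalar.
#' @param tau Thresholds (logits), length m - 1.
#' @return Probability vector over categories 1..m (sums to 1).
#' @export
category_probabilities <- function(B, d, tau) {
  m <- length(tau) + 1L
  # cumulative exponents: k-th category has sum_{j<=k-1} (B - d - tau_j)
  expo <- c(0, cumsum(B - d - tau))
  expo <- expo - max(expo)
  p <- exp(expo)
  p / sum(p)
}

# vectorised over persons: returns N x m matrix of probabilities for one item
rsm_prob_matrix <- function(B, d, tau) {
  m <- length(tau) + 1L
  expo <- outer(B - d, 0:(m - 1)) -
    matrix(c(0, cumsum(tau)), length(B), m, byrow = TRUE)
  expo <- expo - apply(expo, 1, max)
  p <- exp(expo)
  p / rowSums(p)
}

# expected score and score variance per person-item cell (0-based scores)
rsm_moments <- function(B, d, tau) {
  m <- length(tau) + 1L
  ks <- 0:(m - 1)
  N <- length(B); I <- length(d)
  E <- matrix(0, N, I); W <- matrix(0, N, I)
  for (i in seq_len(I)) {
    p <- rsm_prob_matrix(B, d[i], tau)
    e <- drop(p %*% ks)
    E[, i] <- e
    W[, i] <- drop(p %*% ks^2) - e^2
  }
  list(E = E, W = W)
}

#' Convert a soil-sample table to a rating-category matrix
#'
#' Maps each soil property to ordinal categories 1..m, with category 1 the
#' lowest contribution to soil fertility and category m the highest. The
#' default scheme cuts the observed range of each property into m equal
#' intervals; `"quantile"` uses empirical quantile bins. Properties whose
#' high raw values indicate *low* fertility (e.g. sand content) are declared
#' via `polarity` and mapped with the scale reversed. Explicit cut points
#' can be injected per item through `breaks`, overriding the scheme. The
#' mapping table used is always returned for reproducibility.
#'
#' @param table Data frame with an `id` column (optional) and one numeric
#'   column per soil property.
#' @param items Character vector naming the property columns to use.
#' @param m Number of categories (default 5).
#' @param scheme `"equal_interval"` or `"quantile"`.
#' @param polarity Named logical/character-free vector: `+1` if high value =
#'   high fertility (default), `-1` to reverse. Unnamed items default to +1.
#' @param breaks Optional named list of length-(m+1) increasing cut vectors.
#' @return A `category_matrix`: integer matrix `X` (samples x items) in
#'   1..m, with the mapping table as attribute `mapping`.
#' @export
categorize <- function(table, items = NULL, m = 5,
                       scheme = c("equal_interval", "quantile"),
                       polarity = NULL, breaks = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(items)) {
    items <- names(table)[vapply(table, is.numeric, logical(1))]
    items <- setdiff(items, c("id", "sample_id", "x", "y", "zone"))
  }
  N <- nrow(table)
  X <- matrix(NA_integer_, N, length(items), dimnames = list(NULL, items))
  mapping <- vector("list", length(items))
  names(mapping) <- items
  for (i in seq_along(items)) {
    it <- items[i]
    v <- table[[it]]
    pol <- if (!is.null(polarity) && it %in% names(polarity)) polarity[[it]] else 1
    br <- if (!is.null(breaks) && it %in% names(breaks)) {
      breaks[[it]]
    } else if (scheme == "equal_interval") {
      if (diff(range(v, na.rm = TRUE)) == 0) {
        stop("item '", it, "' is constant: zero range", call. = FALSE)
      }
      seq(min(v, na.rm = TRUE), max(v, na.rm = TRUE), length.out = m + 1)
    } else {
      qs <- quantile(v, probs = seq(0, 1, length.out = m + 1), na.rm = TRUE,
                     names = FALSE)
      if (anyDuplicated(qs)) qs <- qs + seq(0, 1e-9, length.out = m + 1)
      qs
    }
    if (length(unique(v[!is.na(v)])) < m) {
      warning("item '", it, "' has fewer than ", m, " distinct values")
    }
    raw <- findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
    cat_i <- if (pol < 0) m + 1L - raw else raw
    X[, i] <- as.integer(cat_i)
    mapping[[i]] <- list(item = it, polarity = pol, breaks = br)
  }
  structure(X, class = c("category_matrix", "matrix", "array"),
            m = as.integer(m), mapping = mapping,
            sample_ids = if ("id" %in% names(table)) table$id else seq_len(N))
}

#' Fit the Rasch rating-scale model by joint maximum likelihood
#'
#' Alternating Newton updates of person measures, item difficulties and
#' category thresholds until every observed raw score matches its model
#' expectation within `score_tol` and no parameter moves more than
#' `change_tol` logits. Item difficulties are re-centred to mean zero each
#' cycle (the identification constraint); thresholds are centred to mean
#' zero. Persons with extreme raw scores (minimum or maximum possible) have
#' no finite ML estimate; their scores are pulled 0.3 score points inward
#' and solved against the final item calibration, flagged as extrapolated.
#' Items observed in a single category are dropped with a warning.
#'
#' @param X A `category_matrix` (or integer matrix in 1..m); `NA` cells are
#'   treated as not administered.
#' @param m Number of categories; taken from `X` if available.
#' @param max_cycles Maximum JMLE cycles.
#' @param score_tol Convergence tolerance on |observed - expected| scores.
#' @param change_tol Convergence tolerance on parameter changes (logits).
#' @return A `rasch_fit` with tibbles `persons` (measure, SE, raw score,
#'   extreme flag) and `items` (difficulty, SE, raw score), `thresholds`,
#'   and a convergence record.
#' @export
fit_rating_scale <- function(X, m = NULL, max_cycles = 200,
                             score_tol = 0.01, change_tol = 0.001) {
  if (is.null(m)) m <- attr(X, "m")
  if (is.null(m)) m <- max(X, na.rm = TRUE)
  ids <- attr(X, "sample_ids")
  item_names <- colnames(X)
  X <- unclass(X)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(ncol(X)))
  if (is.null(ids)) ids <- seq_len(nrow(X))
  if (nrow(X) < 3 || ncol(X) < 2) stop("need >= 3 persons and >= 2 items", call. = FALSE)
  if (any(X < 1 | X > m, na.rm = TRUE)) stop("categories must lie in 1..m", call. = FALSE)

  # drop single-category items (no information about difficulty)
  obs_cats <- apply(X, 2, function(col) length(unique(col[!is.na(col)])))
  if (any(obs_cats < 2)) {
    warning("dropping item(s) with a single observed category: ",
            paste(item_names[obs_cats < 2], collapse = ", "))
    X <- X[, obs_cats >= 2, drop = FALSE]
    item_names <- item_names[obs_cats >= 2]
    if (ncol(X) < 2) stop("fewer than 2 informative items", call. = FALSE)
  }
  x <- X - 1L                      # 0-based scores
  M <- m - 1L
  N <- nrow(x); I <- ncol(x)
  adm <- !is.na(x)                 # administered cells
  r <- rowSums(x, na.rm = TRUE)    # person raw scores
  rmax <- rowSums(adm) * M
  extreme <- r == 0 | r == rmax
  if (all(extreme)) stop("all persons have extreme scores", call. = FALSE)

  est <- which(!extreme)
  B <- stats::qlogis(pmin(pmax((r + 0.5) / (rmax + 1), 1e-3), 1 - 1e-3))
  d <- rep(0, I)
  tau <- rep(0, M)
  free_tau <- M >= 2               # m = 2: single threshold pinned at 0

  max_resid <- Inf
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    max_change <- 0

    mom <- rsm_moments(B, d, tau)
    E <- mom$E; W <- mom$W
    E[!adm] <- 0; W[!adm] <- 0

    # persons (non-extreme only)
    Ep <- rowSums(E); Vp <- rowSums(W)
    stepB <- (r - Ep) / pmax(Vp, 1e-6)
    stepB <- pmin(pmax(stepB, -1), 1)
    B[est] <- B[est] + stepB[est]
    max_change <- max(max_change, max(abs(stepB[est])))

    # items: expected/observed column scores over non-extreme persons
    mom <- rsm_moments(B[est], d, tau)
    Ei <- colSums(mom$E * adm[est, , drop = FALSE])
    Vi <- colSums(mom$W * adm[est, , drop = FALSE])
    si <- colSums(x[est, , drop = FALSE], na.rm = TRUE)
    stepd <- (Ei - si) / pmax(Vi, 1e-6)
    stepd <- pmin(pmax(stepd, -1), 1)
    d <- d + stepd
    ctr <- mean(d)
    d <- d - ctr
    B[est] <- B[est] - ctr         # keep B - d invariant under re-centring
    max_change <- max(max_change, max(abs(stepd)))

    # thresholds: equate counts of responses reaching each category
    if (free_tau) {
      Tgeq <- vapply(seq_len(M), function(j) {
        sum(x[est, , drop = FALSE] >= j, na.rm = TRUE)
      }, numeric(1))
      Egeq <- numeric(M); Vgeq <- numeric(M)
      for (i in seq_len(I)) {
        p <- rsm_prob_matrix(B[est], d[i], tau)
        p[!adm[est, i], ] <- 0
        cg <- t(apply(p, 1, function(row) rev(cumsum(rev(row)))))  # P(X >= k)
        for (j in seq_len(M)) {
          pg <- cg[, j + 1]
          Egeq[j] <- Egeq[j] + sum(pg)
          Vgeq[j] <- Vgeq[j] + sum(pg * (1 - pg))
        }
      }
      steptau <- (Egeq - Tgeq) / pmax(Vgeq, 1e-6)
      steptau <- pmin(pmax(steptau, -1), 1)
      tau <- tau + steptau
      ctr <- mean(tau)
      tau <- tau - ctr
      B[est] <- B[est] - ctr       # tau location trades against B location
      max_change <- max(max_change, max(abs(steptau)))
    }

    mom <- rsm_moments(B, d, tau)
    E <- mom$E; E[!adm] <- 0
    resid_p <- max(abs(r[est] - rowSums(E)[est]))
    Ei <- colSums(mom$E[est, , drop = FALSE] * adm[est, , drop = FALSE])
    resid_i <- max(abs(colSums(x[est, , drop = FALSE], na.rm = TRUE) - Ei))
    max_resid <- max(resid_p, resid_i)
    if ((max_resid < score_tol && max_change < change_tol) || cycles >= max_cycles) break
  }
  converged <- max_resid < score_tol
  if (!converged) warning("JMLE did not fully converge after ", cycles, " cycles")

  # extreme persons: shift scores 0.3 points inward, solve B given (d, tau)
  for (n in which(extreme)) {
    target <- if (r[n] == 0) 0.3 else rmax[n] - 0.3
    B[n] <- solve_person_measure(target, d[adm[n, ]], tau)
  }
  mom <- rsm_moments(B, d, tau)
  Vp <- rowSums(mom$W * adm)
  Vi <- colSums(mom$W[est, , drop = FALSE] * adm[est, , drop = FALSE])

  # threshold disordering is reported, never forced away
  disordered <- is.unsorted(tau)

  persons <- tibble::tibble(
    id = ids, raw_score = r + rowSums(adm),  # back on the 1..m scale
    score_0based = r, max_score = rmax,
    measure = B, se = 1 / sqrt(pmax(Vp, 1e-12)),
    extreme = extreme
  )
  items <- tibble::tibble(
    item = item_names, raw_score = colSums(X, na.rm = TRUE),
    difficulty = d, se = 1 / sqrt(pmax(Vi, 1e-12))
  )
  structure(
    list(persons = persons, items = items, thresholds = tau, m = m,
         disordered_thresholds = disordered,
         convergence = list(converged = converged, cycles = cycles,
                            max_score_residual = max_resid)),
    class = "rasch_fit"
  )
}

# one-dimensional Newton solve of sum_i E[x | B, d_i, tau] = target
solve_person_measure <- function(target, d, tau, tol = 1e-8) {
  B <- 0
  for (it in 1:100) {
    mom <- rsm_moments(B, d, tau)
    f <- sum(mom$E) - target
    v <- sum(mom$W)
    step <- f / max(v, 1e-8)
    B <- B - pmin(pmax(step, -2), 2)
    if (abs(f) < tol) break
  }
  B
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat(sprintf(
    "<rasch_fit> %d persons x %d items, %d categories; converged: %s (%d cycles)\n",
    nrow(x$persons), nrow(x$items), x$m,
    x$convergence$converged, x$convergence$cycles
  ))
  cat("thresholds:", paste(sprintf("%.3f", x$thresholds), collapse = ", "), "\n")
  invisible(x)
}

#' Infit and Outfit mean-square fit statistics
#'
#' Standardised residuals z_ni = (X_ni - E_ni) / sqrt(W_ni), with E and W
#' the model mean and variance of the category score. Outfit is the plain
#' mean of z^2 (outlier-sensitive); Infit the information-weighted
#' sum(W z^2) / sum(W). Values near 1 indicate fit; the conventional
#' acceptance band is [0.6, 1.5]. Extreme persons and zero-variance cells
#' are excluded from the sums.
#'
#' @param X The `category_matrix` that was fitted.
#' @param fit A `rasch_fit`.
#' @param lower,upper Acceptance band for the `acceptable` flag.
#' @return A list of tibbles `items` and `persons` with `infit_mnsq`,
#'   `outfit_mnsq` and acceptance flags.
#' @export
fit_statistics <- function(X, fit, lower = 0.6, upper = 1.5) {
  m <- fit$m
  X <- unclass(X)
  if (!is.null(colnames(X))) {
    X <- X[, fit$items$item, drop = FALSE]
  } else if (ncol(X) != nrow(fit$items)) {
    stop("matrix columns do not match fitted items", call. = FALSE)
  }
  x <- X - 1L
  adm <- !is.na(x)
  B <- fit$persons$measure
  d <- fit$items$difficulty
  tau <- fit$thresholds
  mom <- rsm_moments(B, d, tau)
  E <- mom$E; W <- mom$W
  use <- adm & W > 1e-10
  use[fit$persons$extreme, ] <- FALSE   # extremes carry no fit information
  z2 <- matrix(NA_real_, nrow(x), ncol(x))
  z2[use] <- (x[use] - E[use])^2 / W[use]
  wz2 <- z2 * W

  item_out <- vapply(seq_len(ncol(x)), function(i) mean(z2[use[, i], i]), numeric(1))
  item_in <- vapply(seq_len(ncol(x)), function(i) {
    sum(wz2[use[, i], i]) / sum(W[use[, i], i])
  }, numeric(1))
  pers_out <- vapply(seq_len(nrow(x)), function(n) {
    if (!any(use[n, ])) return(NA_real_)
    mean(z2[n, use[n, ]])
  }, numeric(1))
  pers_in <- vapply(seq_len(nrow(x)), function(n) {
    if (!any(use[n, ])) return(NA_real_)
    sum(wz2[n, use[n, ]]) / sum(W[n, use[n, ]])
  }, numeric(1))

  list(
    items = tibble::tibble(
      item = fit$items$item, infit_mnsq = item_in, outfit_mnsq = item_out,
      acceptable = item_in >= lower & item_in <= upper &
        item_out >= lower & item_out <= upper
    ),
    persons = tibble::tibble(
      id = fit$persons$id, infit_mnsq = pers_in, outfit_mnsq = pers_out
    ),
    n_excluded_cells = sum(adm) - sum(use)
  )
}

#' Mean Rasch measure per management zone
#'
#' @param fit A `rasch_fit`.
#' @param table Data frame with `id` and `zone` columns matching the fitted
#'   samples.
#' @return A tibble with per-zone mean measure and sample count.
#' @export
measures_by_zone <- function(fit, table) {
  stopifnot(all(c("id", "zone") %in% names(table)))
  df <- dplyr::inner_join(fit$persons, table[c("id", "zone")], by = "id")
  if (any(is.na(df$zone))) stop("samples without a zone label", call. = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$zone),
    mean_measure = mean(.data$measure), n = dplyr::n(), .groups = "drop"
  )
  dplyr::arrange(out, .data$zone)
}

#' Tidy a Rasch fit
#'
#' @param x A `rasch_fit`.
#' @param what `"persons"`, `"items"` or `"thresholds"`.
#' @param ... Unused.
#' @return A tibble of parameter estimates.
#' @export
tidy.rasch_fit <- function(x, what = c("persons", "items", "thresholds"), ...) {
  what <- match.arg(what)
  switch(what,
    persons = dplyr::transmute(x$persons, term = as.character(.data$id),
                               estimate = .data$measure, std.error = .data$se,
                               extreme = .data$extreme),
    items = dplyr::transmute(x$items, term = .data$item,
                             estimate = .data$difficulty, std.error = .data$se),
    thresholds = tibble::tibble(term = paste0("tau", seq_along(x$thresholds)),
                                estimate = x$thresholds)
  )
}

#' Glance at a Rasch fit
#'
#' @param x A `rasch_fit`.
#' @param ... Unused.
#' @return A one-row tibble of fit-level summaries.
#' @export
glance.rasch_fit <- function(x, ...) {
  tibble::tibble(
    n_persons = nrow(x$persons), n_items = nrow(x$items), m = x$m,
    n_extreme = sum(x$persons$extreme),
    converged = x$convergence$converged,
    cycles = x$convergence$cycles,
    max_score_residual = x$convergence$max_score_residual,
    disordered_thresholds = x$disordered_thresholds
  )
}

#' Item-person map (Wright map) of a Rasch fit
#'
#' @param object A `rasch_fit`.
#' @param ... Unused.
#' @return A ggplot showing person-measure and item-difficulty distributions
#'   on the shared logit scale.
#' @export
autoplot.rasch_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(kind = "persons", value = object$persons$measure),
    tibble::tibble(kind = "items", value = object$items$difficulty)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$value, fill = .data$kind)) +
    ggplot2::geom_dotplot(binwidth = 0.25, alpha = 0.7) +
    ggplot2::facet_wrap(~kind, ncol = 1) +
    ggplot2::labs(x = "Logits", y = NULL) +
    ggplot2::guides(fill = "none")
}
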