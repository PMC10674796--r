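# Delaunay triangulation by the Bowyer-Watson incremental algorithm, and
# piecewise-linear (TIN-style) interpolation of scattered elevations onto a
# raster geometry. Coordinates are centred/scaled before triangulating to
# keep the in-circumcircle determinants well conditioned.

# Returns an integer matrix, one triangle per row (indices into x, y),
# counter-clockwise orientation.
delaunay_triangulate <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  cx <- mean(x); cy <- mean(y)
  sc <- max(max(abs(x - cx)), max(abs(y - cy)), .Machine$double.eps)
  px <- (x - cx) / sc
  py <- (y - cy) / sc

  # super-triangle comfortably containing the unit box
  big <- 64
  px <- c(px, c(-big, big, 0))
  py <- c(py, c(-big, -big, big))
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  orient2d <- function(ax, ay, bx, by, cx_, cy_) {
    (bx - ax) * (cy_ - ay) - (by - ay) * (cx_ - ax)
  }

  tris <- matrix(c(s1, s2, s3), ncol = 3)
  # cached circumcentres / radii^2
  ccx <- numeric(1); ccy <- numeric(1); cr2 <- numeric(1)
  circum <- function(t) {
    ax <- px[t[1]]; ay <- py[t[1]]
    bx <- px[t[2]]; by <- py[t[2]]
    cx_ <- px[t[3]]; cy_ <- py[t[3]]
    d <- 2 * (ax * (by - cy_) + bx * (cy_ - ay) + cx_ * (ay - by))
    if (abs(d) < 1e-300) return(c(Inf, Inf, Inf))
    ux <- ((ax^2 + ay^2) * (by - cy_) + (bx^2 + by^2) * (cy_ - ay) +
             (cx_^2 + cy_^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx_ - bx) + (bx^2 + by^2) * (ax - cx_) +
             (cx_^2 + cy_^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  cc <- circum(tris[1, ])
  ccx[1] <- cc[1]; ccy[1] <- cc[2]; cr2[1] <- cc[3]

  for (i in seq_len(n)) {
    # triangles whose circumcircle contains point i (with slack for ties)
    inside <- (px[i] - ccx)^2 + (py[i] - ccy)^2 <= cr2 * (1 + 1e-12)
    bad <- which(inside)
    if (length(bad) == 0) {
      # numerical fallback: locate by containment
      for (t in seq_len(nrow(tris))) {
        tt <- tris[t, ]
        d1 <- orient2d(px[tt[1]], py[tt[1]], px[tt[2]], py[tt[2]], px[i], py[i])
        d2 <- orient2d(px[tt[2]], py[tt[2]], px[tt[3]], py[tt[3]], px[i], py[i])
        d3 <- orient2d(px[tt[3]], py[tt[3]], px[tt[1]], py[tt[1]], px[i], py[i])
        if (d1 >= -1e-12 && d2 >= -1e-12 && d3 >= -1e-12) { bad <- t; break }
      }
      if (length(bad) == 0) stop("triangulation failed at point ", i, call. = FALSE)
    }
    # boundary polygon of the cavity = edges not shared by two bad triangles
    edges <- NULL
    for (t in bad) {
      tt <- tris[t, ]
      edges <- rbind(edges, c(tt[1], tt[2]), c(tt[2], tt[3]), c(tt[3], tt[1]))
    }
    keyf <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    tab <- table(keyf)
    boundary <- edges[keyf %in% names(tab)[tab == 1L], , drop = FALSE]
    keep <- setdiff(seq_len(nrow(tris)), bad)
    tris <- tris[keep, , drop = FALSE]
    ccx <- ccx[keep]; ccy <- ccy[keep]; cr2 <- cr2[keep]
    for (e in seq_len(nrow(boundary))) {
      a <- boundary[e, 1]; b <- boundary[e, 2]
      o <- orient2d(px[a], py[a], px[b], py[b], px[i], py[i])
      if (abs(o) < 1e-14) next  # degenerate sliver (collinear)
      tri <- if (o > 0) c(a, b, i) else c(b, a, i)
      tris <- rbind(tris, tri)
      cc <- circum(tri)
      ccx <- c(ccx, cc[1]); ccy <- c(ccy, cc[2]); cr2 <- c(cr2, cc[3])
    }
  }
  # drop triangles touching the super-triangle
  keep <- apply(tris, 1, function(t) all(t <= n))
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0) stop("all points collinear: no triangulation", call. = FALSE)
  rownames(tris) <- NULL
  tris
}

#' Grid scattered elevation points into a DEM
#'
#' Triangulates the survey points (Delaunay) and linearly interpolates within
#' each triangle at the cell centres of the template geometry, the usual
#' TIN-to-raster conversion. Cells outside the convex hull are `NA` unless
#' `fill_nearest = TRUE`, in which case they take the value of the nearest
#' data point. Duplicate coordinates are averaged first. Any affine surface
#' is reproduced exactly at in-hull cell centres.
#'
#' @param points A `point_survey` of elevations.
#' @param template A [raster_grid()] supplying the output geometry (its
#'   values are ignored).
#' @param fill_nearest Fill out-of-hull cells by nearest neighbour?
#' @return A [raster_grid()] of elevations.
#' @export
grid_elevation <- function(points, template, fill_nearest = FALSE) {
  points <- average_duplicates(points)
  if (nrow(points) < 3) stop("need at least 3 points to triangulate", call. = FALSE)
  xs <- points$x; ys <- points$y; zs <- points$value
  # collinearity check on the full set
  a <- cbind(xs - xs[1], ys - ys[1])
  if (qr(a)$rank < 2) stop("points are collinear: cannot triangulate", call. = FALSE)

  tris <- delaunay_triangulate(xs, ys)
  cells <- raster_to_tibble(template)
  gx <- cells$x; gy <- cells$y
  out <- rep(NA_real_, length(gx))

  # per-triangle barycentric containment test, vectorised over cells
  unassigned <- rep(TRUE, length(gx))
  eps <- 1e-9 * max(diff(range(xs)), diff(range(ys)))
  for (t in seq_len(nrow(tris))) {
    i1 <- tris[t, 1]; i2 <- tris[t, 2]; i3 <- tris[t, 3]
    x1 <- xs[i1]; y1 <- ys[i1]; x2 <- xs[i2]; y2 <- ys[i2]; x3 <- xs[i3]; y3 <- ys[i3]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-300) next
    idx <- which(unassigned)
    l1 <- ((y2 - y3) * (gx[idx] - x3) + (x3 - x2) * (gy[idx] - y3)) / det
    l2 <- ((y3 - y1) * (gx[idx] - x3) + (x1 - x3) * (gy[idx] - y3)) / det
    l3 <- 1 - l1 - l2
    tol <- eps / sqrt(abs(det))
    inside <- l1 >= -tol & l2 >= -tol & l3 >= -tol
    hit <- idx[inside]
    if (length(hit) > 0) {
      out[hit] <- l1[inside] * zs[i1] + l2[inside] * zs[i2] + l3[inside] * zs[i3]
      unassigned[hit] <- FALSE
    }
  }
  if (fill_nearest && any(is.na(out))) {
    miss <- which(is.na(out))
    for (j in miss) {
      k <- which.min((xs - gx[j])^2 + (ys - gy[j])^2)
      out[j] <- zs[k]
    }
  }
  m <- matrix(NA_real_, template$n_rows, template$n_cols)
  m[cbind(cells$row, cells$col)] <- out
  raster_grid(m,
    x_origin = template$x_origin, y_origin = template$y_origin,
    cell_size = template$cell_size, nodata = template$nodata
  )
}
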