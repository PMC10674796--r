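#' Regular raster grid
#'
#' A minimal in-memory raster: a numeric matrix with a lower-left origin,
#' square cells and cell-centre registration. Row 1 of `values` is the
#' northernmost row. Missing cells are `NA` internally; the `nodata` sentinel
#' is only used when reading/writing ESRI ASCII grids.
#'
#' @param values Numeric matrix (`n_rows` x `n_cols`), row 1 = north.
#' @param x_origin,y_origin Coordinates (metres) of the lower-left corner of
#'   the lower-left cell.
#' @param cell_size Cell edge length in metres, > 0.
#' @param nodata Sentinel value used on disk for missing cells.
#' @return A `raster_grid` object.
#' @export
raster_grid <- function(values, x_origin = 0, y_origin = 0, cell_size = 1,
                        nodata = -9999) {
  values <- as.matrix(values)
  stopifnot(is.numeric(cell_size), length(cell_size) == 1, cell_size > 0)
  if (any(values == nodata, na.rm = TRUE)) {
    stop("`nodata` sentinel collides with a valid cell value", call. = FALSE)
  }
  structure(
    list(
      x_origin = x_origin, y_origin = y_origin, cell_size = cell_size,
      n_rows = nrow(values), n_cols = ncol(values),
      values = values, nodata = nodata
    ),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "<raster_grid> %d x %d cells, cell %g m, origin (%g, %g), %d NA cells\n",
    x$n_rows, x$n_cols, x$cell_size, x$x_origin, x$y_origin,
    sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) c(x$n_rows, x$n_cols)

same_geometry <- function(a, b, tol = 1e-9) {
  abs(a$x_origin - b$x_origin) < tol && abs(a$y_origin - b$y_origin) < tol &&
    abs(a$cell_size - b$cell_size) < tol &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Cell-centre coordinates of a raster
#'
#' @param grid A [raster_grid()].
#' @param drop_na Drop cells whose value is missing?
#' @return A tibble with columns `x`, `y`, `row`, `col`, `value`.
#' @export
raster_to_tibble <- function(grid, drop_na = FALSE) {
  rows <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  out <- tibble::tibble(
    row = rows, col = cols,
    x = grid$x_origin + (cols - 0.5) * grid$cell_size,
    y = grid$y_origin + (grid$n_rows - rows + 0.5) * grid$cell_size,
    value = as.vector(grid$values)
  )
  if (drop_na) out <- dplyr::filter(out, !is.na(.data$value))
  out
}

#' Locate points on a raster grid
#'
#' Maps planar coordinates to (row, col) indices; points outside the grid
#' extent get `NA` indices.
#'
#' @param grid A [raster_grid()].
#' @param x,y Coordinate vectors (metres).
#' @return A list with integer vectors `row` and `col`.
#' @export
raster_cell_index <- function(grid, x, y) {
  col <- floor((x - grid$x_origin) / grid$cell_size) + 1L
  row <- grid$n_rows - floor((y - grid$y_origin) / grid$cell_size)
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` dialect: a six-line header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by rows
#' north to south. Values are printed with enough significant digits that a
#' write/read round trip is lossless at double precision for all practical
#' purposes.
#'
#' @param grid A [raster_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  header <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$x_origin),
    sprintf("yllcorner %.10g", grid$y_origin),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  body <- apply(v, 1, function(r) paste(sprintf("%.15g", r), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file written in the dialect of
#'   [write_raster()].
#' @return A [raster_grid()]; on-disk nodata cells become `NA`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 7) stop("malformed ESRI ASCII grid: too few lines", call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed header line: ", lines[i], call. = FALSE)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(needed %in% names(hdr))) {
    stop("ESRI ASCII header missing fields: ",
         paste(setdiff(needed, names(hdr)), collapse = ", "), call. = FALSE)
  }
  n_rows <- as.integer(hdr$nrows)
  n_cols <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_rows) {
    stop("ESRI ASCII grid: expected ", n_rows, " data rows, found ",
         length(body), call. = FALSE)
  }
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(vals) != n_cols)) {
    stop("ESRI ASCII grid: row length does not match ncols", call. = FALSE)
  }
  m <- do.call(rbind, vals)
  m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m,
    x_origin = hdr$xllcorner, y_origin = hdr$yllcorner,
    cell_size = hdr$cellsize, nodata = hdr$nodata_value
  )
}

#' Plot a raster grid
#'
#' @param object A [raster_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- raster_to_tibble(object, drop_na = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)")
}
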