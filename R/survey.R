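#' Construct a point survey
#'
#' A point survey is a tibble of georeferenced scalar observations with
#' columns `x`, `y` (planar metres; inputs are assumed already projected,
#' e.g. ETRS89 / UTM) and `value` (survey units: mS/m for ECa, m for
#' elevation). The variable name and sensing depth window travel along as
#' attributes.
#'
#' @param x,y,value Numeric vectors of equal length.
#' @param variable_name Label, e.g. `"ECa"`.
#' @param depth_window Label, e.g. `"0-0.30 m"`.
#' @return A tibble of class `point_survey`.
#' @export
point_survey <- function(x, y, value, variable_name = "value",
                         depth_window = NA_character_) {
  stopifnot(length(x) == length(y), length(x) == length(value))
  keep <- is.finite(x) & is.finite(y) & !is.na(value)
  if (!any(keep)) stop("point survey has no valid records", call. = FALSE)
  out <- tibble::tibble(x = as.numeric(x[keep]), y = as.numeric(y[keep]),
                        value = as.numeric(value[keep]))
  attr(out, "variable_name") <- variable_name
  attr(out, "depth_window") <- depth_window
  class(out) <- c("point_survey", class(out))
  out
}

#' Read a point survey from delimited text
#'
#' Reads a CSV (comma delimiter, `.` decimal, header row) and maps the named
#' columns onto the survey fields. Rows whose mapped fields are missing or
#' unparseable are dropped and counted.
#'
#' @param path CSV file path.
#' @param column_map Named character vector or list mapping survey fields to
#'   file columns, e.g. `c(x = "easting", y = "northing", value = "eca")`.
#' @param variable_name,depth_window Labels stored on the survey.
#' @return A `point_survey`; attributes `n_read` and `n_dropped` report the
#'   parsed and discarded row counts.
#' @export
read_point_survey <- function(path,
                              column_map = c(x = "x", y = "y", value = "value"),
                              variable_name = "value",
                              depth_window = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  column_map <- unlist(column_map)
  stopifnot(all(c("x", "y", "value") %in% names(column_map)))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0) {
    stop("mapped column(s) not in file: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  xs <- suppressWarnings(as.numeric(raw[[column_map[["x"]]]]))
  ys <- suppressWarnings(as.numeric(raw[[column_map[["y"]]]]))
  vs <- suppressWarnings(as.numeric(raw[[column_map[["value"]]]]))
  ok <- is.finite(xs) & is.finite(ys) & is.finite(vs)
  if (!any(ok)) stop("no valid rows in ", path, call. = FALSE)
  out <- point_survey(xs[ok], ys[ok], vs[ok],
                      variable_name = variable_name,
                      depth_window = depth_window)
  attr(out, "n_read") <- nrow(raw)
  attr(out, "n_dropped") <- nrow(raw) - sum(ok)
  out
}

#' Write a point survey to CSV
#'
#' @param survey A `point_survey` (or any tibble with x, y, value).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_point_survey <- function(survey, path) {
  readr::write_csv(tibble::as_tibble(survey[c("x", "y", "value")]), path)
  invisible(path)
}

#' Remove implausible survey values
#'
#' Mobile ECa surveys contain erroneous records (negative or excessively high
#' values, typically metal interference); these are removed by plausibility
#' bounds before any geostatistics.
#'
#' @param survey A `point_survey`.
#' @param min_value,max_value Inclusive plausibility bounds (survey units).
#' @return The filtered survey; attribute `n_removed` counts discarded rows.
#' @export
clean_eca <- function(survey, min_value = 0, max_value = 300) {
  stopifnot(min_value < max_value)
  keep <- survey$value >= min_value & survey$value <= max_value
  if (!any(keep)) stop("all records removed by cleaning bounds", call. = FALSE)
  out <- survey[keep, ]
  attr(out, "variable_name") <- attr(survey, "variable_name")
  attr(out, "depth_window") <- attr(survey, "depth_window")
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- class(survey)
  out
}

# Average records sharing a coordinate (kriging systems are singular
# otherwise). Exact-duplicate coordinates only.
average_duplicates <- function(survey) {
  key <- paste(survey$x, survey$y, sep = "_")
  if (!anyDuplicated(key)) return(survey)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(survey[c("x", "y", "value")]),
                    .data$x, .data$y),
    value = mean(.data$value), .groups = "drop"
  )
  point_survey(agg$x, agg$y, agg$value,
               variable_name = attr(survey, "variable_name"),
               depth_window = attr(survey, "depth_window"))
}

#' Exploratory summary statistics of a survey
#'
#' Mean, median, standard deviation, coefficient of variation, adjusted
#' Fisher-Pearson skewness and excess-free kurtosis, as used to judge
#' approximate normality before variography.
#'
#' @param survey A `point_survey`.
#' @return A one-row tibble.
#' @export
summary_stats <- function(survey) {
  v <- survey$value
  n <- length(v)
  stopifnot(n >= 2)
  m <- mean(v)
  s <- sd(v)
  if (abs(m) < .Machine$double.eps) stop("zero mean: CV undefined", call. = FALSE)
  # adjusted Fisher-Pearson skewness (sample, with n-correction)
  g1 <- mean((v - m)^3) / (mean((v - m)^2))^1.5
  skew <- sqrt(n * (n - 1)) / (n - 2) * g1
  kurt <- mean((v - m)^4) / (mean((v - m)^2))^2
  tibble::tibble(
    n = n, mean = m, median = median(v), sd = s,
    cv_percent = 100 * s / m, skewness = skew, kurtosis = kurt
  )
}
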