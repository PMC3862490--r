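## Route-level survey data: validation, CSV reading, model indexing.

SURVEY_COLS <- c("route_id", "observer_id", "year", "count", "start_lon", "start_lat")

#' Validate a route-level survey data.frame
#'
#' Checks the column contract used throughout the package: one row per
#' route x observer x year with a nonnegative integer total count and the
#' route's start coordinates. Duplicate (route, year) rows are rejected —
#' a route has a single yearly total.
#'
#' @param data data.frame with columns `route_id`, `observer_id`, `year`,
#'   `count`, `start_lon`, `start_lat`.
#' @return the validated data.frame (class `car_survey` prepended).
#' @export
survey_data <- function(data) {
  miss <- setdiff(SURVEY_COLS, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) == 0L) stop("empty survey dataset")
  bad <- which(!is.finite(data$count) | data$count < 0 | data$count != round(data$count))
  if (length(bad)) stop("counts must be nonnegative integers; bad row(s): ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(!is.finite(data$year) | data$year != round(data$year))
  if (length(bad)) stop("years must be integers; bad row(s): ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  dup <- duplicated(data[c("route_id", "year")])
  if (any(dup)) stop("duplicate (route_id, year) row(s): ",
                     paste(utils::head(which(dup), 5L), collapse = ", "))
  ## coordinate range checks via the assignment rule
  assign_route(data$start_lon, data$start_lat)
  rng <- range(data$start_lon)
  one <- stats::aggregate(start_lon ~ route_id, data, function(x) length(unique(x)))
  ## a route has one fixed start point
  two <- stats::aggregate(start_lat ~ route_id, data, function(x) length(unique(x)))
  if (any(one$start_lon > 1L) || any(two$start_lat > 1L))
    stop("route(s) with inconsistent start coordinates across rows")
  data$count <- as.integer(round(data$count))
  data$year <- as.integer(round(data$year))
  class(data) <- unique(c("car_survey", class(data)))
  data
}

#' Read route-level counts from CSV
#'
#' Reads the package's counts dialect: header
#' `route_id,observer_id,year,count,start_lon,start_lat`, UTF-8,
#' comma-separated, no thousands separators. The dataset is validated
#' (see [survey_data()]) and a one-line inventory is printed.
#'
#' @param path CSV file path.
#' @param quiet suppress the inventory message.
#' @return validated `car_survey` data.frame.
#' @export
read_counts <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(SURVEY_COLS, names(df))
  if (length(miss)) stop("malformed counts file ", path, ": missing column(s) ",
                         paste(miss, collapse = ", "))
  for (col in c("year", "count", "start_lon", "start_lat")) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(num))
    if (length(bad)) stop("malformed value in column '", col, "' at data line(s): ",
                          paste(utils::head(bad, 5L), collapse = ", "))
    df[[col]] <- num
  }
  neg <- which(df$count < 0)
  if (length(neg)) stop("negative count at data line(s): ",
                        paste(utils::head(neg, 5L), collapse = ", "))
  df <- survey_data(df)
  if (!quiet) {
    cells <- unique(assign_route(df$start_lon, df$start_lat)$cell)
    message(sprintf(
      "%s routes, distributed among %s cells, %s detections over %d years, %s observers",
      format(length(unique(df$route_id)), big.mark = ","),
      format(length(cells), big.mark = ","),
      format(sum(df$count), big.mark = ","),
      diff(range(df$year)) + 1L,
      format(length(unique(df$observer_id)), big.mark = ",")))
  }
  df
}

## model indexing: map records onto year 1..T (contiguous), observer-route
## (or observer) 1..K, lattice cell 1..C. Records whose cell is not in the
## lattice (e.g. dropped by the connectivity policy) are removed with a
## warning.
index_survey <- function(data, lattice,
                         observer_mode = c("observer-route", "observer")) {
  observer_mode <- match.arg(observer_mode)
  data <- survey_data(data)
  asg <- assign_route(data$start_lon, data$start_lat, lattice$resolution)
  ci <- match(asg$cell, lattice$cells$cell)
  if (anyNA(ci)) {
    warning(sum(is.na(ci)), " record(s) in cells outside the lattice dropped")
    keep <- !is.na(ci)
    data <- data[keep, , drop = FALSE]
    ci <- ci[keep]
    if (nrow(data) == 0L) stop("no records left after dropping off-lattice cells")
  }
  years <- seq(min(data$year), max(data$year))
  ti <- match(data$year, years)
  key <- if (observer_mode == "observer-route") {
    paste(data$observer_id, data$route_id, sep = "\r")
  } else {
    as.character(data$observer_id)
  }
  kf <- factor(key)
  list(data = data, y = data$count, year_idx = ti, obs_idx = as.integer(kf),
       cell_idx = ci, years = years, T = length(years),
       K = nlevels(kf), C = nrow(lattice$cells),
       obs_labels = levels(kf), observer_mode = observer_mode)
}
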