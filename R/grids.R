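#' Gridded monthly geophysical fields
#'
#' A light container for equal-angle lat/lon monthly fields, the common
#' currency of the synthetic-data generators and the regional time-series
#' pipeline. Values are stored per variable as a 3-d array with dimensions
#' (lat, lon, time); `lat` and `lon` are cell-center coordinates in degrees
#' and `time` is a vector of mid-month `Date` stamps.
#'
#' @param lat numeric vector of cell-center latitudes (degrees, ascending)
#' @param lon numeric vector of cell-center longitudes (degrees, ascending,
#'   in \[-180, 180\])
#' @param time vector of `Date` stamps, strictly increasing (mid-month)
#' @param fields named list of arrays, each with dim
#'   `c(length(lat), length(lon), length(time))`
#' @param units named character vector of units per field (optional)
#' @return an object of class `oc_grid`
#' @export
oc_grid <- function(lat, lon, time, fields, units = NULL) {
  stopifnot(is.numeric(lat), is.numeric(lon), length(fields) >= 1)
  if (any(lat < -90 | lat > 90)) stop("latitudes must lie in [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("longitudes must lie in [-180, 180]")
  if (is.unsorted(lat, strictly = TRUE) || is.unsorted(lon, strictly = TRUE))
    stop("lat and lon must be strictly increasing")
  time <- as.Date(time)
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  dims <- c(length(lat), length(lon), length(time))
  for (nm in names(fields)) {
    if (!identical(dim(fields[[nm]]), as.integer(dims)))
      stop("field '", nm, "' has wrong dimensions")
  }
  structure(list(lat = lat, lon = lon, time = time,
                 fields = fields, units = units),
            class = "oc_grid")
}

#' @export
print.oc_grid <- function(x, ...) {
  cat(sprintf("<oc_grid> %d x %d cells, %d months (%s .. %s)\n",
              length(x$lat), length(x$lon), length(x$time),
              format(min(x$time)), format(max(x$time))))
  cat("fields:", paste(names(x$fields), collapse = ", "), "\n")
  invisible(x)
}

# mid-month Date stamps for an inclusive year range (proleptic Gregorian)
month_mid_dates <- function(years) {
  as.Date(unlist(lapply(years, function(y)
    sprintf("%04d-%02d-15", y, 1:12))))
}

# cell-center axes for an equal-angle grid
grid_axes <- function(res_lat, res_lon = res_lat) {
  list(lat = seq(-90 + res_lat / 2, 90 - res_lat / 2, by = res_lat),
       lon = seq(-180 + res_lon / 2, 180 - res_lon / 2, by = res_lon))
}

#' Write a gridded dataset to long-format CSV
#'
#' Columns: `time` (ISO-8601), `lat`, `lon`, one column per field. This is
#' the package's plain-text interchange dialect.
#'
#' @param grid an `oc_grid`
#' @param path output file path
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "oc_grid"))
  idx <- expand.grid(lat = grid$lat, lon = grid$lon,
                     time = format(grid$time), stringsAsFactors = FALSE)
  out <- data.frame(time = idx$time, lat = idx$lat, lon = idx$lon)
  for (nm in names(grid$fields)) out[[nm]] <- as.vector(grid$fields[[nm]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format grid CSV written by [write_grid_csv()]
#' @param path file path
#' @return an `oc_grid`
#' @export
read_grid_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "lat", "lon")
  if (!all(need %in% names(d))) stop("grid CSV must have time, lat, lon columns")
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  time <- sort(unique(as.Date(d$time)))
  dims <- c(length(lat), length(lon), length(time))
  ii <- cbind(match(d$lat, lat), match(d$lon, lon), match(as.Date(d$time), time))
  vars <- setdiff(names(d), need)
  fields <- lapply(vars, function(v) {
    a <- array(NA_real_, dims)
    a[ii] <- d[[v]]
    a
  })
  names(fields) <- vars
  oc_grid(lat, lon, time, fields)
}
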