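#' Rectangular region mask
#'
#' @param name region name
#' @param lat_min,lat_max,lon_min,lon_max bounding box in degrees
#' @return a `region_mask` object
#' @export
region_mask <- function(name, lat_min, lat_max, lon_min, lon_max) {
  if (lat_min >= lat_max || lat_min < -90 || lat_max > 90)
    stop("invalid latitude bounds")
  if (lon_min >= lon_max || lon_min < -180 || lon_max > 180)
    stop("invalid longitude bounds")
  structure(list(name = name, lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max),
            class = "region_mask")
}

#' Named region presets
#'
#' `NH` spans 0-50 N and `SH` 0-50 S (all longitudes). `SPSG` is a
#' rectangular approximation of the South Pacific Subtropical Gyre,
#' 15 S-45 S, 160 W-100 W.
#'
#' @param name one of "NH", "SH", "SPSG"
#' @export
region_preset <- function(name = c("NH", "SH", "SPSG")) {
  name <- match.arg(name)
  switch(name,
    NH   = region_mask("NH", 0, 50, -180, 180),
    SH   = region_mask("SH", -50, 0, -180, 180),
    SPSG = region_mask("SPSG", -45, -15, -160, -100))
}

in_region <- function(mask, lat, lon) {
  outer(lat > mask$lat_min & lat < mask$lat_max,
        lon > mask$lon_min & lon < mask$lon_max, `&`)
}

#' Area-weighted regional mean time series
#'
#' Cell weights are proportional to cos(latitude) at cell centers; cells
#' with missing data are excluded from both the numerator and the weight
#' sum (weights renormalize per month). Geometric aggregation (used for
#' aerosol optical thickness, whose distributions are right-skewed)
#' averages in log space and requires strictly positive values.
#'
#' @param grid an `oc_grid`
#' @param var field name to aggregate
#' @param mask a [region_mask()]
#' @param kind "arithmetic" or "geometric"
#' @return a data.frame of class `regional_series` with columns `time`,
#'   `value` and attributes `variable`, `region`, `kind`
#' @export
regional_mean <- function(grid, var, mask,
                          kind = c("arithmetic", "geometric")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "oc_grid"), inherits(mask, "region_mask"))
  if (!var %in% names(grid$fields)) stop("unknown field: ", var)
  sel <- in_region(mask, grid$lat, grid$lon)
  if (!any(sel)) stop("empty region: mask does not intersect the grid")
  w0 <- outer(cos(grid$lat * pi / 180), rep(1, length(grid$lon)))
  w0[!sel] <- 0
  a <- grid$fields[[var]]
  nt <- length(grid$time)
  vals <- numeric(nt)
  for (k in seq_len(nt)) {
    x <- a[, , k]
    ok <- !is.na(x) & w0 > 0
    if (!any(ok)) { vals[k] <- NA_real_; next }
    w <- w0[ok] / sum(w0[ok])
    if (kind == "geometric") {
      if (any(x[ok] <= 0))
        stop("geometric mean requires strictly positive values")
      vals[k] <- exp(sum(w * log(x[ok])))
    } else {
      vals[k] <- sum(w * x[ok])
    }
  }
  structure(data.frame(time = grid$time, value = vals),
            variable = var, region = mask$name, kind = kind,
            class = c("regional_series", "data.frame"))
}

#' Standardized anomaly of a monthly regional series
#'
#' z_t = (x_t - mu) / sigma, where mu and sigma are the mean and sample SD
#' (n-1 denominator) of all baseline monthly means, i.e. months in years
#' up to and including `baseline_end_year`. The default standardization is
#' against the overall baseline (not a per-calendar-month climatology), so
#' the z series retains its seasonal cycle; set `per_month = TRUE` for a
#' per-calendar-month baseline instead.
#'
#' @param series a `regional_series` (or data.frame with `time`, `value`)
#' @param baseline_end_year last year included in the baseline
#' @param per_month standardize against per-calendar-month baselines
#' @return data.frame with columns `time`, `z` plus attributes recording
#'   the baseline used
#' @export
standardized_anomaly <- function(series, baseline_end_year = 2021,
                                 per_month = FALSE) {
  yr <- as.integer(format(series$time, "%Y"))
  mo <- as.integer(format(series$time, "%m"))
  base <- yr <= baseline_end_year & !is.na(series$value)
  if (sum(base) < 24) stop("need at least 24 baseline months")
  if (per_month) {
    z <- rep(NA_real_, nrow(series))
    for (m in 1:12) {
      b <- base & mo == m
      mu <- mean(series$value[b]); sg <- sd(series$value[b])
      if (!is.finite(sg) || sg == 0) stop("degenerate baseline (sd = 0)")
      k <- mo == m
      z[k] <- (series$value[k] - mu) / sg
    }
  } else {
    mu <- mean(series$value[base]); sg <- sd(series$value[base])
    if (!is.finite(sg) || sg == 0) stop("degenerate baseline (sd = 0)")
    z <- (series$value - mu) / sg
  }
  structure(data.frame(time = series$time, z = z),
            baseline_end_year = baseline_end_year, per_month = per_month,
            class = c("anomaly_score", "data.frame"))
}

#' Per-cell anomaly map of a gridded AOT dataset for one calendar month
#'
#' For each grid cell, the anomaly is the 2022 value of the given calendar
#' month minus the mean of that calendar month over the baseline years.
#' Cells with fewer than `min_months` baseline samples are masked (NA in
#' the anomaly, TRUE in the returned mask), mirroring the coverage rule
#' used for limb-profiler aerosol climatologies.
#'
#' @param grid an `oc_grid` with an AOT field
#' @param var field name (default "aot675")
#' @param month_of_year calendar month (1-12)
#' @param baseline_years years forming the baseline
#' @param min_months minimum number of baseline samples per cell
#' @return list with matrices `anomaly` (lat x lon) and `masked` (logical)
#' @export
aot_anomaly_map <- function(grid, var = "aot675", month_of_year = 6,
                            baseline_years = 2012:2021, min_months = 6) {
  stopifnot(inherits(grid, "oc_grid"))
  yr <- as.integer(format(grid$time, "%Y"))
  mo <- as.integer(format(grid$time, "%m"))
  k2022 <- which(yr == 2022 & mo == month_of_year)
  if (length(k2022) != 1) stop("month ", month_of_year, " absent in 2022")
  kb <- which(yr %in% baseline_years & mo == month_of_year)
  a <- grid$fields[[var]]
  cur <- a[, , k2022]
  base <- a[, , kb, drop = FALSE]
  nbase <- apply(!is.na(base), c(1, 2), sum)
  bmean <- apply(base, c(1, 2), mean, na.rm = TRUE)
  anom <- cur - bmean
  masked <- nbase < min_months
  anom[masked] <- NA_real_
  list(anomaly = anom, masked = masked, lat = grid$lat, lon = grid$lon,
       n_baseline = nbase)
}
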