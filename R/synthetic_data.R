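#' Parameters for the synthetic ocean-color field generator
#'
#' The generator emulates multi-year monthly Level-3-style fields of
#' Rrs(443), Rrs(547), b_bp(443) and Chla: one annual sinusoid per
#' hemisphere (phases opposed by six months), multiplicative lognormal
#' noise, and an optional per-variable multiplicative monthly bias applied
#' to calendar year 2022 only.
#'
#' @param years inclusive year range (integer vector or c(first, last))
#' @param res grid resolution in degrees (equal-angle)
#' @param seasonal_amplitude seasonal amplitude as a fraction of the mean,
#'   in \[0, 1)
#' @param mean_levels named numeric: per-variable baseline
#'   (`Rrs443` sr-1, `Rrs547` sr-1, `bbp443` m-1, `chla` mg m-3)
#' @param noise_cv lognormal coefficient of variation (>= 0)
#' @param bias_2022 optional named list of length-12 multiplicative monthly
#'   bias profiles, applied to 2022 only (names must match `mean_levels`)
#' @param seed integer RNG seed
#' @return a list of class `oc_field_params`
#' @export
oc_field_params <- function(years = c(2002, 2022), res = 10,
                            seasonal_amplitude = 0.05,
                            mean_levels = c(Rrs443 = 0.008, Rrs547 = 0.0018,
                                            bbp443 = 0.001, chla = 0.15),
                            noise_cv = 0.05, bias_2022 = NULL, seed = 1L) {
  years <- seq(min(years), max(years))
  if (length(years) < 1) stop("invalid year range")
  if (res <= 0 || 180 %% res != 0) stop("invalid grid resolution")
  if (any(mean_levels <= 0)) stop("mean_levels must be strictly positive")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (seasonal_amplitude < 0 || seasonal_amplitude >= 1)
    stop("seasonal_amplitude must lie in [0, 1)")
  if (!is.null(bias_2022)) {
    if (!all(names(bias_2022) %in% names(mean_levels)))
      stop("bias_2022 names must match mean_levels")
    if (any(vapply(bias_2022, length, 1L) != 12))
      stop("bias_2022 profiles must have 12 monthly entries")
  }
  structure(list(years = years, res = res,
                 seasonal_amplitude = seasonal_amplitude,
                 mean_levels = mean_levels, noise_cv = noise_cv,
                 bias_2022 = bias_2022, seed = as.integer(seed)),
            class = "oc_field_params")
}

# seasonal factor: NH peaks in June, SH in December (opposed phases);
# amplitude tapers to zero at the equator over +-10 degrees
seasonal_factor <- function(lat, month, amplitude) {
  phase <- ifelse(lat >= 0, 6, 12)          # calendar month of the peak
  taper <- pmin(abs(lat) / 10, 1)
  1 + amplitude * taper * cos(2 * pi * (month - phase) / 12)
}

# mean-preserving multiplicative lognormal noise with coefficient of
# variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate synthetic gridded monthly ocean-color fields
#'
#' Deterministic for a given seed. If `bias_2022` is set, the 2022 fields
#' equal the unbiased fields multiplied by the monthly bias profile, so
#' injected effects are exactly known to downstream tests.
#'
#' @param params an [oc_field_params()] object
#' @return an `oc_grid` with fields `Rrs443`, `Rrs547`, `bbp443`, `chla`
#' @export
gen_oc_fields <- function(params) {
  stopifnot(inherits(params, "oc_field_params"))
  ax <- grid_axes(params$res)
  time <- month_mid_dates(params$years)
  months <- as.integer(format(time, "%m"))
  years <- as.integer(format(time, "%Y"))
  nlat <- length(ax$lat); nlon <- length(ax$lon); nt <- length(time)
  seas <- outer(ax$lat, months,
                function(la, mo) seasonal_factor(la, mo, params$seasonal_amplitude))
  set.seed(params$seed)
  fields <- list()
  for (nm in names(params$mean_levels)) {
    base <- params$mean_levels[[nm]] *
      aperm(array(rep(seas, nlon), c(nlat, nt, nlon)), c(1, 3, 2))
    noise <- array(lognormal_noise(nlat * nlon * nt, params$noise_cv),
                   c(nlat, nlon, nt))
    a <- base * noise
    if (!is.null(params$bias_2022[[nm]])) {
      for (m in 1:12) {
        k <- which(years == 2022 & months == m)
        if (length(k)) a[, , k] <- a[, , k] * params$bias_2022[[nm]][m]
      }
    }
    fields[[nm]] <- a
  }
  oc_grid(ax$lat, ax$lon, time, fields,
          units = c(Rrs443 = "sr-1", Rrs547 = "sr-1",
                    bbp443 = "m-1", chla = "mg m-3")[names(fields)])
}

#' Parameters for the synthetic stratospheric AOT field generator
#'
#' Emulates a limb-profiler style monthly stratospheric aerosol optical
#' thickness product at 675 nm on a 5 deg lat x 15 deg lon grid: lognormal
#' fluctuation about a baseline, plus a 2022 pulse that is Gaussian in
#' latitude and in month. The pulse amplitude is calibrated in log space so
#' that the area-weighted geometric mean over the reference region (SH,
#' 0-50 S) reaches `pulse_peak_factor` x baseline at `pulse_peak_month`,
#' matching the reported 6-7 fold peak.
#'
#' @param years inclusive year range
#' @param baseline_aot dimensionless AOT at 675 nm (> 0)
#' @param pulse_peak_factor fold-increase of the SH regional geometric mean
#'   at the peak (>= 1)
#' @param pulse_peak_month calendar month of the 2022 peak
#' @param pulse_lat_center,pulse_lat_width pulse latitude center / Gaussian
#'   width (degrees)
#' @param noise_cv lognormal cv of the baseline fluctuation
#' @param res_lat,res_lon grid resolution (degrees)
#' @param seed integer RNG seed
#' @export
aot_field_params <- function(years = c(2012, 2022), baseline_aot = 0.005,
                             pulse_peak_factor = 6.5, pulse_peak_month = 6,
                             pulse_lat_center = -22, pulse_lat_width = 18,
                             noise_cv = 0.15, res_lat = 5, res_lon = 15,
                             seed = 1L) {
  years <- seq(min(years), max(years))
  if (baseline_aot <= 0) stop("baseline_aot must be > 0")
  if (pulse_peak_factor < 1) stop("pulse_peak_factor must be >= 1")
  if (!pulse_peak_month %in% 1:12) stop("invalid pulse_peak_month")
  structure(list(years = years, baseline_aot = baseline_aot,
                 pulse_peak_factor = pulse_peak_factor,
                 pulse_peak_month = pulse_peak_month,
                 pulse_lat_center = pulse_lat_center,
                 pulse_lat_width = pulse_lat_width,
                 noise_cv = noise_cv, res_lat = res_lat, res_lon = res_lon,
                 seed = as.integer(seed)),
            class = "aot_field_params")
}

# normalized pulse shape in log space: Gaussian in latitude scaled so the
# cos-weighted mean over 0-50 S equals 1, times a Gaussian month profile
# (the eruption is in January; the sulfate conversion delays the peak)
aot_pulse_logfactor <- function(lat, month, params) {
  g <- exp(-((lat - params$pulse_lat_center)^2) /
             (2 * params$pulse_lat_width^2))
  sh <- lat > -50 & lat < 0
  gbar <- sum(g[sh] * cos(lat[sh] * pi / 180)) / sum(cos(lat[sh] * pi / 180))
  tshape <- ifelse(month >= 2,
                   exp(-((month - params$pulse_peak_month)^2) / (2 * 2.5^2)), 0)
  log(params$pulse_peak_factor) * outer(g / gbar, tshape)
}

#' Generate a synthetic gridded stratospheric AOT dataset
#' @param params an [aot_field_params()] object
#' @return an `oc_grid` with field `aot675`
#' @export
gen_aot_field <- function(params) {
  stopifnot(inherits(params, "aot_field_params"))
  ax <- grid_axes(params$res_lat, params$res_lon)
  time <- month_mid_dates(params$years)
  months <- as.integer(format(time, "%m"))
  years <- as.integer(format(time, "%Y"))
  nlat <- length(ax$lat); nlon <- length(ax$lon); nt <- length(time)
  set.seed(params$seed)
  a <- array(params$baseline_aot * lognormal_noise(nlat * nlon * nt, params$noise_cv),
             c(nlat, nlon, nt))
  lf <- aot_pulse_logfactor(ax$lat, 1:12, params)   # nlat x 12
  for (k in which(years == 2022)) {
    a[, , k] <- a[, , k] * exp(lf[, months[k]])
  }
  oc_grid(ax$lat, ax$lon, time, list(aot675 = a), units = c(aot675 = "1"))
}

#' Parameters for the synthetic BGC-Argo profile generator
#'
#' @param n_floats number of floats
#' @param profiles_per_float casts per float, spread evenly over `years`
#' @param years inclusive year range of the deployment
#' @param depth_grid sampling depths in m (must span at least 5-750 m)
#' @param surface_bbp true surface b_bp(700) baseline (m-1)
#' @param deep_bbp true b_bp(700) in the 700-750 m reference region (m-1)
#' @param noise_cv multiplicative lognormal measurement noise cv
#' @param spike_rate fraction of samples replaced by positive spikes, in \[0,1)
#' @param spike_magnitude multiplicative spike amplitude
#' @param float_offset_sd SD of the per-float additive sensor offset (m-1)
#' @param seed integer RNG seed
#' @export
argo_set_params <- function(n_floats = 8, profiles_per_float = 40,
                            years = c(2016, 2022),
                            depth_grid = seq(5, 750, by = 5),
                            surface_bbp = 4e-4, deep_bbp = 2e-4,
                            noise_cv = 0.05, spike_rate = 0.01,
                            spike_magnitude = 10, float_offset_sd = 5e-5,
                            seed = 1L) {
  if (min(depth_grid) > 5 || max(depth_grid) < 750)
    stop("depth_grid must span at least 5-750 m")
  if (spike_rate < 0 || spike_rate >= 1) stop("spike_rate must lie in [0, 1)")
  structure(list(n_floats = n_floats, profiles_per_float = profiles_per_float,
                 years = seq(min(years), max(years)),
                 depth_grid = sort(depth_grid),
                 surface_bbp = surface_bbp, deep_bbp = deep_bbp,
                 noise_cv = noise_cv, spike_rate = spike_rate,
                 spike_magnitude = spike_magnitude,
                 float_offset_sd = float_offset_sd, seed = as.integer(seed)),
            class = "argo_set_params")
}

#' Generate a synthetic BGC-Argo b_bp(700) profile table
#'
#' Profiles decay exponentially from a surface baseline to a deep value,
#' carry per-float additive offsets, isolated multiplicative spikes, and
#' lognormal noise. Ground-truth columns (`true_bbp700`, `is_spike`,
#' `float_offset`) are retained so the QC chain can be tested closed-loop.
#'
#' @param params an [argo_set_params()] object
#' @return a data.frame with columns float_id, time, lat, lon, depth_m,
#'   bbp700_m.1 plus ground-truth columns
#' @export
gen_argo_profiles <- function(params) {
  stopifnot(inherits(params, "argo_set_params"))
  set.seed(params$seed)
  z <- params$depth_grid
  nz <- length(z)
  shape <- params$deep_bbp +
    (params$surface_bbp - params$deep_bbp) * exp(-z / 150)
  yr0 <- min(params$years); yr1 <- max(params$years)
  out <- vector("list", params$n_floats)
  for (f in seq_len(params$n_floats)) {
    offset <- rnorm(1, 0, params$float_offset_sd)
    # cast times spread over the deployment, jittered within ~10 days
    frac <- (seq_len(params$profiles_per_float) - runif(params$profiles_per_float)) /
      params$profiles_per_float
    t0 <- as.Date(sprintf("%d-01-01", yr0))
    t1 <- as.Date(sprintf("%d-12-31", yr1))
    times <- t0 + round(as.numeric(t1 - t0) * sort(frac))
    lat <- runif(params$profiles_per_float, -40, -20)
    lon <- runif(params$profiles_per_float, -150, -110)
    casts <- vector("list", params$profiles_per_float)
    for (p in seq_len(params$profiles_per_float)) {
      truth <- shape * lognormal_noise(nz, params$noise_cv)
      v <- truth + offset
      spike <- runif(nz) < params$spike_rate
      v[spike] <- v[spike] * params$spike_magnitude
      casts[[p]] <- data.frame(
        float_id = sprintf("F%03d", f),
        time = format(times[p]),
        lat = lat[p], lon = lon[p], depth_m = z,
        bbp700_m.1 = v, true_bbp700 = truth,
        is_spike = spike, float_offset = offset)
    }
    out[[f]] <- do.call(rbind, casts)
  }
  do.call(rbind, out)
}

#' Write an Argo-style profile table as CSV
#'
#' Uses the column dialect `float_id, time, lat, lon, depth_m, bbp700_m-1`;
#' ground-truth columns, when present, are dropped.
#' @param profiles data.frame from [gen_argo_profiles()]
#' @param path output path
#' @export
write_argo_csv <- function(profiles, path) {
  keep <- c("float_id", "time", "lat", "lon", "depth_m", "bbp700_m.1")
  d <- profiles[, keep]
  names(d) <- c("float_id", "time", "lat", "lon", "depth_m", "bbp700_m-1")
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an Argo-style profile CSV
#' @param path file path
#' @export
read_argo_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  names(d)[names(d) == "bbp700_m.1"] <- "bbp700_m.1"
  d
}
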