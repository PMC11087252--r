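#' Sensor spectral band
#'
#' @param name band name
#' @param center center wavelength (nm)
#' @param srf data.frame with columns `wavelength` (nm, strictly
#'   increasing) and `response` (>= 0, not all zero)
#' @export
spectral_band <- function(name, center, srf) {
  stopifnot(is.data.frame(srf), all(c("wavelength", "response") %in% names(srf)))
  if (is.unsorted(srf$wavelength, strictly = TRUE))
    stop("SRF wavelength grid must be strictly increasing")
  if (any(srf$response < 0) || all(srf$response == 0))
    stop("SRF response must be >= 0 and not all zero")
  structure(list(name = name, center = center, srf = srf),
            class = "spectral_band")
}

#' Default band set
#'
#' Eight bands at 412, 443, 488, 531, 547, 667, 748 and 869 nm with
#' Gaussian spectral response functions (sigma 5 nm, sampled at 0.5 nm over
#' +-3 sigma) — a MODIS-like configuration for ocean-color work.
#'
#' @param centers band center wavelengths (nm)
#' @param sigma SRF Gaussian width (nm)
#' @return named list of [spectral_band()] objects
#' @export
default_bands <- function(centers = c(412, 443, 488, 531, 547, 667, 748, 869),
                          sigma = 5) {
  out <- lapply(centers, function(cw) {
    wl <- seq(cw - 3 * sigma, cw + 3 * sigma, by = 0.5)
    spectral_band(as.character(cw), cw,
                  data.frame(wavelength = wl,
                             response = exp(-(wl - cw)^2 / (2 * sigma^2))))
  })
  names(out) <- as.character(centers)
  out
}

#' Gas absorption spectrum
#'
#' @param gas gas name ("O3", "H2O", ...)
#' @param table data.frame with columns `wavelength` (nm) and `k`
#'   (absorption coefficient per unit amount: per DU for ozone, per cm of
#'   precipitable water)
#' @param amount_units "DU" or "cm"
#' @export
gas_spectrum <- function(gas, table, amount_units) {
  stopifnot(all(c("wavelength", "k") %in% names(table)))
  if (any(table$k < 0)) stop("absorption coefficients must be >= 0")
  structure(list(gas = gas, table = table, amount_units = amount_units),
            class = "gas_spectrum")
}

#' Default (synthetic) gas absorption spectra
#'
#' Smooth stylized spectra on a 1-nm grid from 350 to 950 nm. Ozone is a
#' skewed Gaussian Chappuis-like band centered at 602 nm (width 90 nm on
#' the blue side, 50 nm on the red side) with a peak coefficient of
#' 1.21e-4 per DU, giving a 320 DU vertical optical depth of about 0.031
#' at 547 nm. Water vapor has two narrow bands at 724 and 823 nm, placed
#' so the default band set largely avoids them (the 748 nm band catches a
#' weak tail). Real literature cross sections can be supplied through
#' [gas_spectrum()] / [read_spectral_table()] instead.
#'
#' @return named list of [gas_spectrum()] objects (`O3`, `H2O`)
#' @export
default_gas_spectra <- function() {
  wl <- seq(350, 950, by = 1)
  w_o3 <- ifelse(wl < 602, 90, 50)
  k_o3 <- 1.21e-4 * exp(-((wl - 602)^2) / (2 * w_o3^2))
  k_h2o <- 0.004 * exp(-((wl - 724)^2) / (2 * 13^2)) +
           0.040 * exp(-((wl - 823)^2) / (2 * 14^2))
  list(O3  = gas_spectrum("O3",  data.frame(wavelength = wl, k = k_o3),  "DU"),
       H2O = gas_spectrum("H2O", data.frame(wavelength = wl, k = k_h2o), "cm"))
}

#' Read a two-column spectral table (wavelength, value)
#'
#' Accepts whitespace- or comma-separated text with optional `#` comments.
#' @param path file path
#' @return data.frame with columns `wavelength`, `value`
#' @export
read_spectral_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sep <- if (any(grepl(",", lines))) "," else ""
  d <- read.table(text = lines, sep = sep, header = FALSE,
                  col.names = c("wavelength", "value"))
  d[order(d$wavelength), ]
}

#' Two-path plane-parallel airmass
#'
#' M = sec(theta_s) + sec(theta_v): the geometric gas airmass of the
#' direct sun-to-surface-to-sensor path.
#'
#' @param sza solar zenith angle (degrees, in \[0, 75\])
#' @param vza view zenith angle (degrees, in \[0, 75\])
#' @export
airmass_two_path <- function(sza, vza) {
  if (any(c(sza, vza) < 0) || any(c(sza, vza) > 75))
    stop("zenith angles must lie in [0, 75] degrees")
  1 / cos(sza * pi / 180) + 1 / cos(vza * pi / 180)
}

#' Band-integrated gas transmittance
#'
#' T = int SRF(l) exp(-k(l) U M) dl / int SRF(l) dl, integrated by the
#' trapezoid rule on the SRF wavelength grid with the gas coefficient
#' linearly interpolated onto it.
#'
#' @param band a [spectral_band()]
#' @param gas a [gas_spectrum()]
#' @param amount gas amount (DU or cm; >= 0)
#' @param M two-path airmass from [airmass_two_path()]
#' @return band-averaged transmittance in (0, 1]
#' @export
band_transmittance <- function(band, gas, amount, M) {
  if (amount < 0) stop("gas amount must be >= 0")
  if (amount == 0) return(1.0)
  wl <- band$srf$wavelength
  if (min(wl) > max(gas$table$wavelength) || max(wl) < min(gas$table$wavelength))
    stop("SRF and gas spectrum wavelength ranges are disjoint")
  k <- approx(gas$table$wavelength, gas$table$k, wl, rule = 2)$y
  s <- band$srf$response
  tr <- exp(-k * amount * M)
  trapz_ratio(wl, s * tr, s)
}

# trapezoid integral ratio: int f / int g on a common grid
trapz_ratio <- function(x, f, g) {
  dx <- diff(x)
  num <- sum(dx * (f[-1] + f[-length(f)])) / 2
  den <- sum(dx * (g[-1] + g[-length(g)])) / 2
  num / den
}

#' Rayleigh optical depth
#'
#' Hansen & Travis (1974) closed form for the standard atmosphere,
#' tau = 0.008569 l^-4 (1 + 0.0113 l^-2 + 0.00013 l^-4) with l in microns,
#' scaled linearly with surface pressure.
#'
#' @param wavelength_nm wavelength in nm (350-900)
#' @param pressure_hpa surface pressure (hPa)
#' @export
rayleigh_od <- function(wavelength_nm, pressure_hpa = 1013.25) {
  if (any(wavelength_nm < 350) || any(wavelength_nm > 900))
    stop("wavelength must lie in [350, 900] nm")
  lam <- wavelength_nm / 1000
  tau0 <- 0.008569 * lam^-4 * (1 + 0.0113 * lam^-2 + 0.00013 * lam^-4)
  tau0 * pressure_hpa / 1013.25
}

#' Angstrom exponent from two optical depths
#'
#' alpha = -ln(tau1/tau2) / ln(lambda1/lambda2)
#' @param tau1,tau2 optical depths (> 0)
#' @param lambda1,lambda2 wavelengths (> 0, any common unit)
#' @export
angstrom_exponent <- function(tau1, lambda1, tau2, lambda2) {
  if (any(c(tau1, tau2, lambda1, lambda2) <= 0))
    stop("optical depths and wavelengths must be > 0")
  -log(tau1 / tau2) / log(lambda1 / lambda2)
}

#' Gas vertical profile
#'
#' @param gas gas name
#' @param column total column amount (DU or cm)
#' @param height_km height grid (km, strictly increasing)
#' @param density relative density on the height grid (>= 0, integrates
#'   to 1 after normalization, which the constructor applies)
#' @export
gas_profile <- function(gas, column, height_km, density) {
  if (any(density < 0) || all(density == 0)) stop("invalid density profile")
  if (is.unsorted(height_km, strictly = TRUE)) stop("height grid must increase")
  dz <- diff(height_km)
  tot <- sum(dz * (density[-1] + density[-length(density)])) / 2
  structure(list(gas = gas, column = column, height_km = height_km,
                 density = density / tot),
            class = "gas_profile")
}

#' Default gas vertical profiles
#'
#' Ozone: Gaussian layer centered at 25 km with 5 km SD, so a 23 km
#' aerosol layer sits inside it (the co-mingling the eruption produced);
#' water vapor: exponential with 2 km scale height. Height grid 0-50 km at
#' 0.25 km. Columns default to the simulation scenario (320 DU, 1.25 cm).
#'
#' @param ozone_du ozone column (DU)
#' @param wv_cm water-vapor column (cm)
#' @export
default_gas_profiles <- function(ozone_du = 320, wv_cm = 1.25) {
  z <- seq(0, 50, by = 0.25)
  list(O3 = gas_profile("O3", ozone_du, z, exp(-((z - 25)^2) / (2 * 5^2))),
       H2O = gas_profile("H2O", wv_cm, z, exp(-z / 2)))
}

#' Fraction of a gas column strictly above a given height
#'
#' Monotonically decreasing in z; 1 below the whole profile, 0 above it.
#'
#' @param profile a [gas_profile()]
#' @param z_km height (km), within the profile grid
#' @export
gas_fraction_above <- function(profile, z_km) {
  z <- profile$height_km; d <- profile$density
  if (z_km <= min(z)) return(1.0)
  if (z_km >= max(z)) return(0.0)
  dz <- diff(z)
  cum <- c(0, cumsum(dz * (d[-1] + d[-length(d)]) / 2))  # mass below z[i]
  below <- approx(z, cum, z_km)$y
  max(0, min(1, 1 - below))
}
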