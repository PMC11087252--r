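#' Observation geometry
#' @param sza solar zenith (deg, \[0, 75\])
#' @param vza view zenith (deg, \[0, 75\])
#' @param raa relative azimuth (deg, \[0, 180\])
#' @export
geometry <- function(sza, vza = 25, raa = 80) {
  if (sza < 0 || sza > 75 || vza < 0 || vza > 75)
    stop("zenith angles must lie in [0, 75] degrees")
  if (raa < 0 || raa > 180) stop("relative azimuth must lie in [0, 180]")
  structure(list(sza = sza, vza = vza, raa = raa,
                 mus = cos(sza * pi / 180), muv = cos(vza * pi / 180)),
            class = "geometry")
}

#' Scattering angle of the single-scattered reflected beam
#'
#' Angle between the incoming solar propagation direction and the
#' direction toward the sensor; 180 deg is exact backscatter.
#' @param geom a [geometry()]
#' @return scattering angle in degrees
#' @export
scattering_angle <- function(geom) {
  ss <- sin(geom$sza * pi / 180); sv <- sin(geom$vza * pi / 180)
  cosT <- -geom$mus * geom$muv - ss * sv * cos(geom$raa * pi / 180)
  acos(pmax(-1, pmin(1, cosT))) * 180 / pi
}

#' Henyey-Greenstein phase function
#' @param g asymmetry parameter (-1, 1)
#' @param theta_deg scattering angle (deg)
#' @return phase function value, normalized so that
#'   (1/2) int P(theta) sin(theta) dtheta = 1
#' @export
hg_phase <- function(g, theta_deg) {
  ct <- cos(theta_deg * pi / 180)
  (1 - g^2) / (1 + g^2 - 2 * g * ct)^1.5
}

#' Gaussian aerosol layer
#' @param center_km layer center height (km)
#' @param width_km layer width, one SD (km, > 0)
#' @param aot869 aerosol optical thickness at 869 nm (>= 0)
#' @param model an [aerosol_model()] with Mie optics attached
#' @export
gaussian_layer <- function(center_km, width_km, aot869, model) {
  if (width_km <= 0) stop("layer width must be > 0")
  if (aot869 < 0) stop("layer AOT must be >= 0")
  structure(list(center_km = center_km, width_km = width_km,
                 aot869 = aot869, model = model),
            class = "gaussian_layer")
}

#' Atmospheric state: aerosol layers + gas profiles + surface pressure
#' @param layers list of [gaussian_layer()] (sorted by center height)
#' @param gas_profiles named list of [gas_profile()] (`O3`, `H2O`)
#' @param pressure_hpa surface pressure
#' @export
atmosphere_state <- function(layers, gas_profiles = default_gas_profiles(),
                             pressure_hpa = 1013.25) {
  if (!length(layers)) stop("need at least one aerosol layer")
  hh <- vapply(layers, `[[`, 1.0, "center_km")
  layers <- layers[order(hh)]
  structure(list(layers = layers, gas_profiles = gas_profiles,
                 pressure_hpa = pressure_hpa),
            class = "atmosphere_state")
}

#' Ocean state
#' @param chla chlorophyll-a concentration (mg m-3, > 0)
#' @param wind wind speed (m s-1, >= 0); recorded metadata — the
#'   single-scattering simulator carries no glint or whitecap term
#' @export
ocean_state <- function(chla = 0.3, wind = 5) {
  if (chla <= 0 || wind < 0) stop("invalid ocean state")
  structure(list(chla = chla, wind = wind), class = "ocean_state")
}

#' Single-scattering reflectance of one aerosol layer in one band
#'
#' rho = ssa * tau(lambda) * P(Theta) / (4 mu_s mu_v), with P the
#' Henyey-Greenstein parameterization of the layer model's Mie asymmetry
#' parameter. Zero when the layer AOT is zero; linear in AOT.
#'
#' @param layer a [gaussian_layer()]
#' @param wavelength_nm band center wavelength
#' @param geom a [geometry()]
#' @export
single_scatter_reflectance <- function(layer, wavelength_nm, geom) {
  if (layer$aot869 == 0) return(0)
  tau <- layer$aot869 * model_optic(layer$model, wavelength_nm, "ext_rel")
  ssa <- model_optic(layer$model, wavelength_nm, "ssa")
  g <- model_optic(layer$model, wavelength_nm, "g")
  theta <- scattering_angle(geom)
  ssa * tau * hg_phase(g, theta) / (4 * geom$mus * geom$muv)
}

#' Rayleigh single-scattering reflectance
#' @param wavelength_nm wavelength (nm)
#' @param geom a [geometry()]
#' @param pressure_hpa surface pressure (hPa)
#' @export
rayleigh_reflectance <- function(wavelength_nm, geom, pressure_hpa = 1013.25) {
  tau <- rayleigh_od(wavelength_nm, pressure_hpa)
  theta <- scattering_angle(geom)
  pr <- 0.75 * (1 + cos(theta * pi / 180)^2)
  tau * pr / (4 * geom$mus * geom$muv)
}

# aggregated (extinction-weighted) aerosol tau, ssa, g across layers at
# one wavelength
aggregate_aerosol <- function(layers, wavelength_nm) {
  tau <- vapply(layers, function(l)
    l$aot869 * model_optic(l$model, wavelength_nm, "ext_rel"), 1.0)
  ssa <- vapply(layers, function(l)
    model_optic(l$model, wavelength_nm, "ssa"), 1.0)
  g <- vapply(layers, function(l)
    model_optic(l$model, wavelength_nm, "g"), 1.0)
  tt <- sum(tau)
  if (tt == 0) return(list(tau = 0, ssa = 1, g = 0.7))
  sc <- sum(tau * ssa)
  list(tau = tt, ssa = sc / tt, g = sum(tau * ssa * g) / sc)
}

# two-leg diffuse transmittance at one wavelength: Rayleigh (half, the
# forward-scattered part survives) plus non-forward aerosol scattering
diffuse_transmittance <- function(wavelength_nm, geom, layers, pressure_hpa,
                                  forward_fraction = NULL) {
  agg <- aggregate_aerosol(layers, wavelength_nm)
  ff <- if (is.null(forward_fraction)) (1 + agg$g) / 2 else forward_fraction
  taur <- rayleigh_od(wavelength_nm, pressure_hpa)
  taud <- taur / 2 + (1 - agg$ssa * ff) * agg$tau
  exp(-taud / geom$mus) * exp(-taud / geom$muv)
}

# band-effective gas transmittances for a layer at height h:
# ordered transmittance uses only the gas fraction above the layer
layer_gas_transmittance <- function(band, gas_spectra, gas_profiles,
                                    center_km, M) {
  fo3 <- gas_fraction_above(gas_profiles$O3, center_km)
  fwv <- gas_fraction_above(gas_profiles$H2O, center_km)
  band_transmittance(band, gas_spectra$O3, gas_profiles$O3$column * fo3, M) *
    band_transmittance(band, gas_spectra$H2O, gas_profiles$H2O$column * fwv, M)
}

# scattering-absorption coupling factor per band: elevated scattering
# layers intercept the upwelling lower-atmosphere radiance (probability
# ~ tau_sca * M) and redirect it through the ozone below the layer with
# multiplied path length; kappa absorbs the interception-times-recrossing
# geometry (see the methods vignette). Applied to the Rayleigh + water
# terms. Equals 1 when every layer sits below the ozone. Restricted to
# ozone: it models the stratospheric co-mingling, and the band set avoids
# the water-vapor bands by design.
coupling_factor <- function(band, gas_spectra, gas_profiles, layers, M,
                            kappa) {
  if (kappa == 0) return(1.0)
  expo <- 0
  for (l in layers) {
    if (l$aot869 == 0) next
    tausca <- l$aot869 * model_optic(l$model, band$center, "ext_rel") *
      model_optic(l$model, band$center, "ssa")
    fo3 <- gas_fraction_above(gas_profiles$O3, l$center_km)
    ab <- 1 - band_transmittance(band, gas_spectra$O3,
                                 gas_profiles$O3$column * (1 - fo3), M)
    expo <- expo + tausca * M * ab
  }
  exp(-kappa * expo)
}

#' Simulate layered top-of-atmosphere reflectance
#'
#' Layer-ordered single-scattering model: each aerosol layer's reflectance
#' is attenuated only by the gas above it, while the Rayleigh and
#' water-leaving terms (which originate below the gas) carry the full
#' column transmittance times a first-order scattering-absorption coupling
#' factor that accounts for path lengthening of diffuse light by elevated
#' scattering layers. The component breakdown sums exactly to the total.
#'
#' @param atm an [atmosphere_state()]
#' @param ocean an [ocean_state()]
#' @param geom a [geometry()]
#' @param bands list of [spectral_band()] (default [default_bands()])
#' @param gas_spectra named list from [default_gas_spectra()]
#' @param rrs_in optional per-band water Rrs (sr-1); computed from the
#'   bio-optical forward model at the ocean state's Chla when NULL
#' @param options list: `kappa` (coupling constant, default 3),
#'   `forward_fraction` (NULL = (1+g)/2 from the aggregate Mie asymmetry)
#' @return object of class `toa_spectrum`: data.frame `spectrum` with
#'   per-band total and component reflectances, plus inputs for closure
#'   bookkeeping
#' @export
simulate_toa <- function(atm, ocean, geom, bands = default_bands(),
                         gas_spectra = default_gas_spectra(),
                         rrs_in = NULL,
                         options = list()) {
  kappa <- if (is.null(options$kappa)) 3 else options$kappa
  ffrac <- options$forward_fraction
  wl <- vapply(bands, `[[`, 1.0, "center")
  M <- airmass_two_path(geom$sza, geom$vza)
  if (is.null(rrs_in)) {
    state <- bio_state_from_ocean(ocean)
    rrs_in <- forward_rrs(state, default_iop_tables(), wl)$Rrs
  }
  nl <- length(atm$layers)
  rho_a <- matrix(0, nl, length(wl))
  for (i in seq_len(nl)) {
    lay <- atm$layers[[i]]
    tg <- unname(vapply(bands, layer_gas_transmittance, 1.0,
                        gas_spectra = gas_spectra,
                        gas_profiles = atm$gas_profiles,
                        center_km = lay$center_km, M = M))
    rho_a[i, ] <- vapply(wl, single_scatter_reflectance, 1.0,
                         layer = lay, geom = geom) * tg
  }
  tgas_full <- unname(vapply(bands, function(b)
    band_transmittance(b, gas_spectra$O3, atm$gas_profiles$O3$column, M) *
    band_transmittance(b, gas_spectra$H2O, atm$gas_profiles$H2O$column, M),
    1.0))
  cpl <- unname(vapply(bands, coupling_factor, 1.0,
                       gas_spectra = gas_spectra,
                       gas_profiles = atm$gas_profiles, layers = atm$layers,
                       M = M, kappa = kappa))
  rho_r <- unname(vapply(wl, rayleigh_reflectance, 1.0, geom = geom,
                         pressure_hpa = atm$pressure_hpa)) * tgas_full * cpl
  tdif <- unname(vapply(wl, diffuse_transmittance, 1.0, geom = geom,
                        layers = atm$layers,
                        pressure_hpa = atm$pressure_hpa,
                        forward_fraction = ffrac))
  rho_w <- tdif * pi * rrs_in * tgas_full * cpl
  spectrum <- data.frame(wavelength = unname(wl),
                         rho_t = colSums(rho_a) + rho_r + rho_w,
                         rho_r = rho_r, rho_w = rho_w)
  for (i in seq_len(nl)) spectrum[[paste0("rho_a", i)]] <- rho_a[i, ]
  structure(list(spectrum = spectrum, rrs_in = rrs_in, t_diffuse = tdif,
                 coupling = cpl, tgas_full = tgas_full, geom = geom,
                 atm = atm, ocean = ocean, M = M,
                 options = list(kappa = kappa, forward_fraction = ffrac)),
            class = "toa_spectrum")
}

#' Paired with/without-stratosphere scenario runs
#'
#' For each month, simulates the two-layer atmosphere (troposphere +
#' stratospheric layer with that month's AOT) and the matching
#' troposphere-only atmosphere under the same geometry.
#'
#' @param strat_aot869 12 monthly stratospheric AOT values at 869 nm (>= 0)
#' @param geometries list of 12 [geometry()] objects
#' @param config a [scenario_config()]
#' @return list of 12 elements, each `list(with = , without = )`
#' @export
run_scenarios <- function(strat_aot869, geometries, config = scenario_config()) {
  if (length(strat_aot869) != length(geometries))
    stop("AOT series and geometry series lengths differ")
  if (any(strat_aot869 < 0)) stop("stratospheric AOT must be >= 0")
  lapply(seq_along(strat_aot869), function(k) {
    g <- geometries[[k]]
    trop <- gaussian_layer(config$trop_height_km, config$layer_width_km,
                           config$trop_aot869, config$trop_model)
    strat <- gaussian_layer(config$strat_height_km, config$layer_width_km,
                            strat_aot869[k], config$strat_model)
    atm2 <- atmosphere_state(list(trop, strat), config$gas_profiles,
                             config$pressure_hpa)
    atm1 <- atmosphere_state(list(trop), config$gas_profiles,
                             config$pressure_hpa)
    list(with = simulate_toa(atm2, config$ocean, g, config$bands,
                             config$gas_spectra, rrs_in = config$rrs_in,
                             options = config$options),
         without = simulate_toa(atm1, config$ocean, g, config$bands,
                                config$gas_spectra, rrs_in = config$rrs_in,
                                options = config$options))
  })
}
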