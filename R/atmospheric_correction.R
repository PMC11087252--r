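#' Build the candidate aerosol look-up table
#'
#' Candidates are blends of the tropospheric bimodal model with a
#' sulfate-like fine mode at the given 869-nm extinction fractions — a
#' compact stand-in for the operational multi-model family, which likewise
#' spans sulfate-dominated fine fractions. The first fraction should be 0
#' so the table contains the pure tropospheric model. The correction
#' itself never sees layer heights; candidates are purely spectral shapes.
#'
#' @param trop_model tropospheric [aerosol_model()] with optics attached
#' @param fine_model fine/sulfate [aerosol_model()] with optics attached
#' @param fractions 869-nm extinction fractions of the fine model
#' @return object of class `aerosol_lut`
#' @export
build_aerosol_lut <- function(trop_model, fine_model,
                              fractions = c(seq(0, 0.5, by = 0.05), 0.75, 0.9)) {
  if (length(fractions) < 1) stop("need at least 1 candidate")
  if (is.null(trop_model$optics) || is.null(fine_model$optics))
    stop("attach Mie optics with mie_properties() first")
  structure(list(trop = trop_model, fine = fine_model,
                 fractions = sort(fractions)),
            class = "aerosol_lut")
}

# single-scattering aerosol reflectance spectrum (arbitrary scale) of a
# blend with fine-mode 869-nm extinction fraction fs, at one geometry
blend_scatter_shape <- function(lut, fs, wavelength_nm, geom) {
  theta <- scattering_angle(geom)
  comp <- function(model, frac) {
    frac * model_optic(model, wavelength_nm, "ext_rel") *
      model_optic(model, wavelength_nm, "ssa") *
      hg_phase(model_optic(model, wavelength_nm, "g"), theta)
  }
  comp(lut$trop, 1 - fs) + comp(lut$fine, fs)
}

# extinction-weighted blend optical properties at one wavelength
blend_optics <- function(lut, fs, wavelength_nm) {
  et <- (1 - fs) * model_optic(lut$trop, wavelength_nm, "ext_rel")
  ef <- fs * model_optic(lut$fine, wavelength_nm, "ext_rel")
  st <- et * model_optic(lut$trop, wavelength_nm, "ssa")
  sf <- ef * model_optic(lut$fine, wavelength_nm, "ssa")
  gg <- (st * model_optic(lut$trop, wavelength_nm, "g") +
         sf * model_optic(lut$fine, wavelength_nm, "g")) / (st + sf)
  list(ext_rel = et + ef, ssa = (st + sf) / (et + ef), g = gg)
}

#' Full-column gas transmittance correction
#'
#' Divides every band by T_O3(M) T_H2O(M) computed for the full gas
#' columns — the below-ozone assumption, applied regardless of where the
#' aerosol actually resides. This is the step the stratospheric injection
#' invalidates.
#'
#' @param rho named/numeric per-band total reflectance
#' @param bands list of [spectral_band()] matching `rho`
#' @param geom a [geometry()]
#' @param ozone_du,wv_cm assumed total gas columns
#' @param gas_spectra gas spectra list
#' @return gas-corrected reflectance vector
#' @export
gas_correct <- function(rho, bands, geom, ozone_du = 320, wv_cm = 1.25,
                        gas_spectra = default_gas_spectra()) {
  if (ozone_du < 0 || wv_cm < 0) stop("gas amounts must be >= 0")
  M <- airmass_two_path(geom$sza, geom$vza)
  tg <- vapply(bands, function(b)
    band_transmittance(b, gas_spectra$O3, ozone_du, M) *
    band_transmittance(b, gas_spectra$H2O, wv_cm, M), 1.0)
  unname(rho / tg)
}

#' Subtract the Rayleigh reflectance
#'
#' Uses the same Rayleigh code path as the forward simulator. Negative
#' results are permitted and propagated.
#'
#' @param rho gas-corrected per-band reflectance
#' @param wavelengths_nm band centers
#' @param geom a [geometry()]
#' @param pressure_hpa surface pressure
#' @export
subtract_rayleigh <- function(rho, wavelengths_nm, geom,
                              pressure_hpa = 1013.25) {
  unname(rho - vapply(wavelengths_nm, rayleigh_reflectance, 1.0, geom = geom,
                      pressure_hpa = pressure_hpa))
}

#' NIR aerosol model selection (black-pixel scheme)
#'
#' epsilon = rho_aw(748)/rho_aw(869) under the black-pixel assumption
#' (negligible NIR water signal over clear water). The two candidates
#' bracketing the observed epsilon are combined by log-linear
#' interpolation of their spectral shapes; the aerosol reflectance is then
#' extrapolated from 869 nm to all bands via the interpolated shape.
#'
#' @param rho_aw per-band aerosol+water reflectance (gas- and
#'   Rayleigh-corrected), named by rounded band center
#' @param wavelengths_nm band centers (must include 748 and 869)
#' @param lut an [build_aerosol_lut()] table
#' @param geom a [geometry()]
#' @return list: `rho_a` per-band aerosol reflectance, `epsilon`,
#'   `fraction` (interpolated fine fraction), `tau869` (retrieved AOT),
#'   `extrapolated` flag (epsilon outside the table hull)
#' @export
select_aerosol_nir <- function(rho_aw, wavelengths_nm, lut, geom) {
  i748 <- which(abs(wavelengths_nm - 748) < 2)
  i869 <- which(abs(wavelengths_nm - 869) < 2)
  if (!length(i748) || !length(i869)) stop("bands 748 and 869 nm required")
  eps_obs <- rho_aw[i748] / rho_aw[i869]
  fr <- lut$fractions
  shapes <- lapply(fr, function(fs) {
    s <- blend_scatter_shape(lut, fs, wavelengths_nm, geom)
    s / s[i869]
  })
  eps_c <- vapply(shapes, `[[`, 1.0, i748)
  o <- order(eps_c)
  eps_c <- eps_c[o]; fr <- fr[o]; shapes <- shapes[o]
  # flag only meaningful excursions beyond the hull (0.5% relative)
  extrapolated <- eps_obs < min(eps_c) * 0.995 || eps_obs > max(eps_c) * 1.005
  if (length(fr) == 1) {
    bo869 <- blend_optics(lut, fr[1], 869)
    tau869 <- rho_aw[i869] * 4 * geom$mus * geom$muv /
      (bo869$ssa * hg_phase(bo869$g, scattering_angle(geom)))
    return(list(rho_a = rho_aw[i869] * shapes[[1]],
                epsilon = unname(eps_obs), fraction = fr[1],
                tau869 = unname(tau869), extrapolated = extrapolated))
  }
  if (eps_obs <= eps_c[1]) {
    j <- 1; w <- 0
  } else if (eps_obs >= eps_c[length(eps_c)]) {
    j <- length(eps_c) - 1; w <- 1
  } else {
    j <- max(which(eps_c <= eps_obs))
    j <- min(j, length(eps_c) - 1)
    w <- log(eps_obs / eps_c[j]) / log(eps_c[j + 1] / eps_c[j])
  }
  shape <- exp((1 - w) * log(shapes[[j]]) + w * log(shapes[[j + 1]]))
  fs_hat <- (1 - w) * fr[j] + w * fr[j + 1]
  rho_a <- rho_aw[i869] * shape
  bo869 <- blend_optics(lut, fs_hat, 869)
  theta <- scattering_angle(geom)
  tau869 <- rho_aw[i869] * 4 * geom$mus * geom$muv /
    (bo869$ssa * hg_phase(bo869$g, theta))
  list(rho_a = rho_a, epsilon = unname(eps_obs), fraction = fs_hat,
       tau869 = unname(tau869), extrapolated = extrapolated)
}

#' Retrieve remote-sensing reflectance
#'
#' Rrs = (rho_aw - rho_a) / (pi t_down t_up), with the same diffuse
#' transmittance model the simulator uses, evaluated with the selected
#' aerosol blend and retrieved AOT. Negative retrievals are flagged, not
#' clipped — downstream inversions must see the bias as-is.
#'
#' @param rho_aw aerosol+water reflectance
#' @param aerosol output of [select_aerosol_nir()]
#' @param wavelengths_nm band centers
#' @param lut the aerosol table (for blend optical properties)
#' @param geom a [geometry()]
#' @param pressure_hpa surface pressure
#' @param forward_fraction as in the simulator (NULL = (1+g)/2)
#' @return data.frame `wavelength`, `Rrs`, `flag_negative`
#' @export
retrieve_rrs <- function(rho_aw, aerosol, wavelengths_nm, lut, geom,
                         pressure_hpa = 1013.25, forward_fraction = NULL) {
  taur <- vapply(wavelengths_nm, rayleigh_od, 1.0, pressure_hpa = pressure_hpa)
  bo <- lapply(wavelengths_nm, function(wl)
    blend_optics(lut, aerosol$fraction, wl))
  ext <- vapply(bo, `[[`, 1.0, "ext_rel")
  ext869 <- blend_optics(lut, aerosol$fraction, 869)$ext_rel
  taua <- aerosol$tau869 * ext / ext869
  ssa <- vapply(bo, `[[`, 1.0, "ssa")
  g <- vapply(bo, `[[`, 1.0, "g")
  ff <- if (is.null(forward_fraction)) (1 + g) / 2 else forward_fraction
  taud <- taur / 2 + (1 - ssa * ff) * taua
  t2 <- exp(-taud / geom$mus) * exp(-taud / geom$muv)
  rrs <- (rho_aw - aerosol$rho_a) / (pi * t2)
  data.frame(wavelength = wavelengths_nm, Rrs = as.numeric(rrs),
             flag_negative = as.numeric(rrs) < 0)
}

#' Full atmospheric correction of a simulated TOA spectrum
#'
#' Gas correction with full columns, Rayleigh subtraction, NIR aerosol
#' selection, Rrs retrieval. The chain never inspects the atmosphere's
#' layer structure: the below-ozone assumption is structural.
#'
#' @param toa a `toa_spectrum` from [simulate_toa()]
#' @param lut an [build_aerosol_lut()]
#' @param bands band list matching the simulation
#' @param gas_spectra gas spectra
#' @param ozone_du,wv_cm gas columns assumed by the correction
#' @return list: `rrs` data.frame, `aerosol` diagnostics
#' @export
atmospheric_correct <- function(toa, lut, bands = default_bands(),
                                gas_spectra = default_gas_spectra(),
                                ozone_du = 320, wv_cm = 1.25) {
  wl <- toa$spectrum$wavelength
  rho <- toa$spectrum$rho_t
  geom <- toa$geom
  rho_g <- gas_correct(rho, bands, geom, ozone_du, wv_cm, gas_spectra)
  rho_aw <- subtract_rayleigh(rho_g, wl, geom, toa$atm$pressure_hpa)
  aer <- select_aerosol_nir(rho_aw, wl, lut, geom)
  rrs <- retrieve_rrs(rho_aw, aer, wl, lut, geom, toa$atm$pressure_hpa,
                      toa$options$forward_fraction)
  list(rrs = rrs, aerosol = aer)
}
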