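#' Bio-optical water state
#'
#' @param chla chlorophyll-a (mg m-3, >= 0)
#' @param bbp443 particulate backscattering at 443 nm (m-1, >= 0)
#' @param adg443 combined detrital/gelbstoff absorption at 443 nm (m-1)
#' @param eta b_bp power-law spectral exponent (dimensionless, \[0, 3\])
#' @param S a_dg exponential slope (nm-1, \[0.01, 0.03\])
#' @export
bio_optical_state <- function(chla, bbp443, adg443 = 0.002,
                              eta = 1.0, S = 0.018) {
  if (any(c(chla, bbp443, adg443) < 0)) stop("concentrations must be >= 0")
  if (eta < 0 || eta > 3) stop("eta must lie in [0, 3]")
  if (S < 0.01 || S > 0.03) stop("S must lie in [0.01, 0.03] nm-1")
  structure(list(chla = chla, bbp443 = bbp443, adg443 = adg443,
                 eta = eta, S = S),
            class = "bio_optical_state")
}

# default mapping from a scene ocean_state to a full bio-optical state:
# clear-water covariation of the non-water constituents with Chla
bio_state_from_ocean <- function(ocean) {
  sc <- (ocean$chla / 0.3)^0.6
  bio_optical_state(chla = ocean$chla, bbp443 = 8e-4 * sc,
                    adg443 = 2e-3 * sc)
}

#' Pure-seawater and phytoplankton IOP tables
#'
#' Bundled fixture tables on the default band set: pure-seawater
#' absorption `aw` (m-1), pure-seawater backscattering `bbw` (m-1, a
#' lambda^-4.32 power law anchored at 443 nm), and a chlorophyll-specific
#' phytoplankton absorption shape `aphstar` (m2 mg-1). Literature-scale
#' values; user tables can be supplied in the same data.frame layout.
#'
#' @return data.frame with columns `wavelength`, `aw`, `bbw`, `aphstar`
#' @export
default_iop_tables <- function() {
  data.frame(
    wavelength = c(412, 443, 488, 531, 547, 667, 748, 869),
    aw      = c(0.00455, 0.00706, 0.0145, 0.0439, 0.0531, 0.434, 2.82, 5.20),
    bbw     = 0.00121 * (443 / c(412, 443, 488, 531, 547, 667, 748, 869))^4.32,
    aphstar = 0.055 * c(0.87, 1.00, 0.75, 0.38, 0.32, 0.42, 0.0, 0.0))
}

iop_at <- function(tables, wl, what) {
  approx(tables$wavelength, tables[[what]], wl, rule = 2)$y
}

#' Forward semi-analytical water reflectance
#'
#' a(l) = aw + Chla aph*(l) + adg443 exp(-S (l - 443));
#' bb(l) = bbw + bbp443 (443/l)^eta; u = bb/(a+bb);
#' subsurface rrs = G1 u + G2 u^2; above-surface
#' Rrs = 0.52 rrs / (1 - 1.7 rrs).
#'
#' @param state a [bio_optical_state()]
#' @param tables IOP tables from [default_iop_tables()]
#' @param wavelengths_nm bands to evaluate (nm)
#' @param G1,G2 subsurface reflectance quadratic coefficients
#' @return data.frame with `wavelength`, `Rrs` (sr-1) and the IOP terms
#' @export
forward_rrs <- function(state, tables = default_iop_tables(),
                        wavelengths_nm = c(412, 443, 488, 531, 547, 667, 748, 869),
                        G1 = 0.0949, G2 = 0.0794) {
  wl <- wavelengths_nm
  a <- iop_at(tables, wl, "aw") + state$chla * iop_at(tables, wl, "aphstar") +
    state$adg443 * exp(-state$S * (wl - 443))
  bb <- iop_at(tables, wl, "bbw") + state$bbp443 * (443 / wl)^state$eta
  u <- bb / (a + bb)
  if (any(u >= 1)) stop("unphysical state: u >= 1")
  rrs <- G1 * u + G2 * u^2
  Rrs <- 0.52 * rrs / (1 - 1.7 * rrs)
  data.frame(wavelength = wl, Rrs = Rrs, a = a, bb = bb, u = u)
}

#' Default color-index chlorophyll coefficients
#'
#' `Chla = 10^(m0 + m1 CI)`. Calibrated once by log-linear regression of
#' Chla on the color index over forward-model spectra spanning Chla
#' 0.05-1 mg m-3 with covarying bbp443/adg443 (the package's clear-water
#' default mapping), so the index round-trips against the bundled IOP
#' tables.
#' @export
default_chla_coefficients <- function() c(m0 = -0.050927, m1 = 398.584)

#' Color-index chlorophyll
#'
#' CI = Rrs(547) - \[Rrs(443) + (547-443)/(667-443) (Rrs(667)-Rrs(443))\]:
#' the departure of the green band from the blue-red baseline. Being a
#' linear band difference, CI is exactly invariant under any
#' wavelength-independent additive offset to Rrs — the structural reason
#' chlorophyll is less sensitive than backscattering retrievals to
#' common-mode reflectance biases.
#'
#' @param rrs data.frame with `wavelength`, `Rrs` covering 443, 547, 667
#' @param coefficients named vector `c(m0, m1)`
#' @return chlorophyll-a (mg m-3)
#' @export
chla_bandindex <- function(rrs, coefficients = default_chla_coefficients()) {
  get_band <- function(wl) {
    k <- which(abs(rrs$wavelength - wl) < 2)
    if (!length(k)) stop("band ", wl, " nm missing for the color index")
    rrs$Rrs[k[1]]
  }
  r443 <- get_band(443); r547 <- get_band(547); r667 <- get_band(667)
  ci <- r547 - (r443 + (547 - 443) / (667 - 443) * (r667 - r443))
  unname(10^(coefficients["m0"] + coefficients["m1"] * ci))
}

#' Spectral-optimization inversion for bio-optical state
#'
#' Bounded Levenberg-Marquardt least squares of the forward model against
#' an observed Rrs spectrum over the visible bands, solving for the
#' phytoplankton absorption magnitude (expressed as Chla against the
#' bundled specific-absorption shape), adg443 and bbp443, with the
#' spectral slopes eta and S held fixed. Multistart from three fixed
#' initial points; ties broken by lowest residual. Non-convergence is
#' flagged, not raised.
#'
#' @param rrs data.frame with `wavelength`, `Rrs` (>= 4 visible bands)
#' @param tables IOP tables
#' @param eta,S fixed spectral slopes
#' @param max_wavelength_nm fit bands at or below this wavelength
#' @return list: `state` (a [bio_optical_state()]), `rms` residual,
#'   `converged` flag, `fit` (per-band model Rrs)
#' @export
giop_invert <- function(rrs, tables = default_iop_tables(),
                        eta = 1.0, S = 0.018, max_wavelength_nm = 700) {
  k <- rrs$wavelength <= max_wavelength_nm
  wl <- rrs$wavelength[k]; obs <- rrs$Rrs[k]
  if (length(wl) < 4) stop("need at least 4 visible bands")
  if (all(abs(obs) < 1e-9)) {
    return(list(state = NULL, rms = NA_real_, converged = FALSE,
                fit = NULL, message = "degenerate (all-zero) spectrum"))
  }
  resid_fun <- function(p) {
    st <- list(chla = p[1], bbp443 = p[2], adg443 = p[3], eta = eta, S = S)
    a <- iop_at(tables, wl, "aw") + st$chla * iop_at(tables, wl, "aphstar") +
      st$adg443 * exp(-S * (wl - 443))
    bb <- iop_at(tables, wl, "bbw") + st$bbp443 * (443 / wl)^eta
    u <- bb / (a + bb)
    rsub <- 0.0949 * u + 0.0794 * u^2
    0.52 * rsub / (1 - 1.7 * rsub) - obs
  }
  starts <- list(c(0.2, 1e-3, 2e-3), c(0.05, 3e-4, 5e-4), c(1.0, 5e-3, 1e-2))
  best <- NULL
  for (p0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fun,
      lower = c(1e-4, 0, 0), upper = c(50, 0.1, 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rms <- sqrt(mean(fit$fvec^2))
    if (is.null(best) || rms < best$rms) best <- list(fit = fit, rms = rms)
  }
  if (is.null(best)) {
    return(list(state = NULL, rms = NA_real_, converged = FALSE, fit = NULL,
                message = "optimizer failed from all starts"))
  }
  p <- best$fit$par
  conv <- best$fit$info %in% 1:3 && best$rms < 0.5 * sqrt(mean(obs^2))
  state <- bio_optical_state(chla = p[1], bbp443 = p[2], adg443 = p[3],
                             eta = eta, S = S)
  list(state = state, rms = best$rms, converged = conv,
       fit = data.frame(wavelength = wl, Rrs = resid_fun(p) + obs))
}

#' Phytoplankton carbon from particulate backscattering
#'
#' Cphy = slope (bbp443 - intercept): the linear scaling relating the
#' backscattering product to phytoplankton carbon. Defaults follow the
#' widely used carbon-from-backscatter calibration (13000 mg C m-3 per
#' m-1 above a 3.5e-4 m-1 background).
#'
#' @param bbp443 particulate backscattering at 443 nm (m-1)
#' @param slope,intercept scaling coefficients
#' @return list with `cphy` (mg m-3) and `flag_negative`
#' @export
cphy_from_bbp <- function(bbp443, slope = 13000, intercept = 3.5e-4) {
  cphy <- slope * (bbp443 - intercept)
  list(cphy = cphy, flag_negative = bbp443 < intercept)
}
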