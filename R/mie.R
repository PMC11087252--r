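#' Mie efficiencies of a homogeneous sphere
#'
#' Bohren & Huffman series with the logarithmic derivative computed by
#' downward recurrence; Riccati-Bessel functions of the real size
#' parameter by upward recurrence. Returns extinction and scattering
#' efficiencies and the asymmetry parameter.
#'
#' @param x size parameter 2 pi r / lambda (> 0)
#' @param m complex refractive index (relative to the medium)
#' @return list with `qext`, `qsca`, `g`
#' @export
mie_efficiencies <- function(x, m) {
  if (x <= 0) stop("size parameter must be > 0")
  m <- as.complex(m)
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  # logarithmic derivative D_n(mx), downward recurrence
  nmx <- max(nmax, ceiling(Mod(m) * x)) + 16
  D <- complex(nmx + 1)
  mx <- m * x
  for (n in nmx:1) {
    D[n] <- (n + 1) / mx - 1 / (D[n + 1] + (n + 1) / mx)
  }
  # Riccati-Bessel psi, chi by upward recurrence
  psi0 <- cos(x); psi1 <- sin(x)
  chi0 <- -sin(x); chi1 <- cos(x)
  an <- complex(nmax); bn <- complex(nmax)
  for (n in 1:nmax) {
    psi <- (2 * n - 1) / x * psi1 - psi0
    chi <- (2 * n - 1) / x * chi1 - chi0
    xi <- complex(real = psi, imaginary = -chi)
    xi1 <- complex(real = psi1, imaginary = -chi1)
    da <- D[n] / m + n / x
    db <- D[n] * m + n / x
    an[n] <- (da * psi - psi1) / (da * xi - xi1)
    bn[n] <- (db * psi - psi1) / (db * xi - xi1)
    psi0 <- psi1; psi1 <- psi
    chi0 <- chi1; chi1 <- chi
  }
  n <- seq_len(nmax)
  qext <- 2 / x^2 * sum((2 * n + 1) * Re(an + bn))
  qsca <- 2 / x^2 * sum((2 * n + 1) * (Mod(an)^2 + Mod(bn)^2))
  n1 <- n[-nmax]
  gq <- 4 / x^2 * (
    sum(n1 * (n1 + 2) / (n1 + 1) *
          Re(an[n1] * Conj(an[n1 + 1]) + bn[n1] * Conj(bn[n1 + 1]))) +
    sum((2 * n + 1) / (n * (n + 1)) * Re(an * Conj(bn))))
  list(qext = qext, qsca = qsca, g = gq / qsca)
}

#' Aerosol model specification
#'
#' A mixture of lognormal number size distributions. `fraction` is the
#' share of the 869 nm extinction contributed by each mode (sums to 1),
#' which is the operationally meaningful weighting for an optical model
#' referenced at 869 nm.
#'
#' @param modes list of lists, each with `rm` (number median radius,
#'   micron), `gsd` (geometric SD, dimensionless, > 1), `m` (complex
#'   refractive index), `fraction` (869-nm extinction fraction)
#' @param name model name
#' @export
aerosol_model <- function(modes, name = "aerosol") {
  fr <- vapply(modes, `[[`, 1.0, "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("mode fractions must sum to 1")
  for (mo in modes) {
    if (mo$rm <= 0 || mo$gsd <= 1) stop("invalid mode size parameters")
  }
  structure(list(modes = modes, name = name), class = "aerosol_model")
}

#' Tropospheric (boundary-layer) aerosol model
#'
#' Bimodal, coarse-mode dominant with a fine-mode (869 nm extinction)
#' fraction of 0.01: a weakly absorbing maritime-type mixture
#' representative of the clear-sky boundary layer at moderate humidity.
#' @param fine_fraction fine-mode 869-nm extinction fraction
#' @export
aerosol_model_tropospheric <- function(fine_fraction = 0.01) {
  aerosol_model(list(
    list(rm = 0.10, gsd = 1.50, m = complex(real = 1.415, imaginary = 0.002),
         fraction = fine_fraction),
    list(rm = 0.50, gsd = 1.80, m = complex(real = 1.40, imaginary = 1e-4),
         fraction = 1 - fine_fraction)),
    name = sprintf("tropospheric_f%.3f", fine_fraction))
}

#' Stratospheric sulfate aerosol model
#'
#' Monomodal lognormal, number median radius 0.2 micron, geometric SD 1.6,
#' refractive index 1.45 + 0i (purely scattering) — the aged volcanic
#' sulfate description used in the simulation scenarios.
#' @export
aerosol_model_stratospheric <- function() {
  aerosol_model(list(
    list(rm = 0.2, gsd = 1.6, m = complex(real = 1.45, imaginary = 0),
         fraction = 1)),
    name = "stratospheric_sulfate")
}

# per-particle cross sections of one lognormal mode at one wavelength,
# integrated by Gauss-Legendre quadrature in ln r over +-4.5 ln(gsd)
mode_cross_sections <- function(rm, gsd, m, wavelength_nm, nquad = 48) {
  lnsig <- log(gsd)
  gl <- pracma::gaussLegendre(nquad, log(rm) - 4.5 * lnsig, log(rm) + 4.5 * lnsig)
  r <- exp(gl$x)                                    # micron
  pdf <- exp(-((gl$x - log(rm))^2) / (2 * lnsig^2)) / (sqrt(2 * pi) * lnsig)
  wt <- gl$w * pdf
  lam <- wavelength_nm / 1000                       # micron
  cext <- csca <- cg <- 0
  for (i in seq_along(r)) {
    x <- 2 * pi * r[i] / lam
    q <- mie_efficiencies(x, m)
    area <- pi * r[i]^2
    cext <- cext + wt[i] * q$qext * area
    csca <- csca + wt[i] * q$qsca * area
    cg <- cg + wt[i] * q$qsca * area * q$g
  }
  if (!is.finite(cext) || cext <= 0)
    stop("size integration failed (non-finite extinction); check mode spec")
  list(cext = cext, csca = csca, g = cg / csca)
}

#' Derived Mie optical properties of an aerosol model
#'
#' Integrates Mie cross sections over each lognormal mode and combines
#' modes with number weights chosen so the 869-nm extinction shares equal
#' the specified mode fractions. Returns spectral extinction normalized at
#' 869 nm, single-scattering albedo and asymmetry parameter per
#' wavelength.
#'
#' @param model an [aerosol_model()]
#' @param wavelengths_nm wavelengths (nm); 869 is appended if absent
#' @param nquad size-quadrature nodes per mode
#' @return the model with an `optics` data.frame
#'   (`wavelength`, `ext_rel`, `ssa`, `g`) attached
#' @export
mie_properties <- function(model, wavelengths_nm, nquad = 48) {
  stopifnot(inherits(model, "aerosol_model"))
  wl <- sort(unique(c(wavelengths_nm, 869)))
  nm <- length(model$modes)
  cx <- array(0, c(nm, length(wl), 3))
  for (j in seq_len(nm)) {
    mo <- model$modes[[j]]
    for (i in seq_along(wl)) {
      cs <- mode_cross_sections(mo$rm, mo$gsd, mo$m, wl[i], nquad)
      cx[j, i, ] <- c(cs$cext, cs$csca, cs$g)
    }
  }
  i869 <- which(wl == 869)
  frac <- vapply(model$modes, `[[`, 1.0, "fraction")
  nweight <- frac / cx[, i869, 1]                  # number weights
  cext <- matrix(cx[, , 1], nrow = nm)
  csca <- matrix(cx[, , 2], nrow = nm)
  casy <- matrix(cx[, , 3], nrow = nm)
  ext <- colSums(nweight * cext)
  sca <- colSums(nweight * csca)
  gsc <- colSums(nweight * csca * casy)
  optics <- data.frame(wavelength = wl,
                       ext_rel = ext / ext[i869],
                       ssa = sca / ext,
                       g = gsc / sca)
  model$optics <- optics
  model
}

# look up derived optics at a wavelength (linear interpolation)
model_optic <- function(model, wavelength_nm, what = c("ext_rel", "ssa", "g")) {
  what <- match.arg(what)
  if (is.null(model$optics)) stop("run mie_properties() on the model first")
  approx(model$optics$wavelength, model$optics[[what]], wavelength_nm,
         rule = 2)$y
}
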