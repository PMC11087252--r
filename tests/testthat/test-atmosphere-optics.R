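test_that("two-path airmass matches secant arithmetic", {
  expect_equal(airmass_two_path(0, 0), 2)
  expect_equal(airmass_two_path(60, 0), 3, tolerance = 1e-12)
  expect_equal(airmass_two_path(30, 25), 2.2581, tolerance = 1e-4)
  expect_error(airmass_two_path(80, 0), "zenith")
})

test_that("band transmittance closed forms hold", {
  band <- triangular_band()
  gas <- linear_gas(k0 = 1e-4, slope = 0)
  expect_identical(band_transmittance(band, gas, 0, 2.5), 1.0)
  # constant k over the band: exact exponential
  expect_equal(band_transmittance(band, gas, 300, 2.5),
               exp(-1e-4 * 300 * 2.5), tolerance = 1e-12)
})

test_that("band transmittance matches a 0.01 nm trapezoid oracle", {
  band <- triangular_band(center = 550, halfwidth = 15, step = 1)
  gas <- linear_gas(k0 = 5e-5, slope = 2e-7)
  fine <- seq(535, 565, by = 0.01)
  srf <- approx(band$srf$wavelength, band$srf$response, fine)$y
  k <- 5e-5 + 2e-7 * (fine - 300)
  U <- 320; M <- 2.4
  tr <- exp(-k * U * M)
  trap <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2
  oracle <- trap(fine, srf * tr) / trap(fine, srf)
  expect_equal(band_transmittance(band, gas, U, M), oracle,
               tolerance = 1e-6)
})

test_that("transmittance is monotone in amount and airmass, with Jensen bound", {
  band <- triangular_band()
  gas <- linear_gas(k0 = 5e-5, slope = 3e-7)
  amounts <- seq(0, 500, by = 100)
  tr <- vapply(amounts, function(u) band_transmittance(band, gas, u, 2.4), 1.0)
  expect_true(all(diff(tr) < 0))
  ms <- seq(2, 4, by = 0.5)
  trm <- vapply(ms, function(m) band_transmittance(band, gas, 300, m), 1.0)
  expect_true(all(diff(trm) < 0))
  # Jensen: band-averaged T >= exp(-kbar U M)
  wl <- band$srf$wavelength
  k <- approx(gas$table$wavelength, gas$table$k, wl)$y
  s <- band$srf$response
  kbar <- sum(k * s) / sum(s)
  expect_gte(band_transmittance(band, gas, 300, 2.4),
             exp(-kbar * 300 * 2.4) - 1e-12)
})

test_that("Rayleigh optical depth: monotone, pressure-linear, matches formula", {
  expect_true(rayleigh_od(443) > rayleigh_od(547))
  expect_true(rayleigh_od(547) > rayleigh_od(869))
  expect_equal(rayleigh_od(500, 506.625), rayleigh_od(500) / 2,
               tolerance = 1e-12)
  # independent re-statement of the published closed form
  lam <- 0.443
  oracle <- 0.008569 * lam^-4 * (1 + 0.0113 / lam^2 + 0.00013 / lam^4)
  expect_equal(rayleigh_od(443), oracle, tolerance = 0.01 * oracle)
  expect_error(rayleigh_od(300), "wavelength")
})

test_that("Angstrom exponent identities", {
  expect_equal(angstrom_exponent(0.1, 443, 0.1, 869), 0)
  expect_equal(angstrom_exponent(1 / 443, 443, 1 / 869, 869), 1,
               tolerance = 1e-12)
  expect_error(angstrom_exponent(0, 443, 0.1, 869), "> 0")
  # round trip with Mie output
  m <- shared_cfg()$strat_model
  t443 <- stratoc:::model_optic(m, 443, "ext_rel")
  a <- angstrom_exponent(t443, 443, 1, 869)
  expect_equal(1 * (443 / 869)^-a, t443, tolerance = 1e-10)
})

test_that("gas_fraction_above brackets and decreases with height", {
  pr <- default_gas_profiles()$O3
  expect_equal(gas_fraction_above(pr, -1), 1.0)
  expect_equal(gas_fraction_above(pr, 60), 0.0)
  expect_equal(gas_fraction_above(pr, 25), 0.5, tolerance = 1e-3)
  zz <- seq(0, 50, by = 5)
  fr <- vapply(zz, gas_fraction_above, 1.0, profile = pr)
  expect_true(all(diff(fr) <= 0))
})

test_that("Mie code agrees with an independent Bessel-function implementation", {
  # second path: Riccati-Bessel functions from half-integer besselJ/Y
  mie_oracle <- function(x, mr) {
    nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
    n <- 1:nmax
    psi <- function(nn, z) sqrt(pi * z / 2) * besselJ(z, nn + 0.5)
    chi <- function(nn, z) -sqrt(pi * z / 2) * besselY(z, nn + 0.5)
    psix <- psi(n, x); psix0 <- psi(n - 1, x)
    chix <- chi(n, x); chix0 <- chi(n - 1, x)
    xin <- complex(real = psix, imaginary = -chix)
    xin0 <- complex(real = psix0, imaginary = -chix0)
    Dn <- psi(n - 1, mr * x) / psi(n, mr * x) - n / (mr * x)
    da <- Dn / mr + n / x
    db <- Dn * mr + n / x
    an <- (da * psix - psix0) / (da * xin - xin0)
    bn <- (db * psix - psix0) / (db * xin - xin0)
    c(qext = 2 / x^2 * sum((2 * n + 1) * Re(an + bn)),
      qsca = 2 / x^2 * sum((2 * n + 1) * (Mod(an)^2 + Mod(bn)^2)))
  }
  for (x in c(0.5, 1, 3.7, 10, 25)) {
    got <- mie_efficiencies(x, 1.45 + 0i)
    want <- mie_oracle(x, 1.45)
    expect_equal(got$qext, unname(want["qext"]), tolerance = 1e-8)
    expect_equal(got$qsca, unname(want["qsca"]), tolerance = 1e-8)
  }
})

test_that("purely scattering index gives unit single-scattering albedo", {
  m <- shared_cfg()$strat_model
  expect_true(all(abs(m$optics$ssa - 1) < 1e-10))
  # absorbing fine mode pulls ssa below 1
  mt <- shared_cfg()$trop_model
  expect_true(all(mt$optics$ssa < 1))
  expect_true(all(mt$optics$ssa > 0.98))
})

test_that("small-particle limit recovers the Rayleigh Angstrom exponent", {
  m <- mie_properties(aerosol_model(list(list(
    rm = 0.001, gsd = 1.05, m = 1.45 + 0i, fraction = 1))), c(443, 869))
  a <- angstrom_exponent(m$optics$ext_rel[m$optics$wavelength == 443], 443,
                         1, 869)
  expect_equal(a, 4, tolerance = 0.1 * 4)
})

test_that("lognormal extinction ratio matches an independent Mie integration", {
  # oracle: plain trapezoid in ln r with the Bessel-function Mie above
  mie_oracle_qext <- function(x, mr) {
    nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
    n <- 1:nmax
    psi <- function(nn, z) sqrt(pi * z / 2) * besselJ(z, nn + 0.5)
    chi <- function(nn, z) -sqrt(pi * z / 2) * besselY(z, nn + 0.5)
    psix <- psi(n, x); psix0 <- psi(n - 1, x)
    xin <- complex(real = psix, imaginary = -chi(n, x))
    xin0 <- complex(real = psix0, imaginary = -chi(n - 1, x))
    Dn <- psi(n - 1, mr * x) / psi(n, mr * x) - n / (mr * x)
    da <- Dn / mr + n / x
    an <- (da * psix - psix0) / (da * xin - xin0)
    db <- Dn * mr + n / x
    bn <- (db * psix - psix0) / (db * xin - xin0)
    2 / x^2 * sum((2 * n + 1) * Re(an + bn))
  }
  cext_oracle <- function(lam_um, rm = 0.2, gsd = 1.6, mr = 1.45) {
    lnr <- seq(log(rm) - 4.5 * log(gsd), log(rm) + 4.5 * log(gsd),
               length.out = 400)
    r <- exp(lnr)
    pdf <- exp(-((lnr - log(rm))^2) / (2 * log(gsd)^2)) /
      (sqrt(2 * pi) * log(gsd))
    q <- vapply(r, function(ri) mie_oracle_qext(2 * pi * ri / lam_um, mr), 1.0)
    y <- q * pi * r^2 * pdf
    sum(diff(lnr) * (y[-1] + y[-length(y)])) / 2
  }
  want <- cext_oracle(0.675) / cext_oracle(0.869)
  m <- mie_properties(aerosol_model_stratospheric(), c(675, 869))
  got <- m$optics$ext_rel[m$optics$wavelength == 675]
  expect_equal(got, want, tolerance = 0.01 * want)
})
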