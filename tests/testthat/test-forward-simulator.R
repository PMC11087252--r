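test_that("single-scattering reflectance: zero AOT, linearity, closed form", {
  g0 <- geometry(0, 0, 0)
  lay0 <- gaussian_layer(2, 2, 0, flat_model())
  expect_identical(single_scatter_reflectance(lay0, 547, g0), 0)
  lay1 <- gaussian_layer(2, 2, 0.1, flat_model())   # isotropic, ssa 1
  expect_equal(single_scatter_reflectance(lay1, 547, g0), 0.025,
               tolerance = 1e-12)
  lay2 <- gaussian_layer(2, 2, 0.2, flat_model())
  expect_equal(single_scatter_reflectance(lay2, 547, g0),
               2 * single_scatter_reflectance(lay1, 547, g0),
               tolerance = 1e-14)
})

test_that("scattering angle and geometry validation", {
  expect_equal(scattering_angle(geometry(0, 0, 0)), 180)
  expect_equal(scattering_angle(geometry(30, 30, 180)), 120, tolerance = 1e-9)
  expect_equal(scattering_angle(geometry(30, 30, 0)), 180, tolerance = 1e-9)
  expect_error(geometry(80), "zenith")
  expect_error(geometry(30, 25, 200), "azimuth")
})

test_that("component breakdown sums exactly to the total", {
  cfg <- shared_cfg()
  geom <- geometry(35)
  trop <- gaussian_layer(2, 2, 0.08, cfg$trop_model)
  strat <- gaussian_layer(23, 2, 0.02, cfg$strat_model)
  toa <- simulate_toa(atmosphere_state(list(trop, strat)), ocean_state(),
                      geom, cfg$bands, cfg$gas_spectra, rrs_in = cfg$rrs_in)
  s <- toa$spectrum
  expect_equal(s$rho_t, s$rho_r + s$rho_w + s$rho_a1 + s$rho_a2,
               tolerance = 1e-14)
  expect_true(all(s$rho_t >= 0) && all(s$rho_r >= 0) && all(s$rho_w >= 0))
})

test_that("two co-located layers equal one layer with summed AOT", {
  cfg <- shared_cfg()
  geom <- geometry(40)
  a <- gaussian_layer(2, 2, 0.05, cfg$trop_model)
  b <- gaussian_layer(2, 2, 0.03, cfg$trop_model)
  ab <- gaussian_layer(2, 2, 0.08, cfg$trop_model)
  t2 <- simulate_toa(atmosphere_state(list(a, b)), ocean_state(), geom,
                     cfg$bands, cfg$gas_spectra, rrs_in = cfg$rrs_in)
  t1 <- simulate_toa(atmosphere_state(list(ab)), ocean_state(), geom,
                     cfg$bands, cfg$gas_spectra, rrs_in = cfg$rrs_in)
  expect_equal(t2$spectrum$rho_t, t1$spectrum$rho_t, tolerance = 1e-10)
})

test_that("with zero gas columns the added layer contributes its bare term", {
  cfg <- shared_cfg()
  geom <- geometry(30)
  gp0 <- default_gas_profiles(ozone_du = 0, wv_cm = 0)
  opts <- list(kappa = 3, forward_fraction = 1)  # aerosol-transparent t
  trop <- gaussian_layer(2, 2, 0.08, cfg$trop_model)
  strat <- gaussian_layer(23, 2, 0.02, cfg$strat_model)
  t2 <- simulate_toa(atmosphere_state(list(trop, strat), gp0), ocean_state(),
                     geom, cfg$bands, cfg$gas_spectra, rrs_in = cfg$rrs_in,
                     options = opts)
  t1 <- simulate_toa(atmosphere_state(list(trop), gp0), ocean_state(),
                     geom, cfg$bands, cfg$gas_spectra, rrs_in = cfg$rrs_in,
                     options = opts)
  bare <- vapply(cfg$wavelengths, single_scatter_reflectance, 1.0,
                 layer = strat, geom = geom)
  expect_equal(t2$spectrum$rho_t - t1$spectrum$rho_t, unname(bare),
               tolerance = 1e-12)
})

test_that("raising aerosol into the ozone layer depresses ozone bands only", {
  # the mechanism under study: scattering co-mingled with ozone enhances
  # effective absorption, so ozone-affected bands lose signal while
  # gas-free bands are unchanged at machine precision
  cfg <- shared_cfg()
  geom <- geometry(35)
  gp <- default_gas_profiles(ozone_du = 320, wv_cm = 0)  # isolate ozone
  trop <- gaussian_layer(2, 2, 0.08, cfg$trop_model)
  low <- gaussian_layer(2, 2, 0.02, cfg$strat_model)
  high <- gaussian_layer(23, 2, 0.02, cfg$strat_model)
  tl <- simulate_toa(atmosphere_state(list(trop, low), gp), ocean_state(),
                     geom, cfg$bands, cfg$gas_spectra, rrs_in = cfg$rrs_in)
  th <- simulate_toa(atmosphere_state(list(trop, high), gp), ocean_state(),
                     geom, cfg$bands, cfg$gas_spectra, rrs_in = cfg$rrs_in)
  wl <- cfg$wavelengths
  dif <- th$spectrum$rho_t - tl$spectrum$rho_t
  expect_lt(dif[wl == 547], 0)
  expect_lt(dif[wl == 667], 0)
  expect_equal(dif[wl == 869], 0, tolerance = 1e-10)
})

test_that("total reflectance decreases with the ozone column", {
  cfg <- shared_cfg()
  geom <- geometry(35)
  trop <- gaussian_layer(2, 2, 0.08, cfg$trop_model)
  strat <- gaussian_layer(23, 2, 0.02, cfg$strat_model)
  r547 <- vapply(c(200, 320, 450), function(du) {
    atm <- atmosphere_state(list(trop, strat), default_gas_profiles(du, 1.25))
    t <- simulate_toa(atm, ocean_state(), geom, cfg$bands, cfg$gas_spectra,
                      rrs_in = cfg$rrs_in)
    t$spectrum$rho_t[cfg$wavelengths == 547]
  }, 1.0)
  expect_true(all(diff(r547) < 0))
})

test_that("paired scenario runs respond monotonically to stratospheric AOT", {
  cfg <- shared_cfg()
  aots <- c(0, 0.01, 0.02, 0.04)
  geoms <- rep(list(geometry(35)), length(aots))
  runs <- run_scenarios(aots, geoms, cfg)
  d0 <- runs[[1]]
  expect_equal(d0$with$spectrum$rho_t, d0$without$spectrum$rho_t,
               tolerance = 1e-14)
  d869 <- vapply(runs, function(r)
    r$with$spectrum$rho_t[cfg$wavelengths == 869] -
      r$without$spectrum$rho_t[cfg$wavelengths == 869], 1.0)
  expect_true(all(diff(d869) > 0))
  expect_error(run_scenarios(c(0.1, 0.2), geoms, cfg), "lengths differ")
})
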