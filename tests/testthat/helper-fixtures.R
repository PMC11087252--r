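# shared fixtures: built once per test run

# a triangular SRF band and a linearly varying gas spectrum for the
# quadrature oracle tests
triangular_band <- function(center = 550, halfwidth = 15, step = 1) {
  wl <- seq(center - halfwidth, center + halfwidth, by = step)
  spectral_band("tri", center,
                data.frame(wavelength = wl,
                           response = 1 - abs(wl - center) / halfwidth))
}

linear_gas <- function(k0 = 5e-5, slope = 2e-7, units = "DU") {
  wl <- seq(300, 1000, by = 1)
  gas_spectrum("lin", data.frame(wavelength = wl,
                                 k = k0 + slope * (wl - 300)), units)
}

# an aerosol "model" with prescribed flat optics, for analytic checks
flat_model <- function(ext_rel = 1, ssa = 1, g = 0) {
  m <- aerosol_model(list(list(rm = 0.2, gsd = 1.6, m = 1.45 + 0i,
                               fraction = 1)), name = "flat")
  m$optics <- data.frame(wavelength = c(300, 1000),
                         ext_rel = ext_rel, ssa = ssa, g = g)
  m
}

# the scenario configuration and ratio experiment are reused across many
# tests; build them once
shared_cfg <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- scenario_config()
    cfg
  }
})

shared_fig6 <- local({
  f <- NULL
  function() {
    if (is.null(f)) f <<- run_fig6_experiment(shared_cfg())
    f
  }
})
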