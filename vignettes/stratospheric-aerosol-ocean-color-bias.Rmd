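---
title: "Methods: how stratospheric aerosol biases ocean-color retrievals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how stratospheric aerosol biases ocean-color retrievals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stratoc` studies a retrieval artifact: when volcanic sulfate aerosol sits
in the stratosphere, co-mingled with the ozone layer, the standard
ocean-color atmospheric correction (AC) — built on the assumption that all
aerosol lies in the troposphere below the ozone — under-corrects ozone
absorption and returns remote-sensing reflectance Rrs(λ) that is biased low
with the spectral shape of the ozone Chappuis band. This vignette documents
the models, the assumptions, the tunable parameters, and the places where
the design was genuinely open.

## 1. Forward model

The simulator is a layered single-scattering model with analytic gas
transmittances, not a full vector radiative-transfer code. Per band:

ρ_t(λ) = Σ_L ρ_L(λ) · T_O3(U f_L M) · T_wv(W g_L M)
       + [ρ_r(λ) + t_s t_v π Rrs(λ)] · T_O3(U M) · T_wv(W M) · C(λ)

* ρ_L = ω τ_L(λ) P_HG(Θ) / (4 μ_s μ_v) is the single-scattering reflectance
  of aerosol layer L, with the Henyey–Greenstein phase function evaluated at
  the reflected-beam scattering angle and the layer's Mie-derived
  single-scattering albedo ω, spectral extinction τ_L(λ) (normalized at
  869 nm) and asymmetry parameter g.
* f_L, g_L are the fractions of the ozone / water-vapor columns *above* the
  layer center (`gas_fraction_above`), so each layer is attenuated only by
  the gas it actually lies beneath. M = sec θ_s + sec θ_v.
* ρ_r is the Rayleigh reflectance (Hansen–Travis optical depth, pressure
  scaled, 3/4(1 + cos²Θ) phase function); t_s t_v is the two-leg diffuse
  transmittance exp(−(τ_r/2 + (1 − ωF)τ_a)/μ) with F the forward-scattered
  fraction, by default (1 + g)/2.
* C(λ) is the scattering–absorption coupling factor described next.

### The coupling factor, and why it exists

With C ≡ 1 the model is purely "ordered transmittance": an elevated
scattering layer sees *less* ozone than the full column, so the measured
signal in ozone bands would exceed what the AC's full-column model expects,
and the retrieved Rrs would be biased *high*. A single-scattering model
without any aerosol–gas coupling therefore cannot produce the observed
negative bias: that bias is a multiple-scattering effect — light redirected
by a scatterer inside or above the absorber travels extra, slanted paths
through the ozone below, so the true absorption losses exceed the two-path
estimate and the AC under-corrects.

C(λ) is a first-order surrogate for that mechanism:

C(λ) = exp(−κ · Σ_L τ_L,sca(λ) · M · A_L(λ)),

applied to the below-layer (Rayleigh + water) terms, where
A_L = 1 − T_O3(U(1 − f_L)M) is the two-path absorptance of the ozone below
layer L, and κ is a dimensionless path-multiplication constant. The
interception probability of the upwelling radiance by layer L is of order
τ_L,sca·M (both legs); each redirected photon re-crosses the sub-layer ozone
at least twice (down and back up) at slant angles, giving an expected
enhancement of 2–4. The default κ = 3 is the midpoint of that geometric
argument; it is a model constant, configurable through
`scenario_config(kappa = )`. The factor is restricted to ozone — it exists
to represent the stratosphere–ozone co-mingling, and the band set is
designed to avoid the water-vapor bands.

Three structural properties follow, and the tests assert all of them:

* when every layer is below the ozone (f_L → 1), A_L → 0, C → 1, and the
  AC closes exactly up to its look-up-table interpolation error;
* gas-free bands (869 nm with zero water vapor) are unchanged at machine
  precision when a layer moves in height;
* in ozone bands, raising a layer into the ozone *decreases* ρ_t (the
  coupling deficit exceeds the ordered-transmittance excess at the default
  κ), which is what makes the retrieved Rrs bias negative and green-heavy.

The major approximation is documented rather than hidden: no polarization,
no Rayleigh–aerosol cross terms beyond C, no spherical-shell geometry, no
glint or whitecaps (wind is carried as metadata only). Correctness is
defined by closure, sign and ordering tests, not by absolute radiometry.

## 2. Atmospheric correction

The correction chain never inspects layer heights — its below-ozone
assumption is structural. Steps: (i) divide every band by the full-column
T_O3(UM)·T_wv(WM); (ii) subtract the same Rayleigh term the simulator uses
(shared code path); (iii) estimate the aerosol from the near-infrared under
the black-pixel assumption, ε = ρ_aw(748)/ρ_aw(869), select the two
candidates bracketing ε and interpolate their spectral shapes log-linearly;
(iv) Rrs = (ρ_aw − ρ_a)/(π t_s t_v) with the diffuse-transmittance model
shared with the simulator, evaluated at the selected aerosol blend and the
AOT retrieved from ρ_aw(869). Negative retrievals are flagged, never
clipped, so downstream inversions see the bias as-is.

The candidate family is a design choice: blends of the tropospheric bimodal
model with the sulfate-like fine mode at 869-nm extinction fractions 0–0.9
(step 0.05 up to 0.5). The operational multi-model families likewise span
sulfate-dominated fine fractions; parameterizing candidates along the
trop–sulfate axis lets the table represent the true mixture almost exactly,
which is what makes the 2-km relocation null sharp (≤ 0.35% here) and
guarantees that the remaining scenario-2 bias isolates the ozone-ordering
effect rather than a table deficiency.

## 3. Aerosol and gas optics

Mie efficiencies use the Bohren–Huffman logarithmic-derivative downward
recurrence; size integration over each lognormal mode uses 48-point
Gauss–Legendre quadrature in ln r over ±4.5 ln σ_g. Mode mixing weights are
chosen so the 869-nm extinction shares equal the specified mode fractions.
The independent test oracle recomputes the Riccati–Bessel functions from
half-integer-order `besselJ`/`besselY` — a different computational path —
and a 300-point trapezoid size integration; agreement is required to 1% on
the 675/869 extinction ratio and 1e-8 on single-sphere efficiencies.

Aerosol models: tropospheric = bimodal, coarse-dominant (fine mode r_m
0.10 µm, σ_g 1.5, m = 1.415 + 0.002i; coarse mode r_m 0.50 µm, σ_g 1.8,
m = 1.40 + 1e-4i; fine fraction 0.01 of 869-nm extinction), a weakly
absorbing maritime mixture. Stratospheric = monomodal sulfate, r_m 0.2 µm,
σ_g 1.6, m = 1.45 + 0i (purely scattering, so ω ≡ 1 — asserted to 1e-10).
The "width 1.6" of the sulfate distribution is interpreted as the
dimensionless geometric standard deviation, the convention of the aerosol
literature this model family comes from.

Gas spectra are bundled synthetic stylizations, not line-by-line data: a
skewed-Gaussian Chappuis-like ozone band centered at 602 nm (σ = 90 nm blue
side, 50 nm red side, peak 1.21e-4 DU⁻¹, giving τ ≈ 0.031 at 547 nm for
320 DU) and two water-vapor bands at 724/823 nm that the band set largely
dodges. Real cross sections can be supplied as two-column tables through
`read_spectral_table()` / `gas_spectrum()`. Band transmittances integrate
SRF·exp(−kUM) by the trapezoid rule on the SRF grid (Gaussian SRFs, σ =
5 nm, 0.5 nm sampling); the acceptance oracle is a 0.01 nm quadrature.
Ozone's vertical profile defaults to a Gaussian at 25 km (σ = 5 km) so the
23 km aerosol layer sits inside it — the overlap is the mechanism's knob
and is fully configurable; water vapor decays exponentially (2 km scale
height).

## 4. Bio-optics

Forward: a(λ) = a_w + Chla·a*_ph(λ) + a_dg(443)e^(−S(λ−443)),
b_b(λ) = b_bw + b_bp(443)(443/λ)^η, u = b_b/(a + b_b),
r_rs = G₁u + G₂u², Rrs = 0.52 r_rs/(1 − 1.7 r_rs), with G₁ = 0.0949,
G₂ = 0.0794, η = 1.0, S = 0.018 nm⁻¹ by default (all configurable; the
tests do not depend on their exact values). The bundled IOP tables are
literature-scale pure-seawater absorption/backscattering and a normalized
phytoplankton absorption shape on the default band set.

The inversion (`giop_invert`) is bounded Levenberg–Marquardt over
(Chla, a_dg(443), b_bp(443)) with η and S fixed, multistart from three fixed
initial points, ties broken by lowest residual RMS; non-convergence returns
a flagged result. Noise-free self-generated spectra are recovered with
residual RMS below 1e-10 and b_bp(443) within 1% across the tested state
grid (Chla 0.05–1 mg m⁻³, b_bp 5e-4–5e-3 m⁻¹).

CI chlorophyll uses the band-difference color index with
Chla = 10^(m0 + m1·CI); m0 = −0.0509, m1 = 398.58 were calibrated once by
log-linear regression against this package's own forward model over Chla
0.05–1 (round-trip within 7%). CI is exactly invariant under
wavelength-independent additive offsets — the structural reason chlorophyll
is the "in-family" product while b_bp(443) is not. The carbon scaling
defaults to C_phy = 13000·(b_bp(443) − 3.5e-4) mg m⁻³.

## 5. Synthetic data and what passing tests do (and do not) show

The ocean-color generator produces one annual sinusoid per hemisphere
(phases opposed by six months, amplitude tapering to zero at the equator),
mean-preserving multiplicative lognormal noise, and an optional
multiplicative 2022 bias with exact ground truth. Default amplitude (5% of
the mean) and noise (cv 5%) are free parameters — the pre-2022 interannual
variability of real regions is not prescribed anywhere authoritative — and
are documented here as the package's chosen study conditions. The AOT
generator fluctuates lognormally about a 675-nm baseline of 0.005 and adds
a 2022 pulse, Gaussian in latitude (center 22° S, width 18°) and month
(peak June–July), calibrated *in log space* so the area-weighted geometric
mean over the Southern-Hemisphere region peaks at exactly the configured
factor (default 6.5, inside the observed 6–7× range). The Argo generator
uses an exponential-decay profile (surface 4e-4, deep 2e-4 m⁻¹, 150 m
scale), per-float additive offsets, isolated multiplicative spikes, and
retains truth columns.

These generators emulate the *statistical structure* the pipelines consume
— seasonality, skewed noise, coverage, artifacts — not real spatial fields:
no L3 bin geometry, no cloud masking, no trajectory physics, no
spatially-correlated noise. Closed-loop tests therefore demonstrate that
the pipelines recover what was injected under those stated conditions, not
that real-archive magnitudes would be reproduced.

## 6. Pipeline conventions and numerical choices

* Regional means: cos(latitude) cell weights, renormalized after dropping
  missing cells; geometric means (for AOT) require positive values and are
  computed in log space. Presets: NH 0–50° N, SH 0–50° S, and SPSG as the
  rectangle 15–45° S, 160–100° W — a documented approximation of the gyre,
  fully configurable.
* Standardized anomalies use one overall pre-2022 mean and sample SD (n−1),
  not a per-calendar-month climatology, so z series keep their seasonal
  cycle; a per-month mode sits behind `per_month = TRUE`.
* AOT anomaly maps mask cells with fewer than 6 baseline months.
* Argo QC: the alignment target is the fleet-median deep (700–750 m) mean
  with an additive shift (preserves vertical gradients, robust to outlier
  floats). The 5th/95th percentile trim is per 7-day bin (grouping first),
  linear-interpolation percentiles, strict inequality for removal; week
  bins restart each January 1 so years overlay comparably; surface means
  need ≥ 2 samples in 5–20 m. The interannual envelope check pools
  prior-year weekly values over a ±2-week window (≥ 5 values) and asks
  whether at least two-thirds of the 2022 bins lie within ±1.5 SD — a
  deliberately robust operationalization: the band's nominal coverage is
  ~85%, and a genuine level shift drives the fraction toward zero.
* Monthly geometry: noon solar zenith on the 15th at 25° S from the
  standard declination formula, fixed view zenith 25°, relative azimuth 80°
  (reflected-beam convention for the scattering angle).
* Degenerate inputs: σ = 0 baselines, all-zero spectra, empty bins and
  empty regions raise typed errors or flagged results rather than NaNs.

## 7. Problem sizes

The test suite and the acceptance script run on deliberately desk-scale
configurations chosen as sufficient for their statistical claims: 10–30°
synthetic grids over 2002–2022, 8-float/40-cast Argo sets, 20-seed
robustness sweeps, 48-point size quadrature, 50 noisy inversion replicates.
The full suite completes in well under a minute of compute for the module
tests plus ~30 s for the acceptance blocks.

## 8. Known limitations

* The coupling constant κ parameterizes, not derives, the
  multiple-scattering ozone-path enhancement; only signs, orderings and
  nulls — not absolute bias magnitudes — should be read as predictions.
* Single scattering limits validity to small optical depths (τ ≲ 0.2,
  satisfied by the scenarios).
* The ε-selection look-up family shares its endmembers with the simulation's
  true models; with real data the family mismatch would add a bias
  component this package does not model.
* Synthetic gas spectra reproduce band-scale, not line-scale, absorption;
  band sets with strong water-vapor overlap would need real cross sections.
* The chlorophyll coefficients are calibrated to the bundled IOP tables and
  are not the operational algorithm's coefficients.
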