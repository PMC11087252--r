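# stratoc

Quantifying how enhanced stratospheric aerosol loading biases satellite
ocean-color retrievals.

After a major volcanic injection of SO₂ into the stratosphere, the sulfate
aerosol that forms sits at 20–26 km — co-mingled with the ozone layer. The
standard ocean-color atmospheric correction (AC) assumes all aerosol lies in
the troposphere, *below* the ozone, and therefore corrects the top-of-
atmosphere signal for gas absorption with a full-column two-path
transmittance before separating aerosol and water contributions. When
scattering actually happens inside the ozone layer, the effective ozone
absorption of the diffuse light field is larger than the two-path estimate,
the correction under-compensates, and the retrieved remote-sensing
reflectance Rrs(λ) (sr⁻¹) is biased low with a spectral shape that follows
the ozone (Chappuis) absorption band — strongest in the green. Downstream,
the spectral-optimization retrieval of the particulate backscattering
coefficient b_bp(443) (m⁻¹), and hence phytoplankton carbon
C_phy = m·(b_bp(443) − b₀), amplifies the bias, while the band-difference
color-index (CI) chlorophyll algorithm, being invariant to common-mode
reflectance offsets, barely responds. The result is an apparent collapse of
phytoplankton carbon in satellite records that in-situ profiling floats do
not see.

`stratoc` implements this whole chain as testable components:

* **Synthetic data generators** — gridded monthly ocean-color fields with
  seeded noise and an optional 2022 bias injection; a gridded stratospheric
  aerosol optical thickness (AOT) product with a mid-2022 pulse calibrated
  to a 6.5× Southern-Hemisphere peak; BGC-Argo-style b_bp(700) profile sets
  with spikes and per-float sensor offsets. Every injected effect carries
  ground truth.
* **Anomaly pipeline** — cos(latitude)-weighted regional means (arithmetic
  or geometric), standardized anomalies z = (x − μ)/σ against a pre-2022
  baseline, and per-cell AOT anomaly maps with a minimum-coverage mask.
* **Argo QC chain** — three-point moving-median despike, additive deep
  (700–750 m) alignment to the fleet median, 5–20 m surface extraction,
  7-day binning with 5th/95th percentile trimming, interannual overlay.
* **Atmosphere optics** — band-integrated gas transmittances from spectral
  response functions, Rayleigh optical depth, Mie optics of lognormal
  aerosol size distributions (hand-rolled Bohren–Huffman code, oracle-tested
  against an independent Bessel-function implementation), Ångström
  extrapolation, gas vertical-profile bookkeeping.
* **Forward simulator** — layer-ordered single-scattering top-of-atmosphere
  reflectance in which each aerosol layer is attenuated only by the gas
  above it, plus a first-order scattering–absorption coupling term for the
  extra ozone path of diffuse light redirected by elevated layers.
* **Atmospheric correction** — the deliberately layer-blind NASA-style
  chain: full-column gas correction, Rayleigh subtraction, near-infrared
  black-pixel aerosol model selection from an ε = ρ(748)/ρ(869) look-up
  family, Rrs retrieval.
* **Bio-optics** — semi-analytical forward reflectance
  (u = b_b/(a + b_b), r_rs = G₁u + G₂u²), CI chlorophyll, bounded
  Levenberg–Marquardt inversion for b_bp(443), carbon scaling.
* **Experiment drivers** — the monthly with/without-stratosphere retrieval
  ratio experiment and a full synthetic observational study reproducing the
  satellite-anomaly-present / in-situ-anomaly-absent contrast.

## Worked example

```r
library(stratoc)

cfg  <- scenario_config()          # 2 km/0.08 troposphere; 23 km sulfate layer;
                                   # 320 DU ozone; 1.25 cm water vapor; Chla 0.3
fig6 <- run_fig6_experiment(cfg)   # with/without-stratosphere retrieval ratios
subset(fig6, month %in% c(1, 6), c(month, strat_aot869,
                                   ratio_rrs443, ratio_rrs547, ratio_bbp443))
#>   month strat_aot869 ratio_rrs443 ratio_rrs547 ratio_bbp443
#> 1     1       0.0038       0.9976       0.9884       0.9812
#> 6     6       0.0240       0.9713       0.8690       0.7920
```

At the June AOT peak (stratospheric τ(869) ≈ 0.024, ~6.5× baseline) the
retrieval with the stratospheric layer returns 97.1% of the true Rrs(443),
86.9% of Rrs(547), and only 79.2% of b_bp(443): the bias follows the ozone
absorption spectrum (green hit hardest) and is amplified by the
backscattering inversion, while CI chlorophyll moves by only ~5%. Relocating
the same layer to 2 km — below the ozone — restores every ratio to 1 within
0.35%, isolating the aerosol–ozone ordering as the mechanism.

The end-to-end synthetic study ties the modules together:

```r
rep1 <- run_observational_analog(seed = 1, cfg, ratios = fig6)
rep1$min_z["Rrs547"]          # -5.35: satellite analog sees a strong anomaly
rep1$argo$fraction_within     #  0.85: the float analog stays in its envelope
rep1$contrast                 #  TRUE
```

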