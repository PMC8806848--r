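# ramanomer

Quantification of D-mannose and D-glucose in aqueous mixtures from Raman
spectra, for process-analytical monitoring of sugar bioprocesses (e.g. an
epimerization reaction converting D-glucose to D-mannose at fixed 30%
dry matter). In water both sugars live in an anomeric equilibrium of
α- and β-pyranose forms; for D-mannose the ν(CO) ring modes at 960 cm⁻¹
and 974 cm⁻¹ split by anomer, and D-glucose is essentially silent in that
window — which makes the 941–992 cm⁻¹ region a direct, inline probe of
both the D-mannose concentration and its anomeric ratio.

The package implements the full analysis chain plus the in-silico route
that supports the band assignment:

- **Baseline correction** — asymmetric penalized least squares
  (iteratively reweighted Whittaker smoothing with a second-difference
  penalty).
- **Deconvolution** — bounded nonlinear least-squares fitting of sums of
  Gaussian `A·exp(−½((v−x)/σ)²)` or Lorentzian `A/(1+4((v−x)/σ)²)`
  profiles (for the Lorentzian the factor 4 makes σ the FWHM), with
  residual-threshold selection of the number of components.
- **Anomer statistic** — α% = I₉₆₀/(I₉₆₀+I₉₇₄), β% = I₉₇₄/(I₉₆₀+I₉₇₄),
  from apex amplitudes or analytic band areas of the fitted profiles.
- **Calibration** — ordinary least-squares line of anomeric-region band
  area against D-mannose content, and its inversion.
- **In-silico spectra** — conversion of computed vibrational mode tables
  (ω_v, g_v, α′², γ′²) into backscattering Raman cross-sections
  ∝ (ω₀−ω_v)⁴ · g_v/(2ω_v) · (45α′²+7γ′²)/45, broadening into spectra,
  anomer-population weighting, hydration-shell stoichiometry, and
  matching of computed frequencies to experimental bands.
- **Synthetic data** — a seeded generator producing spectra with the
  statistical structure the analysis assumes (reference band positions,
  population-proportional amplitudes, smooth baseline, Gaussian noise),
  so the whole chain is testable without instrument data.

## Worked example

```r
library(ramanomer)

# synthetic aqueous D-mannose at the NMR anomeric equilibrium
cfg <- generator_config(bands = anomeric_bands(),
                        populations = c(alpha = 0.655, beta = 0.345),
                        baseline_coeffs = c(0.05, 0.04, -0.03))
spec <- synth_spectrum(cfg)

q <- quantify_anomers(spec, reg = region(941, 992))
q$fit
#> <fit_result> 2 gaussian profile(s) over [941, 992] cm^-1, rms 0.001319
#>   A = 0.32419  x = 960.0265 cm^-1  sigma = 5.9179 cm^-1  area = 4.8091
#>   A = 0.1699  x = 973.9072 cm^-1  sigma = 5.8815 cm^-1  area = 2.5047
q$composition
#> <anomer_composition> alpha 65.6%, beta 34.4%
```

The two fitted Gaussians land on the 960/974 cm⁻¹ marker bands and their
apex-amplitude ratio recovers the generating α/β populations through the
baseline correction and fit.

The `analysis/` directory holds the workflow as numbered drivers —
`01_simulate.R` (simulated measurement campaign at 30% DM),
`02_deconvolute.R` (baseline + component-count study + doublet fit),
`03_quantify.R` (anomer fractions; area-vs-content calibration, R² >
0.999 on the noiseless-by-construction series), `04_insilico.R`
(cross-section spectra from mode tables, hydration arithmetic, band
matching). Each writes its tables under `results/`.

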