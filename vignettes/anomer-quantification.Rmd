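---
title: "Raman quantification of sugar anomers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Raman quantification of sugar anomers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanomer)
```

## The problem

D-glucose and D-mannose are C2 epimers; in water each equilibrates
between α- and β-pyranose anomers (mutarotation), with the furanose and
open-chain forms negligible. NMR puts aqueous D-mannose at 65.5% α / 34.5%
β and D-glucose at 38% α / 62% β. In the Raman spectrum of aqueous
D-mannose the ν(CO) ring stretch splits by anomer into bands at 960 cm⁻¹
(α) and 974 cm⁻¹ (β), while D-glucose contributes essentially no
intensity in the 941–992 cm⁻¹ window. Two consequences drive the method:

1. the **total band area** in the window is proportional to the
   D-mannose concentration (a linear calibration), and
2. the **ratio** of the two band intensities is the anomer ratio, and is
   independent of concentration.

This package implements the signal-processing chain that extracts both
quantities from a measured spectrum, and the in-silico post-processing
that converts computed vibrational modes into comparable spectra.

## Lineshape model and deconvolution

The overlapped window is modelled as a sum of parametric profiles,

$$I_G(v) = \sum_n A_n \exp\!\left(-\tfrac12\Big(\frac{v - x_n}{\sigma_n}\Big)^2\right),
\qquad
I_L(v) = \sum_n \frac{A_n}{1 + 4\big(\frac{v - x_n}{\sigma_n}\big)^2},$$

evaluated at the grid points $v_i$. The width convention is deliberately
asymmetric between shapes and is preserved exactly: $\sigma$ is the
Gaussian *standard deviation* but, through the factor 4, the Lorentzian
*FWHM* (half maximum at $x \pm \sigma/2$). The analytic areas used for
calibration are $A\sigma\sqrt{2\pi}$ and $A\sigma\pi/2$ respectively;
tests verify both against quadrature of the evaluated profile over the
real line.

`fit_profiles()` solves the bounded nonlinear least-squares problem over
$\{A_n, x_n, \sigma_n\}$ with Levenberg–Marquardt (`minpack.lm::nls.lm`,
cost tolerances $10^{-10}$): centers constrained inside the fitted
region, widths to `[grid step, region width]`, amplitudes non-negative.
Initialization (nothing in the method prescribes one) picks local maxima
with prominence at least 5% of the region maximum, spreading any missing
centers uniformly; amplitudes start at the signal height, widths at
6 cm⁻¹. If two fitted centers collapse within 1 cm⁻¹ the result carries a
`close_centers` flag rather than a penalty — degeneracy is reported, not
hidden. Results are always sorted by center.

`select_n_profiles()` makes the "how many components suffice" judgment
quantitative: the smallest $n$ whose residual RMS falls below a set
fraction (default 1%) of the region maximum. A relative-residual
criterion was chosen over BIC because the underlying judgment is about
fit adequacy, not parsimony among nested stochastic models. The 1%
default equals the noise floor when apex noise is 1%, so on noisy data
the criterion is intentionally strict; the stage-2 analysis driver shows
the residual-vs-$n$ table plateauing at $n = 2$ on simulated D-mannose.

## Baseline model

Fluorescence and scattering backgrounds are removed by asymmetric
penalized least squares (iteratively reweighted Whittaker smoothing):
minimize $\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2$,
reassigning $w_i = p$ where $y_i > z_i$ and $1 - p$ otherwise, until the
mean absolute weight change drops below `tol` or `max_iter` is reached
(the outcome is recorded in the returned metadata, and the last iterate
is returned either way). Defaults $\lambda = 10^5$, $p = 0.01$,
`max_iter` = 10, `tol` = $10^{-3}$ are standard practice for cm⁻¹-gridded
spectra. The second-difference penalty is the convention of the method;
the sparse banded system is solved with `Matrix`.

Two numerical details matter. A dead-band of $10^{-10}\max(|y|, 1)$ in
the weight comparison keeps flat or noiseless segments from flipping
weights on float noise, which would otherwise prevent convergence on
degenerate (e.g. constant) inputs. And the converged smoother has gentle
side-lobes around isolated peaks — worth a few percent of trapezoidal
area — which is why every area in the pipeline is taken from the
*fitted profiles' analytic areas*, not from numerically integrating the
corrected signal.

Normalization (`normalize_spectrum()`) divides by either the maximum
intensity or the trapezoidal area within a chosen region; the default
mode is `max`, a recorded and configurable choice since nothing pins it
down. Both modes are idempotent and scale-equivariant, so normalized
spectra and all downstream ratios are invariant to acquisition scale.

## The anomer statistic and its band map

$$\alpha\% = \frac{I_{960}}{I_{960} + I_{974}}, \qquad
  \beta\% = \frac{I_{974}}{I_{960} + I_{974}}.$$

`anomer_from_fit()` associates fitted profiles to marker bands by
nearest center within a tolerance (default 8 cm⁻¹ — under half the
960→974 separation, so profiles cannot cross-assign) and applies the
statistic to either apex amplitudes (the formula's native intensities,
the default) or analytic areas (equivalent at equal widths, and the more
accurate choice for *concentration* work). The output is normalized to
sum to exactly one by construction.

The band→anomer mapping (960 = α, 974 = β) is an explicit argument
rather than a constant. Reference assignments of these two bands are not
fully consistent across sources — the same intensity pair can be read as
32.2/67.8 or 65.5/34.5 depending on which band is called α — so the
package keeps the formula fixed and lets the mapping be changed, instead
of guessing an intent. All tests here use the 960 = α convention, which
matches the NMR equilibrium when amplitudes are population-proportional.

## Calibration

`fit_calibration()` is ordinary least squares of window band area on
known D-mannose content (unweighted — with a handful of calibration
points there is no variance model to exploit), reporting $R^2$;
`estimate_content()` inverts the line and flags extrapolation outside
[0, 1]. On the noiseless-by-construction mixture series the round trip
recovers content within 1%, and with 1% apex noise the stage-3 driver
recovers the 25/50/75/100% series within about 1 point.

## In-silico route

Computed modes enter as tables (ω_v in cm⁻¹, degeneracy g_v, and the
isotropic/anisotropic polarizability-derivative invariants α′², γ′²).
The unpolarized backscattering cross-section is

$$\frac{d\sigma}{d\Omega} \;\propto\; (\omega_0 - \omega_v)^4\,
  \frac{g_v}{2\omega_v}\, \frac{45\,\alpha'^2 + 7\,\gamma'^2}{45},$$

with ω₀ the excitation wavenumber (785 nm ≈ 12739 cm⁻¹ by default) and
only Stokes scattering modelled; no Boltzmann temperature factor is
applied. The physical prefactor (a combination of h, c and ε₀) is set to
1 in the default *proportional* mode: every quantity the analysis uses —
normalized spectra, band ratios, assignments — is invariant to it. An
*absolute* mode with the standard $h/(8\pi^2 c\,\omega_v)$-type constant
in SI units is provided for completeness and tested to be an exact
rescaling.

`broaden()` convolves the stick cross-sections with a unit-area Gaussian
or Lorentzian so each mode contributes its cross-section as integrated
band area, then optionally normalizes like an experimental spectrum;
`combine_anomers()` weights the α and β structures' spectra by their
solution populations. Supporting arithmetic: `waters_for_dm()` gives the
hydration-shell size implied by a dry-matter fraction (23 waters per
hexose at 30% DM), `count_normal_modes()` the 3n−6 rule, and
`match_bands()` a greedy nearest-distance assignment of computed to
experimental frequencies (each computed frequency used at most once,
default tolerance 10 cm⁻¹ — the typical harmonic-DFT error scale).

The shipped mode tables under `inst/extdata/` are *synthetic*: the
frequencies are the computed harmonic values for the hydrated
structures, but the invariants are invented stand-ins, because no
quantum-chemistry output is distributed or recomputed here. They
exercise the machinery; they do not reproduce computed intensities.

## What the synthetic generator does and does not show

`synth_spectrum()` builds exactly the structure the analysis assumes:
bands at the reference positions with amplitude = strength weight
(s/m/w → 1.0/0.5/0.2) × anomer population, a configurable lineshape of
width σ = 6 cm⁻¹, a gentle polynomial baseline expressed in a
grid-normalized coordinate, and seeded i.i.d. Gaussian noise (a
shot-noise model was rejected for simplicity; intensities are in
arbitrary units). The s/m/w amplitude map and the width are stand-ins —
only qualitative labels and a 2 cm⁻¹ instrument resolution are given
externally — and both are configurable. The default 1 cm⁻¹ grid is finer
than the instrument resolution so that fits are never grid-limited.
Mixtures scale each solute's bands by mass fraction × dry matter, take
solvent bands once scaled by (1 − DM), and add one shared baseline and
noise realization; calibration series derive per-spectrum seeds as
`seed + index − 1`. Noise is drawn in a local RNG scope, so generation
never perturbs the caller's random stream.

Passing on these synthetics therefore demonstrates that the estimators
are *correct under the model's own assumptions* — exact lineshapes,
additive smooth baseline, white noise, known band count. Real spectra
add cosmic-ray spikes, detector response, band asymmetry, concentration-
dependent peak shifts and correlated noise, none of which the generator
emulates; performance there must be established on instrument data. The
physical water envelope at 3400 cm⁻¹ is represented as a single broad
band at most, and bands outside the configured grid are skipped with a
warning (as with the 3400 cm⁻¹ band on the default 100–3000 cm⁻¹ range).

## Degenerate inputs and tie-breaks

Spectra require ≥ 2 strictly increasing grid points; readers reject
duplicate wavenumbers and name the offending line on parse errors; raw
reads warn on negative intensities but corrected spectra may be negative
freely. `crop()` uses closed intervals (printed band ranges read as
inclusive) and errors on empty overlap. Fitting requires ≥ 3n + 1 points
per region. `anomer_from_fit()` errors, naming the band, if no profile
lies within tolerance of a marker, or if one profile is nearest to both.
Zero anomeric signal, zero calibration slope, degenerate calibration
abscissae, all-zero normalization regions, anti-Stokes cross-section
requests and sub-3-atom mode counts are all rejected with specific
errors rather than propagated as NaN.

## Problem sizes

The test suite and drivers run on full-range spectra of 2901 points
(100–3000 cm⁻¹ at 1 cm⁻¹), 52-point anomeric windows, 100-replicate
noise studies for center recovery and 50-replicate studies for the full
pipeline — sizes chosen so the complete suite executes in seconds while
keeping the replicate counts large enough for stable error estimates.

## Known limitations

- Voigt and asymmetric profiles, joint multi-region fits and bootstrap
  uncertainties are out of scope.
- D-glucose anomer quantification is not attempted: no observed band
  pair separates its anomers cleanly in aqueous solution.
- The calibration is univariate (area vs content); multivariate (PLS)
  chemometrics is out of scope.
- No vendor binary or JCAMP formats; two-column delimited text is the
  only spectrum interchange format.
- Cosmic-ray removal and scan averaging are assumed to have happened
  upstream (on-instrument).
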