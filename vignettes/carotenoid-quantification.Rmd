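---
title: "Quantifying carotenoid:albumin complexes from 532 nm Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying carotenoid:albumin complexes from 532 nm Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotRaman)
```

## The measurement model

A 532 nm Raman measurement of a carotenoid:BSA solution is modelled as

$$ y(\Delta\nu) \;=\; T\!\big(u(\Delta\nu)\big)\,\sum_i c_i\,S_i(\Delta\nu)
   \;+\; W(\Delta\nu) \;+\; B(\Delta\nu) \;+\; P(\Delta\nu), $$

where $S_i$ are the pure carotenoid band profiles scaled by concentration
$c_i$ (mg/mL), $W$ and $B$ are the water and BSA spectra (constant solvent,
so fixed amplitudes), $P$ is a slowly varying stray-light baseline, and
$T(u)$ is the self-absorption transmission described below. On top of this
deterministic structure sit a per-spectrum global gain (collection
efficiency varies shot to shot), per-channel multiplicative noise, and
additive detector noise.

Every stage of the package inverts one piece of this model, and the
synthetic generator (`synth_config()`, `simulate_measurement()`) produces
data from exactly this structure with known ground truth, which is how the
chain is validated end to end.

### Self-absorption

At resonance the solution absorbs both the excitation beam and the
Stokes-scattered light. Integrating Beer–Lambert attenuation over the
illuminated depth (normalised to $[0,1]$) gives the transmission

$$ T(u) = \frac{1 - e^{-u}}{u}, \qquad
   u(\Delta\nu) = \alpha_L\,d_1 + \alpha_R\big(\lambda_R(\Delta\nu)\big)\,d_2, $$

with $\alpha = \ln(10)\,A(\lambda)\,c/c_\mathrm{ref}$ the natural
extinction scaled linearly from a reference absorbance spectrum,
$\lambda_R(\Delta\nu) = (1/\lambda_L - \Delta\nu\cdot 10^{-7})^{-1}$ the
Stokes wavelength of a channel, and $d_1, d_2$ dimensionless path factors
absorbing the (different) excitation and collection geometries. $T$ is
strictly decreasing with $T(0)=1$; `attenuation_factor()` evaluates the
small-$u$ limit by Taylor expansion below $10^{-8}$ to avoid cancellation.
The equivalent depth-resolved forms are sometimes printed with positive
exponents; here both paths attenuate, which is the physically meaningful
(and integrable) convention, and the closed form is verified against
numerical quadrature of $\int_0^1 e^{-ut}\,dt$ to $10^{-9}$ in the test
suite.

`fit_path_factors()` estimates $(k, d_1, d_2)$ from the ν1 peak heights of
a concentration series by minimising
$\sum_c\big[I(c) - k\,c\,T(\alpha_L(c)d_1 + \alpha_R(c)d_2)\big]^2$
(L-BFGS-B, $d_1,d_2 \in [0,20]$, eight seeded log-uniform starts). One
identifiability caveat is intrinsic: when the absorbance obeys Beer's law
exactly, $\alpha_R(c)/\alpha_L(c)$ is the same at every concentration, so
only the combination $u = \alpha_L d_1 + \alpha_R d_2$ is determined; the
fit reports that combination (`u_at_cref`) together with the particular
$(d_1, d_2)$ pair found and a `collinear` flag, and the parameter-recovery
test asserts the combination rather than the pair. Correction of a
spectrum divides each channel by $T(u(\Delta\nu))$; a single-wavelength
variant (α_R fixed at the 1519 cm⁻¹ Stokes wavelength, 579 nm) is
available via `per_channel = FALSE`.

### EMSC and the water internal standard

`emsc_fit()` regresses each (smoothed) spectrum on the carotenoid
reference, the water and BSA spectra, and a Chebyshev polynomial basis of
order 7 on the axis rescaled to $[-1,1]$ (the rescaling keeps the design
well conditioned; coefficients are reported in that basis). The corrected
spectrum subtracts the fitted interferents and baseline but keeps the
reference contribution and the residual. Rank deficiency (e.g. a
reference proportional to an interferent) is detected from the QR
decomposition and reported with the most collinear column pair.

Division by the fitted water coefficient (`water_normalize()`) cancels the
global gain exactly, because EMSC is linear: scaling a spectrum by $g$
scales every coefficient by $g$. The replicate-variability test verifies
that the coefficient of variation of the ν1 peak drops after
normalization under gain jitter.

Two ordering choices differ deliberately from common practice and are
worth stating. First, spectra are cropped to the 400–3100 cm⁻¹ analysis
window *before* the EMSC fit rather than after: the water-subtraction
artefacts above 3100 cm⁻¹ (slight changes of the OH band in solution) then
never enter the least squares problem, which is better conditioned.
Second, water normalization precedes self-absorption correction, so the
correction operates on gain-free intensities; the order is configurable in
`preprocess_set()`/`run_paper_twin()`.

For admixtures, whose composition is unknown at preprocessing time, the
EMSC reference column is the sum of the three pure references — the
reference column only has to span the analyte signal so the baseline does
not absorb it. The pure reference spectra used for unmixing are
preprocessed with the same summed reference, so the projection applied to
measured and reference spectra is identical.

### Calibration and differentiation

`fit_plsr()` is a NIPALS PLS1: latent variables maximise covariance
between the (internally mean-centered) spectral matrix and concentration,
and the regression vector is $B = W(P'W)^{-1}q$. It is cross-checked in
the tests against an independent PLS implementation (mixOmics) and against
closed-form rank-1 cases. `cross_validate()` draws `k = 10` random
near-equal folds, `repeats = 100` times, and pools the held-out squared
errors into one RMSECV per latent-variable count; the fold draws are the
only randomness and are fully determined by the seed. Reported R² is the
squared Pearson correlation between cross-validated predictions and
targets, and `lod()` applies the conventional LOD = 3.3 × RMSECV.
`select_n_lv()` implements two selection policies: first LV reaching 99.9%
cumulative explained Y-variance (the quantity that saturates in
regression; X-variance is also reported), or the smallest LV within one
standard error of the RMSECV minimum.

`fit_pca()` vector-normalises each spectrum to unit Euclidean norm,
mean-centers columns, and decomposes by SVD, with signs fixed by making
each loading's largest-magnitude element positive so score plots are
reproducible. Because the generator places the ν1 band at 1516 / 1521 /
1524 cm⁻¹ (beta-carotene / zeaxanthin / lutein), pairwise PC1 loadings
show the derivative-like line shape characteristic of a band shift, and
the three classes separate cleanly in (PC1, PC2).

### Unmixing

`fit_admixture()` minimises
$\lVert y - T(u_\mathrm{mix})\,\sum_i A_i\,\mathrm{ref}_i\rVert^2$ over
non-negative weights $A_i \in [0, 2]$, with
$u_\mathrm{mix}(\Delta\nu) = \sum_i A_i\,u_i(\Delta\nu)$ additive in the
weights by Beer's law (a per-component-correction variant is available).
Eight seeded multistarts plus one deterministic equal-weights start guard
against local minima; in the zero-absorbance limit the problem is linear
and the solution is verified against a non-negative least-squares oracle.
Results are reported as weights, percentages $100 A_i/\sum A$, and — for
comparison with as-prepared parts ratios — `fitted_ratio()` rescales
percentages by the declared total parts. `recovery_regression()` scores a
battery of admixtures by OLS of fitted% on nominal%, with the standard
error $\sqrt{SS_\mathrm{res}/(n-2)}$ in percentage points.

## The synthetic study conditions

The generator emulates the measurement campaign the analysis is designed
for; its defaults are fixed study conditions, not tuning knobs:

- **Grid**: 400–3100 cm⁻¹, step 2 cm⁻¹ (channel spacing is instrument
  dependent; 2 cm⁻¹ is typical of a 300 lines/mm grating at 532 nm and is
  configurable).
- **Bands**: Lorentzian fundamentals (FWHM ≈ 12 cm⁻¹): ν4 ~950 (weak),
  ν3 ~1004, ν2 ~1158, ν1 at 1516/1521/1524 cm⁻¹; Gaussian
  overtone/combination bands (FWHM 40 cm⁻¹) near 2126–2169, 2520–2526,
  2679–2685 and 3036–3040 cm⁻¹, strongest for zeaxanthin. Only the ν1
  *ordering* and the ~1519 cm⁻¹ vicinity are established band facts; the
  exact defaults are this package's choices. ν2/ν3 are relatively stronger
  in beta-carotene.
- **Interferents**: water (1640 cm⁻¹ bend, broad OH stretch centered
  3330 cm⁻¹ entering the window's upper edge) at amplitude 600 counts and
  BSA (sharp 1004 cm⁻¹, Amide I 1650 cm⁻¹, CH ~2900 cm⁻¹) at 150 counts;
  the carotenoid amplitude is 2000 counts·mL/mg, dominating under
  resonance as observed for these complexes.
- **Baseline**: degree-5 Chebyshev series decreasing from low to high
  wavenumber (stray-light scattering of the cloudy BSA solution); the
  EMSC uses order 7, deliberately over-parameterised relative to truth.
- **Absorbance**: Gaussian visible bands at 540/528/486 nm
  (beta-carotene/zeaxanthin/lutein) with peaks 0.70/0.90/0.45 AU per
  mg/mL — chosen once so that the resonance ordering at 532 nm is
  zeaxanthin > beta-carotene > lutein — plus a Mie-like scattering
  background $(a_0 + a_1 c)(700/\lambda)^{1.2}$ that is subtracted at
  700 nm by `subtract_scatter_background()`.
- **Attenuation geometry**: $d_1 = 1.3$, $d_2 = 1.75$, the established
  values for this cell geometry, also the correction defaults.
- **Noise**: 1% multiplicative (per channel), additive at 0.5% of each
  spectrum's maximum, 5% per-spectrum gain jitter. Shot (Poisson) noise is
  not modelled, as the counts scale is arbitrary.

What the generator does *not* emulate: instrument response (grating/CCD
efficiency) across the spectral range, cosmic spikes, wavenumber
calibration drift, solute-induced changes of the water spectrum, and any
deviation of the absorbance from Beer-law linearity. Consequently, passing
tests demonstrate the correctness and self-consistency of the algorithms
under the stated model — not robustness to those instrument effects on
real spectra. Two places where that distinction bites: (i) the
path-factor pair $(d_1, d_2)$ is only jointly identifiable here (see
above), whereas slight Beer-law violations in real data can break the
degeneracy; (ii) the EMSC of an *attenuated* spectrum is slightly biased,
because $T(u(\Delta\nu))\cdot S$ is not exactly in the span of the design
— in the simulated end-to-end admixture battery this leaves fitted
percentages within a few tenths of a point of nominal (recovery R² ≈
0.998), far tighter than the scatter observed on measured admixtures.

## Problem sizes and numerical choices

The shipped experiment driver `run_paper_twin()` uses 82 calibration
spectra (41 levels spanning 0.05–2.0 mg/mL × 2 replicates), 10 spectra
per carotenoid for PCA, and 4 admixture ratios × 3 replicates + 3 pure
spectra for unmixing; the full run takes well under a minute on one core.
The number of PLSR latent variables defaults to 8, where cumulative
Y-variance has long saturated; RMSECV is in fact nearly flat from 1–2 LVs
on, consistent with the essentially rank-1 signal.

Degenerate inputs are handled explicitly rather than numerically:
zero-absorbance series fall back to a linear fit with a `degenerate` flag,
identically-zero unmixing inputs return zero weights with a warning,
zero-norm rows make PCA fail with the row named, and the water coefficient
must exceed a tolerance (default $10^{-6}$) before normalization divides
by it. `resample()` refuses to extrapolate, and interpolation is linear
throughout — spectra are densely sampled and higher-order splines risk
ringing at the sharp ν1 band.

## Interfaces

The package is a library, not a shell tool: the exported functions above
are the public interface, `run_paper_twin()` is the one-call experiment
driver (writing CSV/JSON artefacts when given an output directory), and
`scripts/acceptance.R` is a thin command-line wrapper that recomputes the
headline numbers from a seed. Spectra move in and out as wide-format CSV
plus JSON/YAML sidecar via `read_spectra()`/`write_spectra()`.
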