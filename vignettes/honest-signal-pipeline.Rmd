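---
title: "From calibrated wing photographs to honest-signal tests: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From calibrated wing photographs to honest-signal tests: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aposignal)
```

## What the package models

Studies of quantitative honesty in aposematic coloration ask whether the
strength of a warning signal tracks the strength of the chemical defence it
advertises. For burnet moths (red-and-black day-flying Lepidoptera defended
by the cyanogenic glucosides linamarin and lotaustralin) the measurement
chain runs: calibrated UV-capable photography of the wings, conversion of
camera responses to avian cone catches, predator-vision color metrics,
receptor-noise-limited conspicuousness, LC-MS quantification of the toxins,
and a regression framework relating the two. `aposignal` implements that
chain end to end and, because no field data are deposited with such studies,
drives it with a synthetic-data generator whose ground truth is known, so
every stage can be tested for recovery.

## Camera model and calibration

The simulated camera has four channels: three visible channels behind a
400–700 nm UV/IR-cut filter and one UV channel behind a 300–400 nm UV-pass
filter, with Gaussian sensitivity curves on a shared 1-nm grid over
300–700 nm. The sensor's nonlinearity is a single power law with exponent
0.45 (a typical encoding gamma) applied to the gain-scaled linear signal;
sensor noise is applied to the *linear* signal before the nonlinearity, the
physically sensible ordering, which keeps linearization from amplifying the
noise.

Every frame contains two grey standards reflecting 7% and 93% of all
wavelengths. Calibration is three steps:

1. **Exponent estimation.** The standards share the frame gain, so their raw
   ratio depends only on the exponent: `g = log(s93/s7) / log(0.93/0.07)`,
   averaged over channels.
2. **Linearization.** `value^(1/g)`.
3. **Two-point normalization.** Per channel, the affine map sending the
   linearized standards to (0.07, 0.93). Two anchor points remove both gain
   and black-level offset, so any common positive factor (lighting change)
   cancels exactly; this is preferred over ratio-to-white normalization,
   which cannot remove an offset.

Negative normalized values (possible for patches darker than the dark
standard under noise) are clipped to zero with a warning, because log-ratio
contrasts downstream need positive values.

With noise-free rendering the chain recovers the channel-level reflectance
exactly (machine precision); at 0.5% sensor noise the propagated per-channel
error has a standard deviation of roughly 0.6–0.8%, so accuracy statements
in the test suite are made about the *median* per-channel relative error
(below 1%), not a uniform per-draw bound, which Gaussian tails would violate
for any implementation.

## Visual systems and the polynomial mapping

Receptor sensitivities are log-normal template curves with class-typical
peaks (UVS: 371, 445, 508, 565 nm; VS: 420, 455, 505, 567 nm; double cone
broad at 560 nm). Templates are used instead of tabulated empirical curves
to keep the package self-contained; they preserve the UVS/VS contrast that
matters for the analyses. Relative cone abundances are 1 : 1.92 : 2.68 : 2.7
(UVS) and 1 : 1.9 : 2.2 : 2.1 (VS), with Weber fraction ω = 0.05 attached to
the most abundant cone.

Quantum catches are von Kries normalized to a perfect white,
`q_i = ∫R·I·S_i / ∫I·S_i`, making them invariant to illuminant rescaling.
The camera-to-catch mapping is a per-receptor polynomial regression from the
four normalized channels to the quadrature-true catches, trained on a
synthetic reflectance library (default degree 2 with squares and all
pairwise interactions, 15 terms; at least 5× more spectra than terms are
required). The UV/V receptor uses all four channels, not the UV channel
alone, so cross-channel terms can absorb filter overlap; the double cone has
its own row because luminance is read from it. A fixed every-5th-spectrum
hold-out provides per-receptor R² diagnostics. Negative predictions (only
possible when extrapolating) are clipped to a 1e-6 floor with a warning.

## Color metrics

All chromatic metrics are computed from *relative* catches (each single-cone
catch over the sum of the four), following the proportion-of-total reading
of "standardized": z-scoring across specimens would produce negative values
for which the hue ratio is undefined.

* **Luminance** is the double-cone catch on the normalized scale
  (perfect white = 1), camera-independent.
* **Saturation** is the Euclidean distance from the achromatic center in a
  regular tetrahedron whose vertices are the four cone classes. The
  unit centroid-to-vertex convention is used; all regular-tetrahedron
  conventions agree up to a positive scale factor, which cannot affect any
  downstream correlation or regression.
* **Hue** is the long-wavelength ratio `l / ((u+s+m)/3)`: 1 at the
  achromatic point, larger for redder colors. A covariance PCA of relative
  catches (`pca_first_component()`) is provided to verify, per dataset, that
  one axis dominates color variation and justifies this one-dimensional
  channel; the sign convention fixes the LW loading non-negative.
* **Relative spot area** is total red spot area over wing area.

Because saturation and hue are functions of the same relative catches, they
are near-collinear on realistic ensembles; the generator reproduces this
(r > 0.99), and the within-population regression requires choosing one.

## Conspicuousness in JND

Chromatic contrast uses the log version of the receptor-noise-limited
model. Receptor noise is abundance-only, `e_i = ω·sqrt(η_max/η_i)` (no
photon-shot term: the photography regime is bright). The package computes
the distance as the noise-weighted deviation of the log catch-ratio vector
from the achromatic direction:

$$\Delta S^2 = \min_c \sum_i \left(\frac{\Delta f_i - c}{e_i}\right)^2,
\qquad \Delta f_i = \ln\frac{q_i^A}{q_i^B},$$

which is algebraically identical to the published tetrachromat formula and
reduces to the dichromat closed form
$|\Delta f_1-\Delta f_2|/\sqrt{e_1^2+e_2^2}$ for two receptors. The test
suite verifies equivalence against an independently written term-by-term
implementation of the four-receptor formula to 1e-10. Luminance contrast is
$|\ln(d_A/d_B)|/\omega$; the absolute value is adopted because contrast is
symmetric, though printed formulations sometimes omit it.

For plant backgrounds, patch catches are averaged per plant type first and
contrasts computed specimen-versus-average, one row per specimen × plant
type.

## LC-MS quantification

Chromatograms are three extracted-ion traces (m/z 270, 284, 480 for the
sodium adducts of linamarin, lotaustralin, and the amygdalin internal
standard) on a 0–17 min grid with Gaussian peaks at 2.6, 5.5, and 6.6 min.
Integration is trapezoidal after subtracting the straight baseline through
the window endpoints (default window ±0.3 min; the peaks are well
separated). Calibration is a straight line of analyte/IS area ratio on
amount — linear with free intercept, standard practice at the low-nmol
range. Quantification inverts the curve and divides by body mass; the
internal-standard ratio cancels whole-run multiplicative drift exactly.

One numerical subtlety is documented rather than hidden: endpoint-baseline
subtraction clips a reproducible ~0.3% of the widest peak at the default
window. Standards and samples share the loss, so it cancels through the
calibration curve; noise-free recovery stays within 2%.

Toxin units are nmol (amount) and nmol per mg fresh mass (concentration)
throughout; the literature reports both quantities without fixing units, so
one internal convention is declared.

## The synthetic cohort generator

`scenario_config()` fixes the study conditions. Defaults emulate a
three-population field study: 12 specimens per population per sex, female
mass 85 ± 10 mg versus male 60 ± 8 mg, toxin concentration lognormal
(median 20 nmol/mg, log-SD 0.4), population effects of 0.3 SD, and
`honesty_slope = 0` — the null scenario, reflecting the central empirical
finding that color does not track toxin load. Honest (`> 0`) and dishonest
(`< 0`) scenarios are one argument away, as a scalar or per-latent vector.

Each specimen carries standardized latent values on nine color axes;
observable metrics are affine functions of the latents, with saturation and
hue sharing a chroma latent (their near-collinearity is a feature of the
measurement process, not noise). The honesty slope acts on standardized
*log* concentration, the symmetric scale for a lognormal variable. Sexual
dimorphism defaults (0.8 SD) follow the directions reported for burnet
moths: males redder, more saturated, more contrasting; females larger-spotted
with lighter hindwings, and no forewing-luminance dimorphism.

When `render = TRUE` the generator also renders per-specimen camera patches
whose spectral templates are driven by the latents (amplitude by the
luminance latent, step position by the chroma latent), plus in-frame
standards, so the full measurement chain can run on them.

What the generator does **not** emulate: iridescence and viewing-angle
effects (the emulated protocol holds geometry fixed), spatial texture
within patches (patches are mean-value regions), wing wear and fading,
phylogenetic or spatial structure among populations, and non-Gaussian
sensor noise. Passing tests therefore demonstrate that the *machinery*
recovers known ground truth under these idealized conditions, not that real
wing measurements are this well behaved.

## Statistical pipeline

* **Among populations:** one point per population (means of metric and
  concentration, per sex, because sex ratios vary among sites), simple
  regression of metric on concentration, F test against the intercept-only
  model, *adjusted* R² (which can be negative, as small-sample honesty
  tables show).
* **Within populations:** concentration regressed on all wing metrics for
  one wing, excluding either saturation or hue; VIFs must be below 10;
  backward elimination by nested-model F tests at α = 0.05 ("model
  simplification" implies starting from the full model); Cook's distance
  computed on the **full** model — a gross outlier distorts selection before
  a minimal model exists — with flagged points (> 1) removed and the
  elimination re-run, both results reported.
* **Dimorphism:** `metric ~ sex * population`, interaction dropped when its
  sequential F test gives p ≥ 0.05; Tukey's HSD on populations via the
  studentized range with Tukey–Kramer standard errors (sampling is
  unbalanced in the field).
* **Plant contrasts:** random-intercept-per-individual mixed models fitted
  by maximum likelihood; fixed effects tested by likelihood-ratio
  chi-square between nested fits (LRT chosen and labeled; Wald tests would
  also be defensible). Luminance contrast, a non-negative JND, is mapped to
  (0, 1) by dividing by its maximum plus a small epsilon and
  logit-transformed — a declared rescaling, since a logit of raw JND values
  is undefined.

Raw p-values are reported across the ~11 metrics × 2 sexes without
multiplicity correction, matching field practice for these analyses; a
Benjamini–Hochberg column can be added by the user from the output tables
but is never used for inference here.

### Calibration of the tests

The suite checks, under matched null simulations with fixed seeds (2,000
replicates), that each implemented test rejects at 3.5–6.5% at nominal 5%:
the nested-model F test, the dimorphism sex test, family-wise Tukey error,
and the mixed-model LRT. The LRT calibration is run at the pipeline's own
cohort scale (72 individuals × 3 plant types); at much smaller samples
(tens of individuals) the asymptotic ML likelihood-ratio test is measurably
anticonservative — a known limitation of LRTs, worth remembering when
applying the mixed-model path to small cohorts. Power checks use the
honest scenario: at n = 25 and standardized slope 0.6 the within-population
regression recovers the slope sign in ≥ 95% of replicates; a driving
predictor at slope 0.8 (retention power ≈ 0.97) is kept in the minimal
model in ≥ 90% of replicates, while each null predictor is retained at
roughly the elimination α — which is why "the minimal model contains
*exactly* the true predictor" is not a property backward elimination can
promise at conventional α.

## Problem sizes and determinism

Simulation sizes used by the default pipeline and the test suite (72-specimen
cohorts, 175–200-spectrum mapping libraries, 200 LC-MS recovery replicates,
2,000-replicate null calibrations) were chosen so that binomial/Monte-Carlo
error is small relative to every asserted band. Every stochastic function
takes an explicit seed and restores the caller's RNG state; `run_pipeline()`
writes byte-identical CSVs for a fixed seed.
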