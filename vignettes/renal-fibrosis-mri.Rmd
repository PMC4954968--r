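---
title: "Assessing renal fibrosis from quantitative MRI: models, parameters and design choices"
author: "nephroMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing renal fibrosis from quantitative MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephroMRI)
```

# The problem

Interstitial fibrosis (IF) in a kidney allograft is graded today from a
needle biopsy. Diffusion-weighted MRI and T1 mapping are sensitive to
fibrotic remodelling, but absolute cortical ADC or T1 values scatter
widely between individuals (coil sensitivity, hydration, perfusion).
Referencing the cortex to the *same kidney's* medulla largely cancels
these nuisances, giving the cortico-medullary indices
ΔADC = ⟨ADC~cortex~⟩ − ⟨ADC~medulla~⟩ and ΔT1 defined analogously.
This package implements the full chain from image series to a
cohort-level fibrosis classification built on ΔADC, together with the
synthetic data needed to exercise it end to end.

# Models

## ADC mapping

Per pixel, the diffusion signal is modelled monoexponentially,
$S(b) = S_0 e^{-b \cdot \mathrm{ADC}}$, with $b$ in s/mm² and ADC
stored in 10⁻⁶ mm²/s (the unit every clinical number in this field is
quoted in; the exponent therefore uses ADC·10⁻⁶). Two fit criteria are
offered:

* **log-linear** (default): ordinary least squares of $\ln S$ on $b$.
  Fast and closed-form, but undefined for non-positive samples — such
  pixels are marked invalid, never raised as errors.
* **nonlinear**: least squares on the untransformed signal. The decay
  rate is profiled — at fixed ADC the amplitude is linear and solved
  exactly — over a coarse grid refined by golden-section search, then
  polished by damped Gauss–Newton steps that are accepted pixel-wise
  only when they reduce the residual. This gives machine-precision
  recovery on model-generated data while remaining fully vectorized
  across the map. The log-linear estimate seeds the profile bracket.

The fit is unweighted; more elaborate noise-weighted schemes need a
noise-map estimate that a routine clinical protocol does not provide.
ADC is constrained non-negative (a negative decay rate is non-physical
and occurs only through noise). No Rician bias correction is applied —
a deliberate simplification, listed under limitations.

## T1 mapping

Inversion-recovery magnitude data follow
$|S(TI)| = |A - B e^{-TI/T_1^*}|$. Because magnitude reconstruction
discards polarity, the fit restores it by trying every possible
sign-flip point of the TI-sorted samples (at most n~TI~+1 candidates —
exhaustive and cheap at this scale) and keeping the lowest-SSE
restoration. $T_1^*$ is profiled exactly as the ADC decay rate is (the
model is linear in $A, B$ at fixed $T_1^*$). The apparent time constant
is then corrected by the Look-Locker relation
$T_1 = T_1^*(B/A - 1)$.

Edge policies:

* $A \le 0$ or a non-convergent profile: pixel invalid.
* $B/A \le 1$ makes the correction non-physical; noisy pixels do
  produce this, so the apparent $T_1^*$ is reported with the pixel's
  quality flag set to 1 rather than dropping the pixel.
* With exactly three inversion times the fit has no residual degrees of
  freedom; collinear samples (detected by a second-difference test)
  leave the exponential undetermined and the pixel is invalid. A
  profile optimum pinned at the search ceiling is treated the same way.

The clinical MOLLI protocol modelled here lists three inversion times
(161, 241, 321 ms); a real MOLLI acquires more along the heartbeat
train. The synthetic generator emits six TIs (the three printed ones
plus 800, 1600, 3200 ms) so the three-parameter fit is over-determined
without inventing cardiac gating; the fitter itself accepts any ≥ 3.

## ROI pooling and the Δ indices

Compartment summaries pool **all valid pixels** of a compartment's ROIs
(the default), which weights ROIs by their area; a mean-of-ROI-means
mode is available for sensitivity analyses, since clinical descriptions
of "averaging the ROIs" are ambiguous between the two. The reported SD
is across pixels, with the across-ROI alternative available through the
same switch. Invalid pixels inside ROIs are silently excluded with a
warning once more than 20% of a compartment is lost. The synthetic ROI
sampler mimics manual placement: ~11 cortical ROIs of ~1.2 cm² and ~19
medullary ROIs of ~0.4 cm².

ΔADC is exactly the difference of the two pooled means; its sign
carries the diagnostic information.

## Histology quantification

Sirius-red sections are unmixed by optical-density colour
deconvolution: $OD = -\log_{10} I$ per channel, inverted through a 3×3
stain matrix whose rows are unit OD vectors for hematoxylin (the
published Ruifrok–Johnston vector), the red collagen marker, and their
residual cross product. The commercial software used for the original
marker-area detection does not publish its channel definitions, so the
stain matrix is configurable and the shipped thresholds are comparable
in spirit, not bit-identical, to that software's. Two presets ship:
human (hematoxylin 0.15, brown 0.59, red 0.11, min. area 10 µm²) and
rat (0.07, 0.45, 10 µm²). Channels are rescaled to [0, 1] by a fixed
reference OD of 2 so thresholds are dimensionless.

A pixel is marker if its marker channel passes its threshold while the
hematoxylin channel stays below its own (optionally the brown/residual
channel is also bounded — off by default, since how the brown bound
interacted with red in the original pipeline is undocumented).
8-connected components are then filtered by *physical* area:
pixels × calibration² < 10 µm² is removed. At the default calibration
of 0.232 µm/pixel this is exactly 186 px (⌈10/0.232²⌉), which the test
suite pins down on both sides. The percent area is marker area over
polygon-ROI area; pixel centers decide polygon membership (even-odd
rule).

## Cohort statistics

All hypothesis tests are two-sided; no direction is assumed anywhere.

* **Wilcoxon rank-sum**: "auto" mode computes the exact permutation
  distribution for n₁+n₂ ≤ 12 by convolution over the observed
  midranks (doubled to integers), which handles ties exactly; larger
  samples use the tie-corrected normal approximation with continuity
  correction. At the small sizes where both apply, the discrete null
  puts non-negligible mass on single rank-sum values, so the
  approximation typically tracks the exact p within ~0.02 but can
  deviate by up to ~0.06 on individual draws — identical behaviour to
  the standard R implementation, which the package reproduces exactly
  on its normal path.
* **Fisher-Z comparison** of two correlations treats them as
  independent samples, matching the on-line calculators commonly used
  in clinical work. Applied to overlapping samples (two indices from
  the same patients) it is approximate; this is reproduced as-is
  rather than "corrected", because the package's role is to implement
  the analysis as practised. Documented caveat.
* **ICC(1,1)**: one-way random-effects single-measure agreement,
  $(MS_B - MS_W)/(MS_B + (k-1) MS_W)$, with the F-based 95% CI.
* **ANOVA + Bonferroni**: classic one-way ANOVA and all pairwise
  pooled-SD t-tests with p multiplied by the number of comparisons.

## Threshold sweep, discriminant, bootstrap

The fibrosis threshold is discovered by splitting the cohort at each
grid value (IF > t vs IF ≤ t — strict inequality, consistent with
describing the high group as "more than" t percent), computing the
rank-sum p on ΔADC, and selecting the minimal-p threshold among
non-degenerate splits. **Tie-break**: thresholds tied at the minimal p
necessarily induce the same partition — they all fall in the empirical
gap between the two groups — so the tied threshold nearest the
midpoint of that gap is reported (the maximal-margin convention used
by decision stumps). A naive "first minimum" rule would
systematically report the lower edge of the gap and misplace the
cut-point in a noticeable fraction of cohorts.

Classification uses the one-dimensional equal-variance Gaussian
discriminant with pooled within-class variance. Priors default to
class frequencies (the common statistical-package default; equal
priors are a flag away, as the original choice is undocumented). The
boundary follows in closed form from equating the two class
discriminants. Sensitivity (recall on high-IF) and specificity (recall
on low-IF) are evaluated on the fitting sample — resubstitution, as
small clinical studies report it, and documented as optimistic.

Accuracy is bootstrapped: subjects resampled with replacement, the
discriminant refitted per replicate, resubstitution accuracy recorded;
the estimate is the mean with the 2.5/97.5 percentile interval.
Replicates missing a class are redrawn so the replicate count stays
fixed; if redraws exceed half the replicate budget the cohort is
declared too imbalanced and the run errors out. Every stochastic
result carries its seed.

# The synthetic module

The generators are deterministic functions of (spec, seed) and restore
the caller's RNG stream.

* **Phantoms**: a medullary ellipse nested in a cortical ellipse on
  zero background. Default tissue values (ADC 1800/2000 ×10⁻⁶ mm²/s,
  T1 1350/1450 ms, cortex/medulla) sit inside the clinically observed
  allograft ranges. Noise is Rician — the magnitude of signal plus
  complex Gaussian noise — because both input series are magnitude
  images; background pixels are therefore Rayleigh, which the tests
  verify against the closed-form density. IR phantoms use B = 2A, so
  the Look-Locker correction is the identity and the ground-truth T1
  is directly the specified tissue value.
* **Sections**: marker blobs are grown as connected patches inside a
  fixed rectangular ROI until the painted pixel count hits the target
  fraction exactly; a remainder smaller than the minimum blob size is
  grafted onto an existing blob so the area filter cannot silently eat
  true signal. Rendering goes through the same Beer–Lambert stain
  model the deconvolution inverts, plus slight sensor noise.
* **Cohorts** (n = 29 by default, mirroring the clinically analysed
  subset): IF is drawn from the bimodal mixture
  0.6·U(0, 35) + 0.4·U(45, 80), and
  ΔADC = 250 − 6.25·IF + ε, ε ~ N(0, 110²), truncated to
  [−260, 310] — the deterministic part crosses zero exactly at
  IF = 40%. σ = 110 was calibrated once so that the median cohort R²
  between IF and ΔADC is ≈ 0.64, the strength of coupling reported
  clinically; the truncation keeps compartment values inside their
  observed ranges. The ΔT1 link (20 − 2.8·IF + N(0, 85²), truncated
  to [−205, 23] ms) cannot match both the reported coupling strength
  (R² ≈ 0.29) and the reported extremes exactly under a
  linear-Gaussian model; keeping the values inside the observed range
  was prioritized, which lands the median coupling at R² ≈ 0.24 —
  slightly below the reported figure. Banff ci grades follow
  the standard percent bands (ci0 ≤ 5%, ci1 6–25%, ci2 26–50%,
  ci3 > 50%), ct is coupled to ci ± 1, inflammation scores are drawn
  independently (no inflammation coupling is modelled), and eGFR is
  loosely negatively linked to IF.

What the generators do **not** emulate: kidney anatomy beyond nested
ellipses, respiratory motion, susceptibility distortion, perfusion
(IVIM) effects at low b-values, stain batch variation, or any joint
distribution between ΔT1 and ΔADC beyond their separate links to IF.
Passing tests therefore demonstrate correctness of the *algorithms*
under the stated models, not clinical performance on patient data.

# Numerical choices

* Profile searches run on a coarse grid (201 ADC values to 10⁻² mm²/s;
  140 log-spaced T1* values, 30–8000 ms) followed by golden-section
  refinement (70–80 iterations) and, for ADC, Gauss–Newton polish.
  Noiseless round trips recover ADC to < 10⁻⁹ and T1 to < 10⁻⁶
  relative error at every pixel.
* The exact rank-sum distribution is built by dynamic programming over
  doubled midranks — O(n·n₁·ΣR) — rather than enumeration, and is
  verified against full `combn` enumeration in the tests.
* Percentile bootstrap intervals use the default quantile estimator; a
  single replicate collapses the interval to a point, by construction.
* Degenerate inputs favour flags over failures at pixel level (invalid
  pixels, quality flags) and typed errors at cohort level: I/O
  problems and statistical degeneracies raise distinct condition
  classes so callers and the CLI can map them to different exit codes.

# Problem sizes

Default problem sizes were chosen so a complete run stays interactive
on one core: 64×64 phantoms (48×48 in the round-trip checks), 200×200
sections, 29-subject cohorts, 200-cohort threshold-recovery and
calibration panels, 1000 bootstrap replicates, and a 10 000-simulation
type-I-error check. The full pipeline (`runPipeline()`) completes in
well under two minutes at these sizes.

# Known limitations

* No Rician bias correction in either fit; at clinical SNR the induced
  ADC bias is small but real.
* Resubstitution sensitivity/specificity is optimistic by design
  (matching how small cohorts are reported); no cross-validation is
  offered.
* The Fisher-Z comparison ignores the overlap of the two samples.
* The stain matrix is a published-vector approximation to an
  undocumented commercial pipeline; absolute thresholds should be
  recalibrated per scanner.
* IVIM/kurtosis models, motion and distortion correction, automatic
  cortex/medulla segmentation and ROC analysis are out of scope.
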