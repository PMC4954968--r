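# nephroMRI

Quantitative-MRI assessment of renal interstitial fibrosis, from raw
image series to a cohort-level fibrosis classification.

Interstitial fibrosis (IF) is the common endpoint of chronic kidney
allograft injury and is normally graded on a biopsy — an invasive
procedure with sampling error. Diffusion-weighted MRI and T1 mapping
both respond to fibrotic remodelling, but absolute cortical values vary
too much between individuals to be useful on their own. The
**cortico-medullary difference indices**

ΔADC = ⟨ADC<sub>cortex</sub>⟩ − ⟨ADC<sub>medulla</sub>⟩  (×10⁻⁶ mm²/s),
ΔT1 = ⟨T1<sub>cortex</sub>⟩ − ⟨T1<sub>medulla</sub>⟩  (ms)

cancel most of that inter-individual variation, and ΔADC decreases as
cortical fibrosis accumulates — in allograft cohorts it is positive
below roughly 40% IF and negative above it, which is what makes it a
usable classifier. `nephroMRI` implements the whole analysis chain:

- **mapping** — pixel-wise ADC maps from multi-b-value diffusion series
  via the monoexponential model S(b) = S₀·e^(−b·ADC) (log-linear or
  true nonlinear least squares), and T1 maps from inversion-recovery
  (MOLLI-type) magnitude series via the three-parameter model
  |S(TI)| = |A − B·e^(−TI/T1\*)| with polarity restoration and the
  Look-Locker correction T1 = T1\*(B/A − 1);
- **roi** — pooling of parametric maps over cortex/medulla regions of
  interest and the Δ indices;
- **histology** — automated Sirius-red fibrosis percent area by
  optical-density colour deconvolution, thresholding and a physical
  (µm²) minimum-area component filter;
- **stats** — Pearson correlations, Fisher-Z comparison of two
  correlations, Wilcoxon rank-sum (exact, tie-aware, or tie-corrected
  normal), ICC(1,1) inter-reader agreement, one-way ANOVA with
  Bonferroni post-hoc tests;
- **classify** — the fibrosis-threshold sweep (Wilcoxon p minimized
  over IF cut-offs 10–70%), a one-dimensional Gaussian linear
  discriminant on ΔADC with closed-form boundary, and a 1000-replicate
  bootstrap of classification accuracy;
- **synthetic** — seeded generators for every input: two-compartment
  Rician phantoms, stained sections with known fibrosis fraction, and
  calibrated cohorts (ΔADC linked linearly to IF with the zero
  crossing at 40% IF).

Sign convention: ΔADC is cortex minus medulla throughout, and negative
values are meaningful, not errors. The default imaging phantom mimics
the textbook contrast of a healthy kidney — cortical ADC below
medullary, true ΔADC = −200×10⁻⁶ mm²/s — which exercises the fitting
chain on a known negative index. The cohort generator instead encodes
the clinical regression structure: ΔADC falls linearly with IF and
crosses zero at 40%, so low-fibrosis subjects sit at positive and
high-fibrosis subjects at negative values. The two conventions reflect
two different observations (single-kidney contrast vs cohort-level
trend) and are independent knobs of the synthetic module.

## Worked example

```r
library(nephroMRI)

## a noisy two-compartment phantom: cortex ADC 1800, medulla 2000
ph   <- genDWIPhantom(phantomSpec(ricianSigma = 2, seed = 42))
fit  <- fitADCMap(ph$series, ph$labels > 0)
rois <- genROISet(ph$labels, seed = 42)
cortex  <- summarizeCompartment(fit$adc, rois, "cortex")
medulla <- summarizeCompartment(fit$adc, rois, "medulla")
deltaIndex(cortex, medulla)
#> DeltaIndex: -195.7 1e-6 mm^2/s (cortex 1796 - medulla 1992)

## a synthetic 29-subject cohort through the classification chain
tb <- genCohort(cohortSpec(seed = 42))
sw <- thresholdSweep(tb$if_masson, tb$delta_adc)
sw
#> ThresholdSweepResult: selected IF threshold 30 %
#>  threshold        p degenerate
#>         10 3.55e-03      FALSE
#>         20 7.66e-04      FALSE
#>         30 1.17e-05      FALSE
#>         40 7.82e-05      FALSE
#>         50 6.51e-05      FALSE
#>         60 5.31e-04      FALSE
#>         70 6.21e-02      FALSE
ldaFitEvaluate(tb$delta_adc, tb$if_masson > selectedThreshold(sw))
#> DiscriminantResult: boundary 82.52; sensitivity 88.9%, specificity 100.0%
bootstrapAccuracy(tb$delta_adc, tb$if_masson > selectedThreshold(sw),
                  seed = 42)
#> AccuracyEstimate: 0.940 (95% CI 0.862-1.000; 1000 bootstrap samples,
#>                         0 redrawn, seed 42)
```

The phantom's true ΔADC is −200; the fitted index lands within noise of
it. On this particular synthetic cohort the sweep picks 30% (individual
cohorts fluctuate around the planted 40% zero crossing); the
discriminant then reports resubstitution sensitivity/specificity for
that split and the bootstrap its accuracy distribution. `runPipeline()`
chains all stages and writes a JSON report plus a Markdown summary.

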