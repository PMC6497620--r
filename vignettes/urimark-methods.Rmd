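---
title: "Methods: urinary dietary biomarker discovery from FIE-HRMS fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary dietary biomarker discovery from FIE-HRMS fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urimark)
```

## The problem

Self-reported measures of dietary intake (food-frequency questionnaires,
diet diaries) are noisy and biased.  Urinary metabolites derived from
specific foods offer an objective complement: after a meal containing the
food, the marker's concentration in spot urine rises in a dose- and
time-dependent way, so spot samples — in particular the first morning void
(FMV), which integrates the previous day's exposure — can report what was
actually eaten.  `urimark` implements a complete discovery-and-validation
workflow for such markers from flow-infusion electrospray high-resolution
mass spectrometry (FIE-HRMS) fingerprints of spot urine:

1. **Normalization** of urine dilution by specific gravity (SG).
2. **Fingerprinting**: centroided mzML infusion runs are reduced to a
   samples x m/z-bin intensity matrix per ionization mode.
3. **Discovery**: bootstrapped random-forest / AUC / t-test feature
   selection over day-structured baseline vs postprandial comparisons, with
   model-adequacy gates and a two-tier candidate calling rule.
4. **Annotation**: accurate-mass matching of selected bins against a
   metabolite reference via adduct and neutral-loss rules at ppm tolerance,
   with Metabolomics Standards Initiative (MSI) evidence levels.
5. **Dose-response validation**: portion-size classification, next-day FMV
   concentration summaries, extreme-portion t-tests and Spearman rank
   correlation.

Because real intervention data cannot ship with a package, a first-class
synthetic study generator reproduces the data layout and the statistical
structure the analysis assumes; every stage is tested end-to-end against
its ground truth.

## Normalization

Fluid intake varies widely between spot samples, so all samples are brought
to a common dynamic range before fingerprinting.  The SG excess `SG - 1` is
taken as proportional to total solute (the standard urinomics convention).
With a triplicate-averaged SG (`average_sg`; readings disagreeing by more
than 0.002 raise a QC flag, readings outside [1.000, 1.060] are rejected as
implausible), the urine volume pipetted into a fixed 500 uL make-up volume
is

    urine = 500 uL * (target_sg - 1) / (mean_sg - 1)    if mean_sg > target
    urine = 500 uL (used neat)                          otherwise

(`dilution_volumes`).  Samples more dilute than the target are used neat
because no evaporation step exists in the protocol.  The target SG defaults
to 1.010 and is configurable; the laboratory reference value is a matter of
local convention.  In-silico, the equivalent operation divides a sample's
binned intensities by its dilution factor (`normalize_fingerprint`), which
is exact when instrument response is linear in concentration.  Creatinine
normalization is deliberately not offered (it carries a known gender bias);
voided-volume adjustment (`volume_adjust`, amount = concentration x volume)
is provided for sensitivity analyses but never required, since spot-sample
volumes are not always recorded successfully.

## Fingerprinting

Infusion runs have no chromatography; the information sits in the scans
around the apex of the infusion profile.  The apex is the argmax of the
3-scan moving average of the total ion current, with a raw-TIC plateau
straddling the smoothed apex resolved to its earliest scan; the default
window keeps 5 scans on each side (an 11-scan window), a choice that only
needs to cover the roughly flat top of the profile.  Within the window,
every peak inside the mode's acquisition range (m/z 55-1000 positive,
63-1000 negative) is assigned to the half-open 0.01 amu bin
`[lower, lower + 0.01)` anchored at the range's lower edge; intensities are
summed per bin across scans and divided by the number of scans, so windows
of different widths remain comparable.  Sum-then-average was chosen over a
plain sum for exactly that reason.  Each bin also carries the
intensity-weighted mean of the accurate (un-binned) peak masses it
received, because annotation must work at ppm accuracy while a 0.01 amu bin
is ~25-150 ppm wide over the acquisition range.  Positive- and
negative-mode matrices are kept separate and concatenated with mode-tagged
column labels (`pos_195.08`, `neg_149.00`) for feature selection.

## Discovery

For each experimental day, the fasting and FMV samples form the baseline
against each postprandial sample type of that day; for post-dinner samples
the following day's fasting and FMV form an additional comparison to catch
longer-duration markers (colonic-microbiota products, tissue-sequestered
metabolites).  Studies with both pre-day evening-meal conditions
(standardized vs low-polyphenol free choice) are compared within stratum.

Each comparison runs 100 stratified bootstraps: 2/3 of each class trains a
random forest (ntree = 1000, mtry = floor(sqrt(p))), the held-out 1/3 is
the test set.  Three statistics are aggregated as means across bootstraps:

* **Importance score (IS)** — unscaled permutation importance (mean
  decrease in out-of-bag classification accuracy) from the training fit.
  This is the native importance of the classical random-forest
  implementation; computing it instead on the external test split would
  cost one prediction pass per feature per bootstrap for no change in
  ranking.
* **AUC** — Mann-Whitney area under the ROC curve on the test split, ties
  counted one half, reported direction-agnostically as `max(a, 1 - a)`
  because a marker may rise or fall postprandially.
* **P** — two-sided pooled-variance Student's t-test on the test split.
  When a test split is too small to test (fewer than 2 per class), the
  full-data P-value is used instead; a `p_on_test = FALSE` switch computes
  all P-values once on the full data.

Candidate tiers: **discriminatory** requires IS > 0.002, P < 0.05 and
AUC >= 0.9; otherwise **putative** requires IS > 0.001 and AUC > 0.8.  The
AUC threshold is read as inclusive (>= 0.9) and the putative band as open
lower bounds without upper caps: a feature with a strong importance score
but AUC between 0.8 and 0.9 is still putative, matching how bold
(discriminatory) and italic (putative) calls partition in practice.  No
multiple-testing correction is applied — raw P < 0.05 is one of three
simultaneous conditions, and the bootstrap averaging plus the IS and AUC
thresholds do the heavy lifting; this is a deliberate caveat to keep in
mind when interpreting single-comparison results.  The model-level
adequacy gate (margin > 0.2 and AUC > 0.8, where the margin is the mean
vote-share advantage of the true class) guards against reading feature
tiers off a classifier that cannot actually separate the classes.  Tests
are unpaired: baseline and postprandial samples come from the same
participants, but the classical two-sample form is used; participant ids
travel with the data so a paired mode can be added.

Determinism: one master seed; per-bootstrap forest seeds are drawn from the
seeded R stream, and forests run single-threaded, so identical inputs give
byte-identical feature tables.  The forest engine is `ranger`, a standard
random-forest implementation with exactly the configuration above.

## Annotation

Theoretical m/z values are `multiplicity x M + delta` with deltas built
from the proton (1.007276 Da), Na-H (21.981944), K-H (37.955881), the
13C-12C shift (1.003355) and the SO3 neutral loss (79.956815).  The rule
set covers the ionization products of the bundled reference panel:
[M+H]+, [M-H]-, [M+Na]+, [M+K]+, [2M+H]+, [M+Na-2H]-, [M-SULP-H]- and the
13C satellite of each singly charged rule.  A bin annotates against all
(metabolite, rule) pairs whose theoretical m/z lies within the ppm
tolerance (1-5 ppm; default 5) of the bin's accurate mass; multiple
metabolites hitting one bin are all reported and flagged ambiguous.  MSI
levels are an evidence-flag rule only: level 1 for authentic-standard
matches, 2 for spectral-library matches, 3 for compound-class evidence —
no spectral matching is performed.

## Dose-response validation

Daily exposure to a food group is the sum of grams across that day's meals,
classified against a reference medium portion: large above 1.5x, small
below 0.5x, the medium band inclusive on both edges, zero intake "none".
The bundled portion reference uses 125 g for whole grapes and wine glasses,
204 g for grape juice and 30 g for raisins.  Each exposure day links to the
FMV collected the following morning.  Validation statistics are the
two-sided Student's t-test between the lowest and highest portion groups
and the Spearman rank correlation (midrank ties, t-approximation P) of
portion class — ordinal, the default, matching how portion data are
reported — or raw grams against concentration.  Quantified concentrations
below the limit of detection are substituted by LOD/2 (a standard
left-censoring convention) and flagged; values between LOD and LOQ are kept
but flagged.

## The synthetic study generator

`generate_study` emulates a free-living food-intervention study: menu days
with breakfast/lunch/afternoon-snack/dinner slots (08:00, 13:00, 16:00,
19:00 by convention), five spot samples per day (FMV 07:00, fasting 07:30,
postprandial samples 2-3 h after each main meal) plus the post-day FMV and
fasting samples, and participants alternating between the two pre-day
conditions.

* **Excretion kinetics.**  The above-baseline concentration after one
  exposure is `dose_coefficient x grams x g(t)` with the gamma-shaped
  kernel `g(t) = (t/t_peak)^k exp(k (1 - t/t_peak))`, normalized to peak at
  1; `k` is chosen so the kernel halves `elimination_halflife` hours after
  the peak.  The kernel is smooth, single-peaked and linear in dose by
  construction.  Default grape-marker kinetics (t_peak 6 h, half-life 4 h,
  0.2 ug/mL per gram at peak, baseline 0.5 ug/mL) put the excretion peak
  inside the expected 4-8 h window and the next-morning FMV concentration
  after a 200 g evening wine exposure near 10 ug/mL, with sub-1 ug/mL FMV
  levels after grape-free days — the concentration regime reported for
  tartaric acid as a grape marker.
* **Hydration.**  Per-sample dilution factors are log-normal
  (meanlog log 1.5, sdlog 0.3) and map to SG as `SG = 1 + 0.030/dilution`,
  placing typical SG in 1.011-1.037; voided volume scales with the
  dilution factor so the excreted amount (concentration x volume) is
  hydration-independent, as it must be.  SG triplicates get reading noise
  of sd 3e-4.
* **Spectra.** ~60 centroided scans whose total ion current follows a
  Gaussian infusion profile; each marker contributes peaks at its adduct
  m/z values (with a per-study calibration error of sd 1.5 ppm) plus an
  M+1 13C satellite at +1.003355 Da with abundance 1.1% per carbon in the
  ion (higher isotopologues are negligible at this scale); adducts outside
  the mode range are omitted and recorded in the ground truth.  A 2,000-bin
  background metabolome per mode — log-normal base intensities, identities
  fixed across samples — gives realistic feature dimensionality;
  multiplicative log-normal noise (sdlog 0.1) is applied per peak per scan,
  and all urine-borne intensities scale inversely with the dilution factor.
  Inter-individual variability enters as a log-normal participant
  multiplier (sdlog 0.25) on above-baseline excretion; no variance figures
  being available for it, this is a chosen, stated default.
* **What is not modeled:** gut-microbiome biotransformation differences,
  chromatographic retention, MRM traces, profile-mode peak shapes,
  higher isotopologues, in-source fragmentation.  Passing tests therefore
  demonstrate that the statistical machinery recovers truth under the
  stated model, not that it conquers every pathology of real urine data.

## Numerical and design choices

* Bin edges are half-open `[lower, lower + 0.01)`; the binning is tested
  exactly against a naive dictionary-accumulation oracle.
* AUC uses the rank-sum formulation (scalar path) and a pairwise-counting
  formulation (vectorized path); both are pinned to a brute-force oracle to
  1e-12.
* Zero-variance t-tests: equal means give P = 1; unequal means with zero
  variance are flagged degenerate with P = 0.
* Apex ties resolve to the earliest scan; run edges cannot win the
  smoothed argmax, but a monotone ramp's raw maximum at the edge is still
  honored.
* Stratified bootstrap splits keep class balance; classes below 3 samples
  are a hard error rather than a silent degenerate split.
* Constant vectors make Spearman's rho undefined; it is reported missing
  rather than coerced to zero.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use the scales at which
the method's operating characteristics were specified: spike recovery with
10 vs 10 samples, 2,000 background bins and 5 spiked bins at fold-change 4
over 10 seeds; the pure-noise control over 20 seeds; 100 bootstraps of
1000-tree forests throughout; 50-seed dose-response recovery at 4 dose
levels x 10 participants; 10,000-replicate t-test calibration; and a
smaller fully rendered mzML study (4 participants, 1 day, 150 background
bins) for the end-to-end path.  The end-to-end demonstration uses fewer
background bins than the selection simulations purely because it exercises
plumbing (mzML round trip, stage chaining), not operating characteristics.

## Known limitations

* The putative tier takes no P-value condition; it is a screening band.
* Importance scores are engine-level permutation importances; their
  absolute scale (and hence the 0.002/0.001 thresholds) assumes unscaled
  mean decrease in accuracy and will not transfer to scaled or
  impurity-based importances.
* The annotator reports all rule-compatible matches; it does not rank by
  biological plausibility, and the bundled rule table covers only the
  panel's observed ionization products.
* The generator's dilution/SG model is a single-solute idealization; real
  refractometry drifts with temperature and solute composition.
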