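---
title: "Balanced metrics for binary classifier validation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced metrics for binary classifier validation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4family)
```

## The problem

In medical-device validation — most prominently multi-reader multi-case
(MRMC) reader studies, where several radiologists rate the same cases under
two modalities — the area under the ROC curve (AUROC) is the conventional
primary endpoint. AUROC aggregates sensitivity (TPR) and specificity (TNR)
across decision thresholds, but it ignores the predictive values (PPV, NPV).
On datasets with a rare disease prevalence this hides exactly the quantity a
clinician cares about: if the device flags a patient, how often is it right?
A modality can gain 10 points of PPV and move AUROC barely at all.

`g4family` implements a *balanced metric family* that folds all four
conditional probabilities of the confusion matrix into a single score:

* **G4** — the geometric mean `(TPR * TNR * PPV * NPV)^(1/4)`, with an
  optional weighted form `(TPR^w1 * TNR^w2 * PPV^w3 * NPV^w4)^(1/Σw)`;
* **P4** — the harmonic mean `4 / (1/TPR + 1/TNR + 1/PPV + 1/NPV)`;
* **MCC_scaled** — the Matthews correlation coefficient rescaled to
  `[0, 1]` by `(MCC + 1)/2`.

These are linked by the identity
`MCC = G4^2 - sqrt((1-TPR)(1-TNR)(1-PPV)(1-NPV))`, and by the
arithmetic–geometric–harmonic mean inequality: whenever the dataset
prevalence equals the classifier's bias, `MCC_scaled >= G4 >= P4`, with
equality (and equality with balanced accuracy) when prevalence = bias = 50%.
All three are invariant to swapping the class labels. These identities are
enforced as property tests, including agreement of the MCC identity form
with the count-based Pearson form to 1e-10 over ten thousand random
matrices.

## Undefined rates

A rate with a zero denominator (e.g. PPV when nothing is predicted
positive) is reported as `NA`, an explicit undefined marker. Family metrics
refuse such input with a classed error (`g4family_undefined_error`) rather
than coercing to 0: a silent zero inside a bootstrap would contaminate the
replicate distribution. Two deliberate conventions follow:

* a *defined* rate equal to 0 yields `G4 = 0` and `P4 = 0` (the continuous
  limits of the formulas) — this is not an error;
* MCC with any zero marginal is treated as undefined, not as the "MCC = 0"
  convention some libraries use, so that the identity and Pearson forms
  never disagree on their domain.

Confusion-matrix cells accept non-integer values, because the
reader-average matrix of an MRMC modality (cell-wise mean over readers) is
a first-class object here.

## ROC conventions

Thresholding is strict: a case is positive iff its score exceeds the
threshold, so a probability of exactly 0.5 is a negative call at the 50%
threshold. Tied scores are grouped into a single ROC step, which makes the
trapezoidal area equal the Mann–Whitney rank statistic with half credit for
ties; the test suite checks that identity to 1e-12. For a binary predictor
the curve has a single interior point and the trapezoidal AUROC equals
balanced accuracy exactly.

## The binormal simulation engine

To compare the family against AUROC across prevalence regimes, scores are
generated from the binormal model. A nominal AUROC is converted to Cohen's
D by

```
t = sqrt(ln(1 / (1 - AUROC)^2))
z = t - (2.515517 + 0.802853 t + 0.0103328 t^2) /
        (1 + 1.432788 t + 0.189269 t^2 + 0.001308 t^3)
D = z * sqrt(2)
```

— the classical rational approximation to the normal quantile, so
`D ≈ sqrt(2) * Φ⁻¹(AUROC)` with absolute error below 7e-4 on D. AUROC = 1
is excluded (t diverges); grids cap at 0.999 and the printed 100% endpoint
is understood as a limit. Positive cases are drawn from N(+D/2, 1) and
negative from N(−D/2, 1), with class sizes fixed at `round(n * prevalence)`
rather than binomially sampled, so every run has exactly the configured
prevalence.

**The probability map.** Raw scores are passed through the logistic CDF
`plogis`, a fixed strictly increasing map onto (0, 1) centred so that raw 0
maps to probability 0.5. Any strictly increasing map leaves AUROC
unchanged; centring makes the 50% probability threshold coincide with the
binormal midpoint, which is the natural operating point when the two
classes are treated symmetrically. The bias observed at that threshold is
recorded per grid cell rather than forced to equal the prevalence: away
from prevalence 0.5 the midpoint threshold does not yield bias = prevalence,
and we prefer reporting what the construction actually produces.

**Benchmarks.** `benchmark_grid()` averages each cell over 20 replicates of
n = 10,000 by default, with a single seed driving the whole grid. At
prevalence 50% the three family metrics coincide up to Monte-Carlo error and
the cells are reproducible quantitatively (e.g. G4 near 0.72 at AUROC 80%
and near 0.81 at AUROC 90%). At lower prevalence the cell values depend on
the exact score-to-probability mapping, which published benchmark tables do
not pin down; several natural constructions (midpoint threshold, posterior
threshold, bias-matched quantile) give materially different values there.
The package therefore treats low-prevalence cells *qualitatively*: values
decrease monotonically as prevalence falls at fixed AUROC, and
P4 ≤ G4 ≤ MCC_scaled within each cell — both properties hold for the
midpoint-threshold construction used here and are asserted by the tests.
`benchmark_lookup()` interpolates bilinearly and refuses to extrapolate
outside the grid hull. As a rule of thumb, `rule_of_thumb()` returns the
benchmark for good performance: 0.70 when the minority prevalence is common
(> 30%), 0.60 when uncommon (10–30%, edges inclusive), 0.50 when rare
(< 10%), folding prevalences above 0.5 onto the minority class.

## MRMC inference

The unit of resampling is the **case**: a stratified, clustered,
non-parametric bootstrap resamples cases with replacement independently
within the positive and negative truth strata, preserving the stratum sizes
so every replicate has exactly the original prevalence. A resampled case
carries all of its readers' ratings (case = cluster), and replicate-local
duplicates are kept as distinct observations. Design choices:

* the replicate statistic is the metric of the replicate's *reader-average*
  confusion matrix, not the average of per-reader metrics, matching how
  reader-average results are reported; readers are weighted equally;
* the interval is the percentile interval at the requested level with
  B = 2000 by default — the simplest defensible choice; BCa or normal
  approximations could be substituted but are not needed for the widths
  involved here. Percentile intervals may exclude the plug-in point under
  skew, and that is not "corrected";
* a replicate on which the metric is undefined (a degenerate reader-average
  matrix) is redrawn and counted; the run aborts if redraws exceed 1% of B,
  since heavier redrawing would mean the data are too sparse for the metric
  and silent skipping would bias the interval.

Between-modality differences support two modes. `"crossed"` applies one
shared case resample to both modalities, appropriate for fully-crossed
designs and preserving the between-modality correlation; `"nested"`
resamples each modality independently, which ignores that correlation and
is therefore more conservative (wider) when modalities are positively
correlated — the appropriate assumption when only per-modality summary
data are available.

`reconstruct_counts()` inverts published summaries (N, prevalence, the
four rates) back to an integer matrix by exhaustive search, minimising the
maximum absolute rate deviation with a deterministic lexicographic
tie-break; composed with `rates()` at full precision it is the identity.

## The synthetic MRMC generator

`generate_synthetic_mrmc()` is the package's test bed and defines the
study conditions used throughout the test suite. It emulates a
rare-prevalence reader study: fixed class sizes, per-reader AUROCs drawn
from a normal truncated to \[0.51, 0.99\], modality 2 shifting every
reader's AUROC by a constant, and a shared-latent binormal score
`x = case_component + reader_noise ± D/2` with the case component carrying
half the variance — this induces the within-case correlation across readers
and modalities that makes case-cluster resampling necessary in the first
place. Scores are binned into ordinal ratings at standard-normal quantile
edges `qnorm(k/L)`; with an even number of levels the middle edge is 0, so
"rating ≥ L/2 + 1" coincides exactly with "probability above 50%". Defaults
mirror a breast-cancer reader study: 663 cases at prevalence 0.074, 10
readers around AUROC 0.93 (SD 0.02), a modality shift of 0.03, a 1–6 scale
cut at 4.

What it does *not* emulate: asymmetric operating points (real readers sit
off the binormal midpoint — the breast-cancer study's sensitivity of 0.918
at AUROC ~0.96 reflects such asymmetry), unequal case sets per reader,
reader-specific thresholds, and non-normal score distributions. Passing
coverage tests on this generator therefore demonstrates correctness of the
resampling machinery under a well-specified clustered data-generating
process, not robustness to every real-world reader behaviour.

## Power analysis

No published formula exists for G4 power, so the package defines its own
simulation-based procedure and documents it as such. A study of `n_cases`
at the configured AUROC and prevalence is simulated from the binormal
engine, dichotomized at the probability threshold, and analysed with the
stratified case bootstrap; the study "succeeds" if the one-sided lower
percentile bound at level alpha exceeds a fixed benchmark (e.g. from
`rule_of_thumb()`). Power is the success fraction over `n_replicates`
studies, reported with its binomial Monte-Carlo standard error. A two-sided
variant uses the lower bound of the two-sided interval. `B_inner` defaults
to 500 — power estimation tolerates coarser intervals than a confirmatory
analysis, and the saving is quadratic. `required_n()` doubles n until the
target power is met, then bisects to the smallest adequate n; because the
power at each n is itself Monte Carlo, the returned n inherits that
uncertainty and the full search trace is returned.

## Problem sizes in the test suite

The suite verifies the balanced-dataset benchmark cells at n = 10,000 with
20 replicates; bootstrap coverage on 200 synthetic studies of 240 cases
(prevalence 0.25, 4 readers) at B = 500; and null-power calibration with
150 simulated studies of 400 cases at B_inner = 300. These sizes were
chosen as the smallest at which the Monte-Carlo error is comfortably below
the tolerances being asserted (binomial SE ~1.6–1.8 points for the
coverage and power proportions).

## Known limitations

* Low-prevalence benchmark cells are construction-dependent (above); use
  the package's own grid, generated under the documented mapping, rather
  than mixing tables across tools.
* The percentile interval's small-sample coverage error is inherited by
  the power tool's alpha calibration at small n.
* Random-effects MRMC models (Obuchowski–Rockette / DBM) are out of scope;
  the bootstrap here conditions on the observed reader panel.
* AUROC confidence intervals for reader studies require per-reader rank
  data and are not produced from reader-average matrices.
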