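# g4family

Balanced confusion-matrix metrics for validating binary classifiers, aimed
at medical-device validation and multi-reader multi-case (MRMC) reader
studies, where AUROC is the conventional endpoint but hides changes in the
predictive values on imbalanced data.

The package centres on the **balanced metric family** — three means of the
four conditional probabilities of the 2×2 confusion matrix
(TPR = TP/(TP+FN), TNR = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN)):

* **G4** = (TPR · TNR · PPV · NPV)^(1/4) — geometric mean (optionally
  weighted: (TPR^w1 · TNR^w2 · PPV^w3 · NPV^w4)^(1/Σw));
* **P4** = 4 / (1/TPR + 1/TNR + 1/PPV + 1/NPV) — harmonic mean;
* **MCC_scaled** = (MCC + 1)/2, with
  MCC = G4² − √((1−TPR)(1−TNR)(1−PPV)(1−NPV)), equal to the count-based
  Pearson form (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)).

When prevalence equals the classifier's bias, MCC_scaled ≥ G4 ≥ P4 (the
arithmetic–geometric–harmonic inequality); at prevalence = bias = 50% all
three collapse to balanced accuracy. Around the family the package provides
the standard metric zoo (accuracy, F1, Youden's J, Cohen's kappa, ...),
empirical/trapezoidal ROC analysis, a binormal simulation engine for
prevalence-specific benchmarks against AUROC, a stratified clustered
case-resampling bootstrap for MRMC standalone and between-modality
inference, integer count reconstruction from published summary rates, and
simulation-based power analysis for G4 benchmark tests.

## Worked example

A published breast-cancer reader study (663 exams, 10 radiologists, AI-aided
"new technology" vs the current standard of care) reports the
reader-average confusion matrix TP = 45, FP = 72, FN = 4, TN = 542 for the
new technology:

```r
library(g4family)

cm_new <- confusion_matrix(45, 72, 4, 542)
cm_std <- confusion_matrix(44, 117, 5, 497)

round(rates(cm_new), 3)
#>   tpr   tnr   ppv   npv
#> 0.918 0.883 0.385 0.993
round(prevalence_bias(cm_new), 3)
#> prevalence       bias
#>      0.074      0.176
round(balanced_family(cm_new), 3)
#>         g4         p4 mcc_scaled
#>      0.746      0.686      0.775
round(balanced_family(cm_std), 3)
#>         g4         p4 mcc_scaled
#>      0.666      0.570      0.716
```

The disease prevalence is rare (7.4%), so despite both modalities having
AUROC above 0.92, the family sits far lower — it is pulled down by the PPV
of 0.385 — and separates the modalities much more sharply (G4 difference
8.0 points, P4 difference 11.6) than AUROC does. Against the rare-prevalence
rule-of-thumb benchmark:

```r
rule_of_thumb(0.074)
#> [1] 0.5
```

both modalities pass, but the margin differs by metric. For inference, the
stratified clustered bootstrap on a synthetic crossed reader study (same
design: 663 cases, prevalence 0.074, 10 readers, 1–6 ratings cut at ≥ 4):

```r
t <- generate_synthetic_mrmc(seed = 1)
bootstrap_metric_ci(t, 1, "g4", B = 2000, seed = 1)
#> g4: 0.7075  95% CI [0.6830, 0.7313]  (B = 2000, mode = standalone)
bootstrap_difference_ci(t, 2, 1, "g4", B = 2000, seed = 1, mode = "crossed")
#> g4: 0.0534  95% CI [0.0379, 0.0699]  (B = 2000, mode = crossed)
```

Every replicate resamples whole cases (with all their readers' ratings)
within the positive and negative strata, so the prevalence is identical in
every replicate; the interval is the percentile interval.

A thin command-line entry point wraps the same functions
(`inst/cli/g4family` once installed):

```sh
Rscript inst/cli/g4family metrics --counts 45,72,4,542
Rscript inst/cli/g4family benchmark --aurocs 0.8,0.9 --seed 1 --out grid.csv
```

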