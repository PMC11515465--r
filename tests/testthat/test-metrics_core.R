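cm_new <- confusion_matrix(45, 72, 4, 542)   # breast-study new technology
cm_std <- confusion_matrix(44, 117, 5, 497)  # current standard of care

test_that("rates computes the four conditional probabilities with explicit undefined markers", {
  q <- rates(cm_new)
  expect_equal(unname(q[["tpr"]]), 45 / 49, tolerance = 1e-12)
  expect_equal(unname(q[["tnr"]]), 542 / 614, tolerance = 1e-12)
  expect_equal(unname(q[["ppv"]]), 45 / 117, tolerance = 1e-12)
  expect_equal(unname(q[["npv"]]), 542 / 546, tolerance = 1e-12)

  expect_equal(as.numeric(rates(confusion_matrix(1, 0, 0, 1))),
               c(1, 1, 1, 1))

  # no predicted positives: PPV denominator is zero -> NA, never silent 0/0
  q0 <- rates(confusion_matrix(0, 0, 5, 5))
  expect_equal(unname(q0[["tpr"]]), 0)
  expect_equal(unname(q0[["tnr"]]), 1)
  expect_true(is.na(q0[["ppv"]]))
  expect_equal(unname(q0[["npv"]]), 0.5)
})

test_that("prevalence and bias follow the count definitions", {
  pb <- prevalence_bias(cm_new)
  expect_equal(unname(pb[["prevalence"]]), 49 / 663, tolerance = 1e-12)
  expect_equal(round(pb[["prevalence"]], 3), 0.074)
  expect_equal(unname(prevalence_bias(confusion_matrix(25, 25, 25, 25))),
               c(0.5, 0.5))
  expect_equal(unname(prevalence_bias(cm_std)[["bias"]]), 161 / 663,
               tolerance = 1e-12)
})

test_that("G4 is the (weighted) geometric mean of the rate quartet", {
  expect_equal(g4(cm_new), 0.7458820594, tolerance = 1e-9)
  expect_equal(g4(rate_quartet(1, 1, 1, 1)), 1)
  # zero-weighted components drop out: geometric mean of TPR, TNR
  expect_equal(g4(rate_quartet(0.9, 0.4, NA, NA), weights = c(1, 1, 0, 0)),
               0.6, tolerance = 1e-12)
  # weight scaling is a no-op; equal weights match the unweighted formula
  q <- rates(cm_std)
  expect_equal(g4(q, weights = c(2, 2, 2, 2)), g4(q), tolerance = 1e-15)
  expect_equal(g4(q), prod(q)^(1 / 4), tolerance = 1e-15)
  # a defined zero rate gives 0; an undefined rate is an error, not 0
  expect_equal(g4(rate_quartet(0, 1, 0.5, 0.5)), 0)
  expect_error(g4(rates(confusion_matrix(0, 0, 5, 5))),
               class = "g4family_undefined_error")
})

test_that("P4 is the harmonic mean of the rate quartet", {
  expect_equal(p4(cm_std), 0.5699467011, tolerance = 1e-9)
  expect_equal(p4(cm_new), 0.6862110683, tolerance = 1e-9)
  expect_equal(p4(rate_quartet(1, 1, 1, 1)), 1)
  expect_equal(p4(rate_quartet(0, 1, 0.5, 0.5)), 0)
  expect_error(p4(rates(confusion_matrix(0, 0, 5, 5))),
               class = "g4family_undefined_error")
})

test_that("MCC identity form, count form, and scaling agree", {
  expect_equal(mcc(cm_new), 0.5497707176, tolerance = 1e-9)
  expect_equal(mcc_scaled(cm_new), 0.7748853588, tolerance = 1e-9)
  # direct Pearson form on counts: 24102 / sqrt(117 * 49 * 614 * 546)
  expect_equal(mcc(cm_new, method = "counts"),
               24102 / sqrt(117 * 49 * 614 * 546), tolerance = 1e-12)
  expect_equal(mcc(cm_new), mcc(cm_new, method = "counts"),
               tolerance = 1e-10)
  # fully balanced matrix: scaled MCC is balanced accuracy
  bal <- confusion_matrix(20, 5, 5, 20)
  expect_equal(mcc_scaled(bal), zoo_metric("balanced_accuracy", bal),
               tolerance = 1e-12)
  expect_error(mcc(confusion_matrix(0, 0, 5, 5)),
               class = "g4family_undefined_error")
})

test_that("the metric zoo evaluates its printed formulas", {
  expect_equal(zoo_metric("accuracy", cm_new), 587 / 663, tolerance = 1e-12)
  expect_equal(zoo_metric("misclassification_rate", cm_new), 76 / 663,
               tolerance = 1e-12)
  expect_equal(zoo_metric("f1", cm_new), 90 / 166, tolerance = 1e-12)
  expect_equal(zoo_metric("ppa", cm_new), 90 / 166, tolerance = 1e-12)
  expect_equal(zoo_metric("youden_j", confusion_matrix(9, 2, 1, 8)),
               0.9 / 1 + 8 / 10 - 1, tolerance = 1e-12)
  q <- rates(cm_new)
  expect_equal(zoo_metric("geometric_mean", cm_new),
               sqrt(q[["tpr"]] * q[["tnr"]]), tolerance = 1e-12)
  expect_equal(zoo_metric("fowlkes_mallows", cm_new),
               sqrt(q[["tpr"]] * q[["ppv"]]), tolerance = 1e-12)
  expect_equal(zoo_metric("jaccard", cm_new), 45 / 121, tolerance = 1e-12)
  expect_equal(zoo_metric("pna", cm_new), 1084 / 1160, tolerance = 1e-12)
  expect_equal(zoo_metric("markedness", cm_new),
               q[["ppv"]] + q[["npv"]] - 1, tolerance = 1e-12)
  # (TP+FP)(FP+TN) + (TP+FN)(FN+TN) = 117*614 + 49*546; equals the
  # classical (p_o - p_e) / (1 - p_e) form
  expect_equal(zoo_metric("cohens_kappa", cm_new),
               2 * (45 * 542 - 72 * 4) / (117 * 614 + 49 * 546),
               tolerance = 1e-12)
  po <- 587 / 663
  pe <- (117 * 49 + 546 * 614) / 663^2
  expect_equal(zoo_metric("cohens_kappa", cm_new), (po - pe) / (1 - pe),
               tolerance = 1e-12)
  expect_equal(zoo_metric("p4", cm_new), p4(cm_new))
  expect_equal(zoo_metric("mcc", cm_new), mcc(cm_new))
  expect_length(zoo_metrics(), 14)
  expect_error(zoo_metric("aurocc", cm_new), "unknown metric")
})

test_that("balanced_family bundles the three metrics", {
  fam <- balanced_family(cm_std)
  expect_equal(unname(fam),
               c(0.6659337434, 0.5699467011, 0.7158021798),
               tolerance = 1e-9)
  expect_equal(unname(balanced_family(confusion_matrix(10, 0, 0, 10))),
               c(1, 1, 1))
})

test_that("family metrics are invariant to swapping the class labels", {
  set.seed(42)
  for (i in 1:200) {
    v <- rand_cm_counts()
    cm <- confusion_matrix(v["tp"], v["fp"], v["fn"], v["tn"])
    sw <- confusion_matrix(v["tn"], v["fn"], v["fp"], v["tp"])
    expect_equal(g4(cm), g4(sw), tolerance = 1e-12)
    expect_equal(p4(cm), p4(sw), tolerance = 1e-12)
    expect_equal(mcc(cm), mcc(sw), tolerance = 1e-12)
    expect_equal(mcc_scaled(cm), mcc_scaled(sw), tolerance = 1e-12)
  }
})

test_that("G4 dominates P4 wherever both are defined and positive", {
  set.seed(7)
  for (i in 1:500) {
    q <- rate_quartet(runif(1, 0.01, 1), runif(1, 0.01, 1),
                      runif(1, 0.01, 1), runif(1, 0.01, 1))
    expect_gte(g4(q), p4(q) - 1e-12)
  }
})

test_that("prevalence = bias collapses the quartet and orders the family", {
  # fn = fp forces prevalence = bias; then TPR = PPV and TNR = NPV exactly
  set.seed(11)
  for (i in 1:200) {
    tp <- sample(1:50, 1); tn <- sample(1:50, 1); off <- sample(0:20, 1)
    cm <- confusion_matrix(tp, off, off, tn)
    q <- rates(cm)
    expect_equal(q[["tpr"]], q[["ppv"]], tolerance = 1e-12)
    expect_equal(q[["tnr"]], q[["npv"]], tolerance = 1e-12)
    expect_equal(mcc_scaled(cm), zoo_metric("balanced_accuracy", cm),
                 tolerance = 1e-12)
    expect_gte(mcc_scaled(cm), g4(cm) - 1e-12)
    expect_gte(g4(cm), p4(cm) - 1e-12)
  }
  # fully balanced in addition (tp = tn, fp = fn): everything coincides
  cm <- confusion_matrix(30, 10, 10, 30)
  expect_equal(length(unique(round(rates(cm), 12))), 1L)
  expect_equal(g4(cm), p4(cm), tolerance = 1e-12)
  expect_equal(g4(cm), mcc_scaled(cm), tolerance = 1e-12)
})

test_that("confusion matrices admit fractional (reader-averaged) cells", {
  cm <- confusion_matrix(4.5, 7.2, 0.4, 54.2)
  expect_s3_class(cm, "confusion_matrix")
  expect_equal(g4(cm), g4(confusion_matrix(45, 72, 4, 542)),
               tolerance = 1e-12)
  expect_error(confusion_matrix(-1, 0, 0, 1), "non-negative")
  expect_error(confusion_matrix(0, 0, 0, 0), "positive total")
})
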