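#' G4: weighted geometric mean of the four conditional probabilities
#'
#' G4 = (TPR^w1 * TNR^w2 * PPV^w3 * NPV^w4)^(1 / sum(w)). With equal weights
#' it is the plain geometric mean of sensitivity, specificity, PPV and NPV.
#' A defined rate equal to 0 gives G4 = 0 (the continuous limit); an
#' *undefined* rate (zero denominator) raises a classed error — the two cases
#' are deliberately distinct.
#'
#' @param x A `rate_quartet`, `confusion_matrix`, or numeric 4-vector.
#' @param weights Non-negative exponents for (TPR, TNR, PPV, NPV), not all
#'   zero. Scaling all weights by a constant leaves G4 unchanged.
#' @return A score in \[0, 1\].
#' @examples
#' g4(confusion_matrix(45, 72, 4, 542))        # 0.746
#' g4(c(0.9, 0.4, 1, 1), weights = c(1, 1, 0, 0))  # geometric mean of TPR,TNR
#' @export
g4 <- function(x, weights = c(1, 1, 1, 1)) {
  q <- as_rate_quartet(x)
  if (!is.numeric(weights) || length(weights) != 4L || any(weights < 0) ||
      sum(weights) <= 0)
    stop("weights must be four non-negative numbers, not all zero",
         call. = FALSE)
  used <- weights > 0
  if (anyNA(q[used])) undefined_error("G4")
  if (any(q[used] == 0)) return(0)
  exp(sum(weights[used] * log(q[used])) / sum(weights))
}

#' P4: harmonic mean of the four conditional probabilities
#'
#' P4 = 4 / (1/TPR + 1/TNR + 1/PPV + 1/NPV). Any defined component equal to 0
#' gives P4 = 0 (harmonic-mean limit); an undefined component raises a
#' classed error.
#'
#' @inheritParams g4
#' @return A score in \[0, 1\].
#' @examples
#' p4(confusion_matrix(44, 117, 5, 497))  # 0.570
#' @export
p4 <- function(x) {
  q <- as_rate_quartet(x)
  if (anyNA(q)) undefined_error("P4")
  if (any(q == 0)) return(0)
  4 / sum(1 / q)
}

#' Matthews correlation coefficient and its \[0, 1\] rescaling
#'
#' `mcc()` evaluates the rate-based identity
#' `MCC = G4^2 - sqrt((1-TPR)(1-TNR)(1-PPV)(1-NPV))`, which is algebraically
#' equal to the count-based Pearson form
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`
#' (available via `method = "counts"` as an independent cross-check).
#' When any marginal (row or column sum) is zero MCC is undefined here and a
#' classed error is raised — not the "call it 0" convention some libraries
#' use — so that degenerate bootstrap replicates are caught, not averaged in.
#' `mcc_scaled()` maps it to \[0, 1\] via `(MCC + 1) / 2`.
#'
#' @inheritParams g4
#' @param method `"identity"` (rate-based, the default) or `"counts"`
#'   (Pearson form; requires a confusion matrix, not a bare quartet).
#' @return `mcc()`: a score in \[-1, 1\]; `mcc_scaled()`: in \[0, 1\].
#' @examples
#' mcc(confusion_matrix(45, 72, 4, 542))         # 0.5498
#' mcc_scaled(confusion_matrix(45, 72, 4, 542))  # 0.775
#' @export
mcc <- function(x, method = c("identity", "counts")) {
  method <- match.arg(method)
  if (method == "counts") {
    cm <- as_confusion_matrix(x)
    tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
    denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (denom2 == 0) undefined_error("MCC")
    return((tp * tn - fp * fn) / sqrt(denom2))
  }
  q <- as_rate_quartet(x)
  if (anyNA(q)) undefined_error("MCC")
  g4(q)^2 - sqrt(prod(1 - q))
}

#' @rdname mcc
#' @export
mcc_scaled <- function(x, method = c("identity", "counts")) {
  (mcc(x, method) + 1) / 2
}

#' The balanced metric family in one call
#'
#' Convenience bundle of G4, P4 and scaled MCC — the three means (geometric,
#' harmonic, arithmetic in disguise) of the four conditional probabilities.
#' Used as the unit of reporting by the simulation benchmarks and the MRMC
#' bootstrap.
#'
#' @inheritParams g4
#' @return Named numeric vector `c(g4 = , p4 = , mcc_scaled = )`.
#' @examples
#' balanced_family(confusion_matrix(45, 72, 4, 542))
#' @export
balanced_family <- function(x) {
  q <- as_rate_quartet(x)
  c(g4 = g4(q), p4 = p4(q), mcc_scaled = mcc_scaled(q))
}

# ---- metric zoo -----------------------------------------------------------

# registry entries take the confusion matrix and its rate quartet; rates that
# an entry uses and finds NA propagate as an undefined error via req()
req <- function(q, comps) {
  if (anyNA(q[comps])) undefined_error("metric")
  q
}

zoo_registry <- list(
  accuracy = function(cm, q) (cm[["tp"]] + cm[["tn"]]) / sum(cm),
  misclassification_rate = function(cm, q) (cm[["fp"]] + cm[["fn"]]) / sum(cm),
  balanced_accuracy = function(cm, q) {
    q <- req(q, c("tpr", "tnr")); (q[["tpr"]] + q[["tnr"]]) / 2
  },
  geometric_mean = function(cm, q) {
    q <- req(q, c("tpr", "tnr")); sqrt(q[["tpr"]] * q[["tnr"]])
  },
  fowlkes_mallows = function(cm, q) {
    q <- req(q, c("tpr", "ppv")); sqrt(q[["tpr"]] * q[["ppv"]])
  },
  f1 = function(cm, q) {
    denom <- 2 * cm[["tp"]] + cm[["fp"]] + cm[["fn"]]
    if (denom == 0) undefined_error("F1")
    2 * cm[["tp"]] / denom
  },
  jaccard = function(cm, q) {
    denom <- cm[["tp"]] + cm[["fp"]] + cm[["fn"]]
    if (denom == 0) undefined_error("Jaccard index")
    cm[["tp"]] / denom
  },
  ppa = function(cm, q) {
    denom <- 2 * cm[["tp"]] + cm[["fp"]] + cm[["fn"]]
    if (denom == 0) undefined_error("percent positive agreement")
    2 * cm[["tp"]] / denom
  },
  pna = function(cm, q) {
    denom <- 2 * cm[["tn"]] + cm[["fp"]] + cm[["fn"]]
    if (denom == 0) undefined_error("percent negative agreement")
    2 * cm[["tn"]] / denom
  },
  p4 = function(cm, q) p4(q),
  youden_j = function(cm, q) {
    q <- req(q, c("tpr", "tnr")); q[["tpr"]] + q[["tnr"]] - 1
  },
  markedness = function(cm, q) {
    q <- req(q, c("ppv", "npv")); q[["ppv"]] + q[["npv"]] - 1
  },
  cohens_kappa = function(cm, q) {
    tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
    denom <- (tp + fp) * (fp + tn) + (tp + fn) * (fn + tn)
    if (denom == 0) undefined_error("Cohen's kappa")
    2 * (tp * tn - fp * fn) / denom
  },
  mcc = function(cm, q) mcc(q)
)

#' Evaluate a named confusion-matrix metric
#'
#' A registry of the standard single-matrix metrics (accuracy,
#' misclassification rate, balanced accuracy, geometric mean,
#' Fowlkes-Mallows, F1, Jaccard, percent positive/negative agreement, P4,
#' Youden's J, markedness, Cohen's kappa, MCC), keyed by lower-snake name.
#'
#' @param name Metric name; see [zoo_metrics()] for the registry keys.
#' @param cm A [confusion_matrix()] or numeric 4-vector.
#' @return The metric value; range as implied by its formula.
#' @examples
#' zoo_metric("accuracy", confusion_matrix(45, 72, 4, 542))
#' zoo_metric("youden_j", confusion_matrix(9, 2, 1, 8))
#' @export
zoo_metric <- function(name, cm) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(zoo_registry))
    stop("unknown metric '", name, "'; see zoo_metrics()", call. = FALSE)
  cm <- as_confusion_matrix(cm)
  zoo_registry[[name]](cm, rates(cm))
}

#' @rdname zoo_metric
#' @export
zoo_metrics <- function() names(zoo_registry)

# resolve a metric spec (registry name, family name, or function) to a
# function of a confusion matrix; used by the bootstrap and power modules
resolve_metric <- function(metric) {
  if (is.function(metric)) return(metric)
  if (is.character(metric) && length(metric) == 1L) {
    if (metric == "g4") return(function(cm) g4(cm))
    if (metric == "mcc_scaled") return(function(cm) mcc_scaled(cm))
    if (metric %in% names(zoo_registry))
      return(function(cm) zoo_metric(metric, cm))
  }
  stop("metric must be a function or one of: g4, mcc_scaled, ",
       paste(names(zoo_registry), collapse = ", "), call. = FALSE)
}
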