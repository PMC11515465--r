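#' Construct a confusion matrix
#'
#' Bundles the four cells of a 2x2 truth-vs-prediction table. Cells may be
#' non-integer so that reader-averaged matrices from multi-reader studies are
#' first-class objects.
#'
#' @param tp,fp,fn,tn Non-negative cell counts (reals allowed). `tp` and `fn`
#'   are truly-positive cases, `fp` and `tn` truly-negative cases; `tp` and
#'   `fp` are predicted positive.
#' @return An object of class `confusion_matrix`: a named numeric vector with
#'   elements `tp`, `fp`, `fn`, `tn`.
#' @examples
#' cm <- confusion_matrix(45, 72, 4, 542)
#' rates(cm)
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (length(cells) != 4L || anyNA(cells) || !is.numeric(cells))
    stop("confusion matrix needs four numeric cells", call. = FALSE)
  if (any(cells < 0))
    stop("confusion matrix cells must be non-negative", call. = FALSE)
  if (sum(cells) <= 0)
    stop("confusion matrix must have a positive total", call. = FALSE)
  structure(as.numeric(cells), names = c("tp", "fp", "fn", "tn"),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x[["tp"]], x[["fp"]], x[["fn"]], x[["tn"]]),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("pred +", "pred -"),
                              c("truth +", "truth -")))
  print(m, ...)
  invisible(x)
}

as_confusion_matrix <- function(x) {
  if (inherits(x, "confusion_matrix")) return(x)
  if (is.numeric(x) && length(x) == 4L)
    return(confusion_matrix(x[[1]], x[[2]], x[[3]], x[[4]]))
  stop("cannot interpret input as a confusion matrix", call. = FALSE)
}

#' Conditional probabilities of a confusion matrix
#'
#' Computes sensitivity (TPR), specificity (TNR), positive and negative
#' predictive values. A component whose denominator is zero is returned as
#' `NA` — an explicit undefined marker, never silently coerced to 0 — so that
#' downstream metrics can refuse degenerate matrices rather than corrupt
#' aggregate distributions.
#'
#' @param cm A [confusion_matrix()] (or a numeric 4-vector `tp, fp, fn, tn`).
#' @return An object of class `rate_quartet`: named numeric vector
#'   `tpr`, `tnr`, `ppv`, `npv`, each in \[0, 1\] or `NA` when undefined.
#' @examples
#' rates(confusion_matrix(45, 72, 4, 542))
#' @export
rates <- function(cm) {
  cm <- as_confusion_matrix(cm)
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  div <- function(num, den) if (den > 0) num / den else NA_real_
  rate_quartet(tpr = div(tp, tp + fn), tnr = div(tn, tn + fp),
               ppv = div(tp, tp + fp), npv = div(tn, tn + fn))
}

#' Construct a rate quartet directly
#'
#' @param tpr,tnr,ppv,npv Proportions in \[0, 1\], or `NA` for an undefined
#'   component (zero denominator in the source matrix).
#' @return A `rate_quartet` object.
#' @export
rate_quartet <- function(tpr, tnr, ppv, npv) {
  q <- c(tpr = tpr, tnr = tnr, ppv = ppv, npv = npv)
  bad <- !is.na(q) & (q < 0 | q > 1)
  if (any(bad))
    stop("rate components must lie in [0, 1]: ",
         paste(names(q)[bad], collapse = ", "), call. = FALSE)
  structure(as.numeric(q), names = c("tpr", "tnr", "ppv", "npv"),
            class = "rate_quartet")
}

as_rate_quartet <- function(x) {
  if (inherits(x, "rate_quartet")) return(x)
  if (inherits(x, "confusion_matrix")) return(rates(x))
  if (is.numeric(x) && length(x) == 4L)
    return(rate_quartet(x[[1]], x[[2]], x[[3]], x[[4]]))
  stop("cannot interpret input as a rate quartet", call. = FALSE)
}

#' Prevalence and bias of a confusion matrix
#'
#' Prevalence is the fraction of truly positive cases,
#' `(TP + FN) / N`; bias is the fraction of cases the classifier predicts
#' positive, `(TP + FP) / N`.
#'
#' @inheritParams rates
#' @return Named numeric vector `c(prevalence = , bias = )`, both in \[0, 1\].
#' @examples
#' prevalence_bias(confusion_matrix(45, 72, 4, 542))
#' @export
prevalence_bias <- function(cm) {
  cm <- as_confusion_matrix(cm)
  n <- sum(cm)
  c(prevalence = (cm[["tp"]] + cm[["fn"]]) / n,
    bias = (cm[["tp"]] + cm[["fp"]]) / n)
}

# classed condition for metrics asked to evaluate a degenerate matrix
undefined_error <- function(what) {
  stop(structure(class = c("g4family_undefined_error", "error", "condition"),
                 list(message = paste0(what, " is undefined: a required ",
                                       "denominator (row or column sum) is 0"),
                      call = sys.call(-1))))
}
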