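#' Construct a score set
#'
#' Pairs continuous classifier scores (probabilities or raw scores) with
#' binary ground-truth labels.
#'
#' @param scores Numeric vector of scores.
#' @param truth Parallel vector of labels; anything coercible to 0/1
#'   (logical, 0/1 numeric, or a factor/character with two levels where the
#'   larger / second level is positive).
#' @return A `score_set`: data frame with columns `score` and `truth` (0/1).
#' @export
score_set <- function(scores, truth) {
  if (length(scores) != length(truth))
    stop("scores and truth must have equal length", call. = FALSE)
  if (length(scores) == 0L)
    stop("empty score set", call. = FALSE)
  if (!is.numeric(scores) || anyNA(scores))
    stop("scores must be numeric without NA", call. = FALSE)
  t01 <- as_binary_truth(truth)
  structure(data.frame(score = as.numeric(scores), truth = t01),
            class = c("score_set", "data.frame"))
}

as_binary_truth <- function(truth) {
  if (is.logical(truth)) return(as.integer(truth))
  if (is.factor(truth) || is.character(truth)) {
    lv <- sort(unique(as.character(truth)))
    if (length(lv) > 2) stop("truth has more than two levels", call. = FALSE)
    return(as.integer(as.character(truth) == lv[length(lv)]))
  }
  if (is.numeric(truth)) {
    if (anyNA(truth) || !all(truth %in% c(0, 1)))
      stop("numeric truth must be 0/1", call. = FALSE)
    return(as.integer(truth))
  }
  stop("cannot interpret truth labels", call. = FALSE)
}

#' Dichotomize scores at a threshold
#'
#' A case is called positive iff its score is strictly greater than the
#' threshold; scores equal to the threshold are negative calls. The same
#' strict rule is used throughout the package, including by the binormal
#' simulation engine at its 50% probability threshold.
#'
#' @param s A [score_set()].
#' @param threshold Decision threshold on the score scale.
#' @return A [confusion_matrix()] whose cells sum to `nrow(s)`.
#' @examples
#' s <- score_set(c(0.4, 0.5, 0.6), c(0, 0, 1))
#' threshold_classify(s, 0.5)  # 0.5 falls in the negatives
#' @export
threshold_classify <- function(s, threshold) {
  stopifnot(inherits(s, "score_set"))
  pred <- s$score > threshold
  pos <- s$truth == 1L
  confusion_matrix(tp = sum(pred & pos), fp = sum(pred & !pos),
                   fn = sum(!pred & pos), tn = sum(!pred & !pos))
}

#' Empirical ROC curve
#'
#' Sweeps the decision threshold across the distinct observed scores (tied
#' scores grouped into a single step) and collects the
#' (1 - specificity, sensitivity) operating points, anchored at (0,0) and
#' (1,1).
#'
#' @param s A [score_set()] containing at least one positive and one
#'   negative case.
#' @return A `roc_curve`: data frame with columns `fpr`, `tpr`,
#'   non-decreasing in both, starting at (0,0) and ending at (1,1).
#' @export
roc_curve <- function(s) {
  stopifnot(inherits(s, "score_set"))
  n_pos <- sum(s$truth == 1L)
  n_neg <- sum(s$truth == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC curve requires both classes present", call. = FALSE)
  # descending unique scores: each is a threshold "call positive if > t" for
  # t just below it; cumulate class counts within tied groups at once
  ord <- order(s$score, decreasing = TRUE)
  sc <- s$score[ord]
  pos <- s$truth[ord] == 1L
  grp_last <- !duplicated(sc, fromLast = TRUE)  # last index of each tie group
  tpr <- cumsum(pos)[grp_last] / n_pos
  fpr <- cumsum(!pos)[grp_last] / n_neg
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  # the final tie group always lands on (1,1); interior points only otherwise
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  structure(pts, class = c("roc_curve", "data.frame"))
}

#' Trapezoidal area under the ROC curve
#'
#' Sums the trapezoid areas between consecutive curve points. With the tie
#' handling used by [roc_curve()], this equals the Mann-Whitney rank
#' statistic U / (n_pos * n_neg) with ties given half credit.
#'
#' @param x A `roc_curve` or a [score_set()] (curve built on the fly).
#' @return AUROC in \[0, 1\].
#' @examples
#' s <- score_set(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
#' auroc_trapezoid(s)
#' @export
auroc_trapezoid <- function(x) {
  if (inherits(x, "score_set")) x <- roc_curve(x)
  stopifnot(inherits(x, "roc_curve"))
  dx <- diff(x$fpr)
  mid <- (x$tpr[-1] + x$tpr[-nrow(x)]) / 2
  sum(dx * mid)
}
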