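#' Construct a multi-reader multi-case (MRMC) ratings table
#'
#' Long-format records of a reader study: one row per (modality, reader,
#' case) holding the case's binary truth and the reader's ordinal rating or
#' continuous score. Truth must be constant per case across readers and
#' modalities. The positivity rule turning ratings into binary calls is part
#' of the object: `rating >= positive_cut` (e.g. a biopsy recommendation at
#' >= 4 on a 1-6 scale), or `rating > positive_cut` with `strict = TRUE` for
#' continuous probability scores thresholded the same way the ROC module
#' thresholds them.
#'
#' @param data Data frame with columns `modality`, `reader`, `case`,
#'   `truth`, `rating`.
#' @param positive_cut Rating threshold for a positive call (default 4).
#' @param strict If `TRUE`, positive iff `rating > positive_cut`; if `FALSE`
#'   (default, ordinal convention), positive iff `rating >= positive_cut`.
#' @return An `mrmc_table` (a data frame with attributes `positive_cut`,
#'   `strict`).
#' @export
mrmc_table <- function(data, positive_cut = 4, strict = FALSE) {
  need <- c("modality", "reader", "case", "truth", "rating")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  data <- as.data.frame(data)[need]
  data$truth <- as_binary_truth(data$truth)
  if (!is.numeric(data$rating) || anyNA(data$rating))
    stop("rating must be numeric without NA", call. = FALSE)
  tr_per_case <- tapply(data$truth, data$case, function(x) length(unique(x)))
  if (any(tr_per_case > 1))
    stop("truth must be constant per case across readers and modalities",
         call. = FALSE)
  structure(data, positive_cut = positive_cut, strict = isTRUE(strict),
            class = c("mrmc_table", "data.frame"))
}

mrmc_positive <- function(t, rating) {
  if (attr(t, "strict")) rating > attr(t, "positive_cut")
  else rating >= attr(t, "positive_cut")
}

# Per-case summary for one modality: truth and the fraction of readers
# calling the case positive. The reader-average confusion matrix is a linear
# image of this vector, which makes case-cluster bootstrapping O(n) per
# replicate. Enforces the crossed requirement that every reader in the
# modality rated every case.
case_posrate <- function(t, modality) {
  sub <- t[t$modality == modality, , drop = FALSE]
  if (nrow(sub) == 0) stop("modality not present: ", modality, call. = FALSE)
  readers <- unique(sub$reader)
  cases <- sort(unique(sub$case))
  counts <- table(factor(sub$case, levels = cases))
  if (any(counts != length(readers)) ||
      nrow(sub) != length(readers) * length(cases))
    stop("missing ratings: every reader must rate every case within a ",
         "modality", call. = FALSE)
  pos_call <- mrmc_positive(t, sub$rating)
  a <- tapply(pos_call, factor(sub$case, levels = cases), mean)
  truth <- tapply(sub$truth, factor(sub$case, levels = cases), function(x) x[1])
  list(case = cases, truth = as.integer(truth), posrate = as.numeric(a),
       n_readers = length(readers))
}

posrate_cm <- function(truth, a) {
  pos <- truth == 1L
  confusion_matrix(tp = sum(a[pos]), fp = sum(a[!pos]),
                   fn = sum(1 - a[pos]), tn = sum(1 - a[!pos]))
}

#' Reader-average confusion matrix of one modality
#'
#' The cell-wise mean of the per-reader confusion matrices (equal reader
#' weights). Cells are generally non-integer; they sum to the per-reader
#' case total, and the matrix's prevalence equals the case-level prevalence
#' exactly because truth is reader-invariant.
#'
#' @param t An [mrmc_table()].
#' @param modality Modality id present in the table.
#' @return A [confusion_matrix()] with (possibly) fractional cells.
#' @export
reader_average_cm <- function(t, modality) {
  stopifnot(inherits(t, "mrmc_table"))
  pr <- case_posrate(t, modality)
  posrate_cm(pr$truth, pr$posrate)
}

#' Reconstruct integer confusion-matrix counts from summary rates
#'
#' Publications often report only N, prevalence and the four conditional
#' probabilities. This searches all integer matrices with the given total
#' and `round(N * prevalence)` positives for the one whose implied rates
#' minimize the maximum absolute deviation from the reported quartet
#' (deterministic tie-break: lexicographically smallest `tp`, then `fp`).
#'
#' @param n_total Total case count N.
#' @param prevalence Reported prevalence; fixes the positive count at
#'   `round(n_total * prevalence)`.
#' @param q A [rate_quartet()] (NA components are unconstrained).
#' @return A [confusion_matrix()] with integer cells.
#' @examples
#' reconstruct_counts(663, 0.074, rate_quartet(0.918, 0.883, 0.385, 0.993))
#' @export
reconstruct_counts <- function(n_total, prevalence, q) {
  q <- as_rate_quartet(q)
  n_pos <- round(n_total * prevalence)
  n_neg <- n_total - n_pos
  if (n_pos < 0 || n_neg < 0)
    stop("infeasible: class sizes negative", call. = FALSE)
  if (n_pos == 0 && !is.na(q[["tpr"]]) && q[["tpr"]] > 0)
    stop("infeasible: prevalence rounds to 0 positives but tpr > 0",
         call. = FALSE)
  tp <- rep(0:n_pos, each = n_neg + 1)
  fp <- rep(0:n_neg, times = n_pos + 1)
  dev <- function(implied, target) {
    if (is.na(target)) return(rep(0, length(implied)))
    ifelse(is.na(implied), Inf, abs(implied - target))
  }
  # vectorized safe division over candidate matrices (den may be scalar)
  sdiv <- function(num, den) {
    out <- rep(NA_real_, max(length(num), length(den)))
    ok <- rep_len(den > 0, length(out))
    out[ok] <- (rep_len(num, length(out)) / rep_len(den, length(out)))[ok]
    out
  }
  d <- pmax(dev(sdiv(tp, n_pos), q[["tpr"]]),
            dev(sdiv(n_neg - fp, n_neg), q[["tnr"]]),
            dev(sdiv(tp, tp + fp), q[["ppv"]]),
            dev(sdiv(n_neg - fp, n_neg - fp + n_pos - tp), q[["npv"]]))
  if (all(!is.finite(d)))
    stop("infeasible: no integer matrix attains the reported rates",
         call. = FALSE)
  best <- which.min(d)  # ties: first index = smallest tp, then smallest fp
  confusion_matrix(tp = tp[best], fp = fp[best],
                   fn = n_pos - tp[best], tn = n_neg - fp[best])
}

bootstrap_result <- function(estimate, reps, level, seed, mode, redraws,
                             metric) {
  ci <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(estimate = estimate, ci_lower = ci[1], ci_upper = ci[2],
                 level = level, B = length(reps), seed = seed, mode = mode,
                 redraws = redraws, metric = metric, replicates = reps),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%s: %.4f  %d%% CI [%.4f, %.4f]  (B = %d, mode = %s",
              x$metric, x$estimate, round(100 * x$level), x$ci_lower,
              x$ci_upper, x$B, x$mode))
  if (x$redraws > 0) cat(sprintf(", %d replicates redrawn", x$redraws))
  cat(")\n")
  invisible(x)
}

# stratified case-cluster resample indices: positions into the positive and
# negative case vectors, sizes preserved so prevalence is constant
strat_indices <- function(n_pos, n_neg) {
  list(pos = sample.int(n_pos, n_pos, replace = TRUE),
       neg = sample.int(n_neg, n_neg, replace = TRUE))
}

# run B stratified-bootstrap replicates of stat(idx); stat must raise a
# g4family_undefined_error on a degenerate replicate, which triggers a
# redraw (counted; aborts past 1% of B)
run_bootstrap <- function(B, n_pos, n_neg, stat) {
  reps <- numeric(B)
  redraws <- 0L
  max_redraws <- max(1L, ceiling(0.01 * B))
  for (b in seq_len(B)) {
    repeat {
      val <- tryCatch(stat(strat_indices(n_pos, n_neg)),
                      g4family_undefined_error = function(e) NULL)
      if (!is.null(val)) break
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("more than 1% of bootstrap replicates were degenerate ",
             "(undefined metric); the data are too sparse for this metric",
             call. = FALSE)
    }
    reps[b] <- val
  }
  list(reps = reps, redraws = redraws)
}

#' Stratified clustered bootstrap CI for a standalone MRMC metric
#'
#' Cases are resampled with replacement independently within the positive
#' and negative truth strata (stratum sizes preserved, so every replicate
#' has exactly the original prevalence). A resampled case is a cluster: it
#' carries all its readers' ratings, and replicate-local duplicates count as
#' distinct observations. The metric is computed on each replicate's
#' reader-average confusion matrix; the CI is the percentile interval.
#' Replicates on which the metric is undefined are redrawn and counted; the
#' run aborts if more than 1% of `B` need redrawing.
#'
#' @param t An [mrmc_table()].
#' @param modality Modality id.
#' @param metric Metric name (`"g4"`, `"p4"`, `"mcc_scaled"`, or any
#'   [zoo_metrics()] key) or a function of a confusion matrix.
#' @param B Number of bootstrap replicates (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed (default `NULL`: current RNG stream).
#' @return A `bootstrap_result` with the plug-in point estimate, percentile
#'   CI bounds, `B`, seed, redraw count and the replicate values.
#' @export
bootstrap_metric_ci <- function(t, modality, metric = "g4", B = 2000L,
                                level = 0.95, seed = NULL) {
  stopifnot(inherits(t, "mrmc_table"))
  f <- resolve_metric(metric)
  if (!is.null(seed)) set.seed(seed)
  pr <- case_posrate(t, modality)
  a_pos <- pr$posrate[pr$truth == 1L]
  a_neg <- pr$posrate[pr$truth == 0L]
  if (length(a_pos) == 0L || length(a_neg) == 0L)
    stop("both truth strata must be non-empty", call. = FALSE)
  est <- f(posrate_cm(pr$truth, pr$posrate))
  stat <- function(idx) {
    cm <- confusion_matrix(tp = sum(a_pos[idx$pos]),
                           fp = sum(a_neg[idx$neg]),
                           fn = sum(1 - a_pos[idx$pos]),
                           tn = sum(1 - a_neg[idx$neg]))
    f(cm)
  }
  bs <- run_bootstrap(B, length(a_pos), length(a_neg), stat)
  bootstrap_result(est, bs$reps, level, seed, mode = "standalone",
                   redraws = bs$redraws,
                   metric = if (is.character(metric)) metric else "custom")
}

#' Stratified clustered bootstrap CI for a between-modality difference
#'
#' Replicate difference is `metric(modality_a) - metric(modality_b)` on the
#' replicates' reader-average matrices. In `"crossed"` mode one shared case
#' resample is applied to both modalities (appropriate when the same cases
#' were read under both, preserving the between-modality correlation); in
#' `"nested"` mode each modality's case clusters are resampled
#' independently, which ignores that correlation and tends to give wider,
#' more conservative intervals.
#'
#' @inheritParams bootstrap_metric_ci
#' @param modality_a,modality_b The two modality ids; the difference is
#'   a minus b.
#' @param mode `"crossed"` (shared resample) or `"nested"` (independent).
#' @return A `bootstrap_result` for the difference.
#' @export
bootstrap_difference_ci <- function(t, modality_a, modality_b, metric = "g4",
                                    B = 2000L, level = 0.95, seed = NULL,
                                    mode = c("crossed", "nested")) {
  stopifnot(inherits(t, "mrmc_table"))
  mode <- match.arg(mode)
  f <- resolve_metric(metric)
  if (!is.null(seed)) set.seed(seed)
  pa <- case_posrate(t, modality_a)
  pb <- case_posrate(t, modality_b)
  if (mode == "crossed" &&
      (!identical(pa$case, pb$case) || !identical(pa$truth, pb$truth)))
    stop("crossed mode requires both modalities to share the same case set",
         call. = FALSE)
  split_a <- list(pos = pa$posrate[pa$truth == 1L],
                  neg = pa$posrate[pa$truth == 0L])
  split_b <- list(pos = pb$posrate[pb$truth == 1L],
                  neg = pb$posrate[pb$truth == 0L])
  cm_from <- function(s, idx)
    confusion_matrix(tp = sum(s$pos[idx$pos]), fp = sum(s$neg[idx$neg]),
                     fn = sum(1 - s$pos[idx$pos]),
                     tn = sum(1 - s$neg[idx$neg]))
  est <- f(posrate_cm(pa$truth, pa$posrate)) -
    f(posrate_cm(pb$truth, pb$posrate))
  if (mode == "crossed") {
    stat <- function(idx) f(cm_from(split_a, idx)) - f(cm_from(split_b, idx))
    bs <- run_bootstrap(B, length(split_a$pos), length(split_a$neg), stat)
  } else {
    stat <- function(idx) {
      idx_b <- strat_indices(length(split_b$pos), length(split_b$neg))
      f(cm_from(split_a, idx)) - f(cm_from(split_b, idx_b))
    }
    bs <- run_bootstrap(B, length(split_a$pos), length(split_a$neg), stat)
  }
  bootstrap_result(est, bs$reps, level, seed, mode = mode,
                   redraws = bs$redraws,
                   metric = if (is.character(metric)) metric else "custom")
}

#' Generate a synthetic crossed MRMC ratings table
#'
#' Emulates a reader study with rare-prevalence binary truth, heterogeneous
#' readers and two modalities differing in discrimination. Case truth uses
#' fixed class sizes (`round(n_cases * prevalence)` positives). Each reader
#' draws a personal AUROC from a normal truncated to \[0.51, 0.99\];
#' modality 2 shifts every reader's AUROC by `modality_delta`. Scores follow
#' a shared-latent binormal model: a case component (variance 1/2, common to
#' all readers and both modalities, inducing the case-cluster correlation
#' the bootstrap exists for) plus independent reader noise (variance 1/2),
#' shifted by half the reader's Cohen's D per class. Scores are binned into
#' `rating_levels` ordinal ratings at standard-normal quantile edges
#' `qnorm(k / L)`; with even `L` the middle edge is 0, so a rating of
#' `L/2 + 1` or more corresponds exactly to a probability above 50%.
#'
#' Defaults mirror a breast-cancer reader study: 663 cases at prevalence
#' 0.074, 10 readers near AUROC 0.93, a 1-6 rating scale cut at 4.
#'
#' @param n_cases Number of cases (default 663).
#' @param prevalence Positive-class prevalence (default 0.074).
#' @param n_readers Number of readers (default 10).
#' @param reader_auroc_mean,reader_auroc_sd Mean and SD of the per-reader
#'   AUROC distribution (defaults 0.93 and 0.02).
#' @param modality_delta AUROC shift of modality 2 relative to modality 1
#'   (default 0.03).
#' @param rating_levels Number of ordinal rating levels (default 6; even
#'   values keep the middle bin edge at the 50% operating point).
#' @param seed Integer seed.
#' @return An [mrmc_table()] with modalities `1` and `2`, positivity rule
#'   `rating >= rating_levels / 2 + 1`.
#' @export
generate_synthetic_mrmc <- function(n_cases = 663L, prevalence = 0.074,
                                    n_readers = 10L,
                                    reader_auroc_mean = 0.93,
                                    reader_auroc_sd = 0.02,
                                    modality_delta = 0.03,
                                    rating_levels = 6L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_pos <- round(n_cases * prevalence)
  if (n_pos < 1 || n_cases - n_pos < 1)
    stop("degenerate class sizes", call. = FALSE)
  if (rating_levels < 2) stop("need at least 2 rating levels", call. = FALSE)
  clamp <- function(x) pmin(pmax(x, 0.51), 0.99)
  auroc_r <- clamp(stats::rnorm(n_readers, reader_auroc_mean, reader_auroc_sd))
  truth <- c(rep(1L, n_pos), rep(0L, n_cases - n_pos))
  latent <- stats::rnorm(n_cases, sd = sqrt(0.5))
  edges <- stats::qnorm(seq_len(rating_levels - 1) / rating_levels)
  rows <- vector("list", 2L * n_readers)
  k <- 0L
  for (m in 1:2) {
    a_m <- clamp(auroc_r + (m == 2) * modality_delta)
    for (r in seq_len(n_readers)) {
      d <- auroc_to_cohens_d(a_m[r])
      x <- latent + stats::rnorm(n_cases, sd = sqrt(0.5)) +
        ifelse(truth == 1L, d / 2, -d / 2)
      k <- k + 1L
      rows[[k]] <- data.frame(modality = m, reader = r,
                              case = seq_len(n_cases), truth = truth,
                              rating = findInterval(x, edges) + 1L)
    }
  }
  mrmc_table(do.call(rbind, rows),
             positive_cut = floor(rating_levels / 2) + 1L)
}
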