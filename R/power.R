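#' Power configuration for G4 benchmark tests
#'
#' @param true_auroc True underlying AUROC of the simulated classifier.
#' @param prevalence Positive-class prevalence.
#' @param n_cases Study size (total cases).
#' @param benchmark Benchmark the metric must exceed (e.g. from
#'   [rule_of_thumb()]).
#' @param alpha One-sided significance level (default 0.05).
#' @param n_replicates Simulated studies per power estimate (default 200).
#' @param B_inner Bootstrap replicates inside each simulated study (default
#'   500; power studies tolerate coarser CIs than a single analysis would).
#' @param metric Metric under test (default `"g4"`).
#' @param threshold Probability threshold for dichotomization (default 0.5).
#' @param two_sided If `TRUE`, test with the lower bound of the two-sided
#'   `1 - alpha` interval instead of the one-sided `alpha` quantile.
#' @param seed Integer seed.
#' @return A `power_config` list.
#' @export
power_config <- function(true_auroc, prevalence, n_cases, benchmark,
                         alpha = 0.05, n_replicates = 200L, B_inner = 500L,
                         metric = "g4", threshold = 0.5, two_sided = FALSE,
                         seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, benchmark > 0, benchmark < 1)
  cfg <- simulation_config(true_auroc, prevalence, n_cases,
                           threshold = threshold)  # validates the regime
  structure(list(true_auroc = true_auroc, prevalence = prevalence,
                 n_cases = as.integer(n_cases), benchmark = benchmark,
                 alpha = alpha, n_replicates = as.integer(n_replicates),
                 B_inner = as.integer(B_inner), metric = metric,
                 threshold = cfg$threshold, two_sided = isTRUE(two_sided),
                 seed = seed),
            class = "power_config")
}

# one simulated study: binormal scores -> binary calls at the threshold ->
# stratified case bootstrap of the metric -> lower confidence bound
study_lower_bound <- function(cfg, f) {
  sim <- simulate_scoreset(simulation_config(cfg$true_auroc, cfg$prevalence,
                                             cfg$n_cases,
                                             threshold = cfg$threshold))
  pred <- as.numeric(sim$score > cfg$threshold)
  a_pos <- pred[sim$truth == 1L]
  a_neg <- pred[sim$truth == 0L]
  stat <- function(idx)
    f(confusion_matrix(tp = sum(a_pos[idx$pos]), fp = sum(a_neg[idx$neg]),
                       fn = sum(1 - a_pos[idx$pos]),
                       tn = sum(1 - a_neg[idx$neg])))
  bs <- run_bootstrap(cfg$B_inner, length(a_pos), length(a_neg), stat)
  q <- if (cfg$two_sided) cfg$alpha / 2 else cfg$alpha
  stats::quantile(bs$reps, q, names = FALSE)
}

#' Simulation-based power of a G4 benchmark test
#'
#' Estimates the probability that a study of `n_cases` cases, analyzed with
#' a stratified case-resampling bootstrap, rejects "metric <= benchmark":
#' i.e. the fraction of simulated studies whose one-sided lower confidence
#' bound exceeds the benchmark. The binormal engine generates each study at
#' the configured AUROC and prevalence. The companion Monte-Carlo standard
#' error `sqrt(p (1 - p) / n_replicates)` is reported alongside.
#'
#' @param cfg A [power_config()].
#' @return Named list: `power`, `mc_se`, `n_cases`, `alpha`, `benchmark`,
#'   `n_replicates`, `seed`.
#' @examples
#' \donttest{
#' cfg <- power_config(0.9, 0.3, 200, benchmark = 0.6, n_replicates = 50,
#'                     B_inner = 200, seed = 7)
#' estimate_power(cfg)
#' }
#' @export
estimate_power <- function(cfg) {
  stopifnot(inherits(cfg, "power_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  f <- resolve_metric(cfg$metric)
  rejections <- vapply(seq_len(cfg$n_replicates), function(i)
    study_lower_bound(cfg, f) > cfg$benchmark, logical(1))
  p <- mean(rejections)
  list(power = p, mc_se = sqrt(p * (1 - p) / cfg$n_replicates),
       n_cases = cfg$n_cases, alpha = cfg$alpha, benchmark = cfg$benchmark,
       n_replicates = cfg$n_replicates, seed = cfg$seed)
}

#' Smallest study size reaching a target power
#'
#' Doubles `n` from `n_start` until the estimated power reaches
#' `target_power`, then bisects down to the smallest such `n`. Because each
#' power estimate is Monte Carlo, the returned `n` carries the estimate's
#' uncertainty; the search trace is returned for inspection.
#'
#' @param cfg A [power_config()] whose `n_cases` is ignored.
#' @param target_power Target power in (`alpha`, 1).
#' @param n_start Starting study size (default 50).
#' @param n_cap Give up beyond this size (default 16000).
#' @return Named list: `n` (smallest size whose estimated power meets the
#'   target), `power_at_n`, and `trace` (data frame of evaluated sizes).
#' @export
required_n <- function(cfg, target_power, n_start = 50L, n_cap = 16000L) {
  stopifnot(inherits(cfg, "power_config"),
            target_power > cfg$alpha, target_power < 1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  base_seed <- if (is.null(cfg$seed)) NULL else cfg$seed
  eval_at <- function(n) {
    c2 <- cfg
    c2$n_cases <- as.integer(n)
    c2$seed <- NULL  # flow from the outer stream, already seeded
    estimate_power(c2)$power
  }
  trace <- data.frame(n = integer(), power = numeric())
  n <- as.integer(n_start)
  p <- eval_at(n)
  trace <- rbind(trace, data.frame(n = n, power = p))
  lo <- NA_integer_
  while (p < target_power) {
    lo <- n
    n <- n * 2L
    if (n > n_cap)
      stop("target power unreachable within n_cap = ", n_cap, call. = FALSE)
    p <- eval_at(n)
    trace <- rbind(trace, data.frame(n = n, power = p))
  }
  hi <- n
  p_hi <- p
  # bisect (lo fails, hi passes); if the first n already passed, keep it
  while (!is.na(lo) && hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    pm <- eval_at(mid)
    trace <- rbind(trace, data.frame(n = mid, power = pm))
    if (pm >= target_power) { hi <- mid; p_hi <- pm } else lo <- mid
  }
  list(n = hi, power_at_n = p_hi, trace = trace, seed = base_seed)
}
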