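#' Convert a nominal AUROC to Cohen's D under the binormal model
#'
#' Evaluates, exactly as written, the three-step conversion
#' \deqn{t = \sqrt{\ln(1 / (1 - AUROC)^2)}}
#' \deqn{z = t - \frac{2.515517 + 0.802853 t + 0.0103328 t^2}
#'                    {1 + 1.432788 t + 0.189269 t^2 + 0.001308 t^3}}
#' \deqn{D = z \sqrt{2}}
#' where the middle step is the classic rational approximation to the
#' standard-normal quantile (absolute error < 4.5e-4), so that
#' `D ~ sqrt(2) * qnorm(auroc)`. D is the separation, in standard
#' deviations, between the two class-conditional score distributions that
#' yields the requested AUROC via `pnorm(D / sqrt(2))`.
#'
#' @param auroc Nominal AUROC in \[0.5, 1). 1 is excluded (t diverges).
#' @return Cohen's D (non-negative real, up to the approximation's error
#'   near 0.5).
#' @examples
#' auroc_to_cohens_d(0.8)  # ~1.190
#' @export
auroc_to_cohens_d <- function(auroc) {
  if (!is.numeric(auroc) || length(auroc) != 1L || is.na(auroc))
    stop("auroc must be a single number", call. = FALSE)
  if (auroc < 0.5 || auroc >= 1)
    stop("auroc must lie in [0.5, 1); 1 is a limit the conversion ",
         "cannot represent", call. = FALSE)
  t <- sqrt(log(1 / (1 - auroc)^2))
  z <- t - (2.515517 + 0.802853 * t + 0.0103328 * t^2) /
    (1 + 1.432788 * t + 0.189269 * t^2 + 0.001308 * t^3)
  z * sqrt(2)
}

#' Simulation configuration for the binormal score generator
#'
#' @param nominal_auroc Target AUROC in \[0.5, 1).
#' @param prevalence Minority (positive) class prevalence in (0, 1).
#' @param n Total number of simulated cases; `round(n * prevalence)` and its
#'   complement must both be at least 1.
#' @param threshold Probability threshold for downstream dichotomization
#'   (default 0.5, which corresponds to raw score 0).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(nominal_auroc, prevalence, n,
                              threshold = 0.5, seed = NULL) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  n_pos <- round(n * prevalence)
  if (n_pos < 1 || n - n_pos < 1)
    stop("class sizes degenerate: round(n * prevalence) and its complement ",
         "must both be >= 1", call. = FALSE)
  if (nominal_auroc < 0.5 || nominal_auroc >= 1)
    stop("nominal_auroc must lie in [0.5, 1)", call. = FALSE)
  structure(list(nominal_auroc = nominal_auroc, prevalence = prevalence,
                 n = as.integer(n), threshold = threshold, seed = seed),
            class = "simulation_config")
}

#' Simulate a binormal score set
#'
#' Draws exactly `round(n * prevalence)` positive cases from N(+D/2, 1) and
#' the remainder from N(-D/2, 1), with D from [auroc_to_cohens_d()], then
#' maps the raw scores onto (0, 1) through the logistic CDF `plogis` — a
#' fixed strictly increasing map (so AUROC is untouched) whose midpoint
#' sends raw 0 to probability 0.5, making the 50% probability threshold
#' equal to the binormal midpoint.
#'
#' @param cfg A [simulation_config()].
#' @return A [score_set()] with probabilities in (0, 1).
#' @examples
#' s <- simulate_scoreset(simulation_config(0.8, 0.5, 2000, seed = 1))
#' auroc_trapezoid(s)  # near 0.8
#' @export
simulate_scoreset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  d <- auroc_to_cohens_d(cfg$nominal_auroc)
  n_pos <- round(cfg$n * cfg$prevalence)
  n_neg <- cfg$n - n_pos
  raw <- c(stats::rnorm(n_pos, mean = d / 2), stats::rnorm(n_neg, mean = -d / 2))
  score_set(stats::plogis(raw), c(rep(1L, n_pos), rep(0L, n_neg)))
}

#' Tabulate balanced-family benchmarks against AUROC
#'
#' For every (AUROC, prevalence) cell, repeatedly simulates a binormal score
#' set, dichotomizes it at the probability threshold, computes G4, P4 and
#' scaled MCC on the resulting confusion matrix, and stores the mean over
#' replicates. The observed bias at the threshold is recorded per cell
#' rather than forced to equal the prevalence.
#'
#' @param aurocs,prevalences Grid axes (each within the respective domain).
#' @param n Cases per simulated dataset (default 10000).
#' @param replicates Simulation replicates per cell (default 20).
#' @param threshold Probability threshold (default 0.5).
#' @param seed Integer seed for the whole grid.
#' @return A `benchmark_grid`: data frame with columns `metric`, `auroc`,
#'   `prevalence`, `value`, `bias`, plus attributes `replicates`, `seed`,
#'   `n`.
#' @export
benchmark_grid <- function(aurocs, prevalences, n = 10000L, replicates = 20L,
                           threshold = 0.5, seed = 1L) {
  stopifnot(all(aurocs >= 0.5 & aurocs < 1),
            all(prevalences > 0 & prevalences < 1),
            replicates >= 1)
  set.seed(seed)
  grid <- expand.grid(prevalence = prevalences, auroc = aurocs,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- simulation_config(grid$auroc[i], grid$prevalence[i], n,
                             threshold = threshold)
    acc <- matrix(NA_real_, nrow = replicates, ncol = 3)
    bias <- numeric(replicates)
    for (r in seq_len(replicates)) {
      cm <- threshold_classify(simulate_scoreset(cfg), threshold)
      acc[r, ] <- balanced_family(cm)
      bias[r] <- prevalence_bias(cm)[["bias"]]
    }
    data.frame(metric = c("g4", "p4", "mcc_scaled"),
               auroc = grid$auroc[i], prevalence = grid$prevalence[i],
               value = colMeans(acc), bias = mean(bias))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("benchmark_grid", "data.frame"),
            replicates = as.integer(replicates), seed = as.integer(seed),
            n = as.integer(n))
}

#' Look up a benchmark value by bilinear interpolation
#'
#' Exact at grid nodes; queries outside the grid's hull are refused rather
#' than extrapolated.
#'
#' @param grid A [benchmark_grid()].
#' @param metric One of `"g4"`, `"p4"`, `"mcc_scaled"`.
#' @param auroc,prevalence Query point, inside the grid hull.
#' @return Interpolated benchmark value.
#' @export
benchmark_lookup <- function(grid, metric, auroc, prevalence) {
  stopifnot(inherits(grid, "benchmark_grid"))
  sub <- grid[grid$metric == metric, ]
  if (nrow(sub) == 0) stop("metric not in grid: ", metric, call. = FALSE)
  ax <- sort(unique(sub$auroc))
  px <- sort(unique(sub$prevalence))
  if (auroc < min(ax) || auroc > max(ax) ||
      prevalence < min(px) || prevalence > max(px))
    stop("query outside the grid hull; refusing to extrapolate",
         call. = FALSE)
  bracket <- function(axis, v) {
    if (length(axis) == 1L) return(c(axis, axis))
    i <- min(max(findInterval(v, axis), 1L), length(axis) - 1L)
    axis[c(i, i + 1L)]
  }
  a01 <- bracket(ax, auroc)
  p01 <- bracket(px, prevalence)
  val <- function(a, p) sub$value[sub$auroc == a & sub$prevalence == p][1]
  wa <- if (a01[2] > a01[1]) (auroc - a01[1]) / (a01[2] - a01[1]) else 0
  wp <- if (p01[2] > p01[1]) (prevalence - p01[1]) / (p01[2] - p01[1]) else 0
  (1 - wa) * ((1 - wp) * val(a01[1], p01[1]) + wp * val(a01[1], p01[2])) +
    wa * ((1 - wp) * val(a01[2], p01[1]) + wp * val(a01[2], p01[2]))
}

#' Rule-of-thumb benchmark for good classification performance
#'
#' Returns the benchmark a balanced-family metric should exceed to claim
#' good performance or better: 0.70 when the minority-class prevalence is
#' common (> 30%), 0.60 when uncommon (10%-30% inclusive), 0.50 when rare
#' (< 10%). Prevalences above 0.5 are folded to the minority class.
#'
#' @param prevalence Prevalence in (0, 1).
#' @return 0.70, 0.60 or 0.50.
#' @examples
#' rule_of_thumb(0.074)  # rare disease -> 0.50
#' @export
rule_of_thumb <- function(prevalence) {
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  p <- ifelse(prevalence > 0.5, 1 - prevalence, prevalence)
  ifelse(p > 0.30, 0.70, ifelse(p >= 0.10, 0.60, 0.50))
}
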