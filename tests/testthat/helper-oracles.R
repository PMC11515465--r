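# Independent oracles kept deliberately separate from the package's own
# computation paths.

# Mann-Whitney rank statistic U / (n+ * n-), ties counted half: the exact
# probabilistic definition of AUROC.
oracle_rank_auroc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# count-based Pearson form of MCC, written out longhand
oracle_mcc_counts <- function(tp, fp, fn, tn) {
  (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
}

# random confusion matrix with all four marginals positive
rand_cm_counts <- function() {
  repeat {
    cells <- stats::rpois(4, lambda = sample(c(3, 10, 40), 1)) +
      stats::rbinom(4, 1, 0.5)
    tp <- cells[1]; fp <- cells[2]; fn <- cells[3]; tn <- cells[4]
    if ((tp + fp) > 0 && (tp + fn) > 0 && (tn + fp) > 0 && (tn + fn) > 0)
      return(c(tp = tp, fp = fp, fn = fn, tn = tn))
  }
}

# empirical rank-oracle AUROC of one simulated score set
oracle_rank_auroc_of_sim <- function(nominal, n, seed) {
  s <- simulate_scoreset(simulation_config(nominal, 0.5, n, seed = seed))
  oracle_rank_auroc(s$score, s$truth)
}

# expected reader-average confusion matrix of the synthetic MRMC generator
# at reader sd 0: binormal with unit-variance scores and midpoint cut, so
# TPR = TNR = pnorm(D / 2) with D = sqrt(2) * qnorm(auroc)
oracle_true_family <- function(auroc, n_pos, n_neg) {
  phi <- stats::pnorm(sqrt(2) * stats::qnorm(auroc) / 2)
  cm <- confusion_matrix(tp = n_pos * phi, fp = n_neg * (1 - phi),
                         fn = n_pos * (1 - phi), tn = n_neg * phi)
  balanced_family(cm)
}
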