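# Independent oracles used to cross-check the package's implementations.

# AUC by brute-force pair counting over all (positive, negative) pairs.
auc_paircount <- function(y, scores) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins.
fisher_enum <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small deterministic cohort used by several module tests.
make_test_cohort <- function(seed = 42, n = 200, npos = 40, ...) {
  generate_cohort(cohort_config(n_subjects = n, n_positives = npos,
                                seed = seed, ...))
}

# A fabricated prediction-distribution tibble (for gate/routing tests).
make_dist <- function(mu, s) {
  out <- tibble::tibble(.row = seq_along(mu), mu = mu, s = s)
  class(out) <- c("prediction_distribution", class(out))
  out
}

# pROC ROC object with fixed orientation (no auto direction flipping).
proc_roc <- function(y, s) {
  pROC::roc(y, s, quiet = TRUE, direction = "<", levels = c(0, 1))
}
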