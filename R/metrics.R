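#' Area under the ROC curve (Mann–Whitney form)
#'
#' Equals the probability that a random positive outscores a random
#' negative, counting ties as 1/2 — computed from average ranks.
#'
#' @param y Binary 0/1 outcome with both classes present.
#' @param scores Numeric scores (higher = more positive).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(y, scores) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("data error: y contains a single class", call. = FALSE)
  stopifnot(length(y) == length(scores))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a probability cutoff
#'
#' A prediction is positive iff `probability > cutoff`. If a class is
#' absent from `y`, the corresponding rate is returned as `NA` (flagged
#' missing, not 0).
#'
#' @param y Binary 0/1 outcome.
#' @param probabilities Predicted probabilities.
#' @param cutoff Decision cutoff (default 0.5, the scale's midpoint).
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`.
#' @export
binary_metrics <- function(y, probabilities, cutoff = 0.5) {
  y <- as.integer(y)
  pred <- as.integer(probabilities > cutoff)
  tibble::tibble(
    accuracy = mean(pred == y),
    sensitivity = if (any(y == 1)) mean(pred[y == 1] == 1) else NA_real_,
    specificity = if (any(y == 0)) mean(pred[y == 0] == 0) else NA_real_
  )
}

# DeLong structural components: placement values of each positive against
# all negatives (V10) and vice versa (V01), with ties counted 1/2.
delong_components <- function(y, scores) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("data error: y contains a single class", call. = FALSE)
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi), m = m, n = n)
}

delong_var <- function(comp) {
  s10 <- if (comp$m > 1) stats::var(comp$v10) else 0
  s01 <- if (comp$n > 1) stats::var(comp$v01) else 0
  s10 / comp$m + s01 / comp$n
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors on the same samples via the
#' structural-components (placement-value) estimator of the variance of
#' the AUC difference, followed by a two-sided z-test. Identical scores
#' (zero difference with zero variance) give p = 1 by convention.
#'
#' @param y Binary 0/1 outcome (both classes present).
#' @param scores1,scores2 Paired score vectors.
#' @return One-row tibble: `auc1`, `auc2`, `z`, `p_value`.
#' @export
delong_test <- function(y, scores1, scores2) {
  y <- as.integer(y)
  stopifnot(length(scores1) == length(y), length(scores2) == length(y))
  c1 <- delong_components(y, scores1)
  c2 <- delong_components(y, scores2)
  cov10 <- if (c1$m > 1) stats::cov(c1$v10, c2$v10) else 0
  cov01 <- if (c1$n > 1) stats::cov(c1$v01, c2$v01) else 0
  var_diff <- delong_var(c1) + delong_var(c2) - 2 * (cov10 / c1$m + cov01 / c1$n)
  d <- c1$auc - c2$auc
  if (var_diff <= .Machine$double.eps) {
    if (abs(d) <= .Machine$double.eps) {
      return(tibble::tibble(auc1 = c1$auc, auc2 = c2$auc, z = 0, p_value = 1))
    }
    stop("degenerate-variance error: AUCs differ but the DeLong variance is zero",
         call. = FALSE)
  }
  z <- d / sqrt(var_diff)
  tibble::tibble(auc1 = c1$auc, auc2 = c2$auc, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)))
}

#' DeLong confidence interval for one AUC
#'
#' `AUC +- z * SE` with the structural-components standard error,
#' truncated to [0, 1]. Constant scores carry no ranking information and
#' raise a degenerate-variance error; a perfect classifier (SE 0 with a
#' well-defined AUC) yields a zero-width interval.
#'
#' @param y Binary 0/1 outcome.
#' @param scores Numeric scores.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `auc`, `lower`, `upper`, `se`.
#' @export
delong_ci <- function(y, scores, level = 0.95) {
  y <- as.integer(y)
  if (stats::sd(scores) == 0) {
    stop("degenerate-variance error: constant scores", call. = FALSE)
  }
  comp <- delong_components(y, scores)
  se <- sqrt(delong_var(comp))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(auc = comp$auc,
                 lower = max(0, comp$auc - zq * se),
                 upper = min(1, comp$auc + zq * se),
                 se = se)
}

#' McNemar tests on sensitivity and specificity
#'
#' Paired comparison of two classifiers' class predictions: among
#' true-positive-labeled samples (sensitivity) and true-negative-labeled
#' samples (specificity) separately, the discordant counts (model A
#' uniquely correct vs model B uniquely correct) are tested with the exact
#' binomial McNemar test when fewer than 25 pairs are discordant, and the
#' continuity-corrected chi-square test otherwise. No discordance gives
#' p = 1 (defined, not an error).
#'
#' @param y Binary 0/1 outcome.
#' @param pred1,pred2 Paired 0/1 class predictions.
#' @return Tibble with rows `sensitivity` and `specificity`: discordant
#'   counts `b` (model 1 uniquely correct), `c` (model 2 uniquely
#'   correct), `method`, `p_value`.
#' @export
mcnemar_sens_spec <- function(y, pred1, pred2) {
  y <- as.integer(y); pred1 <- as.integer(pred1); pred2 <- as.integer(pred2)
  stopifnot(length(pred1) == length(y), length(pred2) == length(y))
  one <- function(idx) {
    ok1 <- pred1[idx] == y[idx]; ok2 <- pred2[idx] == y[idx]
    b <- sum(ok1 & !ok2); c_ <- sum(!ok1 & ok2)
    if (b + c_ == 0) return(list(b = b, c = c_, method = "none", p = 1))
    if (b + c_ < 25) {
      list(b = b, c = c_, method = "exact",
           p = stats::binom.test(b, b + c_, 0.5)$p.value)
    } else {
      stat <- (abs(b - c_) - 1)^2 / (b + c_)
      list(b = b, c = c_, method = "chi-square",
           p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
    }
  }
  rs <- list(sensitivity = one(which(y == 1)), specificity = one(which(y == 0)))
  tibble::tibble(metric = names(rs),
                 b = unname(purrr::map_int(rs, ~ as.integer(.x$b))),
                 c = unname(purrr::map_int(rs, ~ as.integer(.x$c))),
                 method = unname(purrr::map_chr(rs, "method")),
                 p_value = unname(purrr::map_dbl(rs, "p")))
}

#' AUC across uncertainty percentiles
#'
#' For each percentile q of the uncertainty s, restricts the sample to
#' subjects with `s >= quantile(s, q/100)` — an increasingly uncertain
#' subset — and reports the AUC with its DeLong confidence interval.
#' Subsets that lose one outcome class (or have constant scores) are
#' emitted with missing values rather than dropped.
#'
#' @param y Binary 0/1 outcome.
#' @param dist A [predict_distribution()] tibble (`mu`, `s`).
#' @param percentiles Grid within [0, 100); default `seq(0, 90, 10)`.
#' @param level Confidence level for the DeLong interval.
#' @return Tibble: `percentile`, `n`, `auc`, `lower`, `upper`.
#' @export
uncertainty_percentile_auc <- function(y, dist, percentiles = seq(0, 90, 10),
                                       level = 0.95) {
  stopifnot(all(percentiles >= 0 & percentiles < 100))
  y <- as.integer(y)
  purrr::map_dfr(percentiles, function(q) {
    thr <- stats::quantile(dist$s, q / 100, names = FALSE)
    idx <- which(dist$s >= thr)
    if (length(idx) < 2 || length(unique(y[idx])) < 2) {
      return(tibble::tibble(percentile = q, n = length(idx), auc = NA_real_,
                            lower = NA_real_, upper = NA_real_))
    }
    auc <- roc_auc(y[idx], dist$mu[idx])
    ci <- tryCatch(delong_ci(y[idx], dist$mu[idx], level),
                   error = function(e) tibble::tibble(lower = NA_real_,
                                                      upper = NA_real_))
    tibble::tibble(percentile = q, n = length(idx), auc = auc,
                   lower = ci$lower, upper = ci$upper)
  })
}

# ROC curve coordinates (step function vertices), for plotting/export.
roc_points <- function(y, scores) {
  y <- as.integer(y)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  # collapse tied score runs to their last point
  last <- rev(!duplicated(rev(scores[o])))
  tibble::tibble(fpr = c(0, fp[last] / sum(y == 0)),
                 tpr = c(0, tp[last] / sum(y == 1)))
}

# TPR of an ROC step curve interpolated at given FPR grid points.
roc_interpolate <- function(pts, fpr_grid) {
  stats::approx(pts$fpr, pts$tpr, xout = fpr_grid, method = "constant",
                ties = max, yleft = 0, yright = 1, rule = 2)$y
}
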