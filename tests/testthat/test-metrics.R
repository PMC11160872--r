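test_that("roc_auc equals the pair-counting oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1), c(0.7, 0.7)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "single class")
  for (i in 1:100) {
    set.seed(i)
    n <- sample(5:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))          # both classes guaranteed
    s <- round(runif(n), 1)                       # coarse grid forces ties
    expect_equal(roc_auc(y, s), auc_paircount(y, s))
  }
})

test_that("confusion-matrix metrics follow their definitions", {
  expect_equal(binary_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)),
               tibble::tibble(accuracy = 1, sensitivity = 1, specificity = 1))
  # all-negative predictions on a 94/547 cohort
  y <- c(rep(1, 94), rep(0, 453))
  m <- binary_metrics(y, rep(0, 547))
  expect_equal(m$accuracy, 453 / 547)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)
  # hand-counted instance
  mh <- binary_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(unlist(mh), c(accuracy = 0.5, sensitivity = 0.5, specificity = 0.5))
  # single-class labels: the undefined rate is missing, not zero
  ms <- binary_metrics(c(1, 1), c(0.9, 0.2))
  expect_true(is.na(ms$specificity))
  expect_equal(ms$sensitivity, 0.5)
})

test_that("DeLong test and CI match an independent implementation", {
  skip_if_not_installed("pROC")
  for (i in 1:20) {
    set.seed(100 + i)
    n <- 30
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s1 <- runif(n); s2 <- 0.5 * s1 + 0.5 * runif(n)
    ours <- delong_test(y, s1, s2)
    ref <- pROC::roc.test(proc_roc(y, s1),
                          proc_roc(y, s2), method = "delong")
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-9)
    # one-AUC variance against pROC's structural-components estimate
    expect_equal(stagedrisk:::delong_var(stagedrisk:::delong_components(y, s1)),
                 unname(pROC::var(proc_roc(y, s1), method = "delong")),
                 tolerance = 1e-9)
    ci <- delong_ci(y, s1)
    ref_ci <- pROC::ci.auc(proc_roc(y, s1), method = "delong")
    expect_equal(c(ci$lower, ci$auc, ci$upper), as.numeric(ref_ci),
                 tolerance = 1e-9)
  }
})

test_that("DeLong handles identical, degenerate and perfect scores", {
  set.seed(9)
  y <- rep(c(0, 1), 6)
  s <- runif(12)
  expect_equal(delong_test(y, s, s)$p_value, 1)
  # symmetry under swapping the models
  s2 <- runif(12)
  expect_equal(delong_test(y, s, s2)$p_value, delong_test(y, s2, s)$p_value)
  expect_error(delong_ci(y, rep(0.4, 12)), "degenerate")
  # perfect classifier on a finite set: zero-width interval at 1
  yp <- c(0, 0, 0, 1, 1, 1)
  ci <- delong_ci(yp, c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))
  expect_equal(ci$auc, 1)
  expect_equal(ci$upper, 1)
  expect_equal(ci$lower, 1)
})

test_that("McNemar tests use exact and corrected variants appropriately", {
  y <- c(rep(1, 20), rep(0, 20))
  pred <- as.integer(runif(40) > 0.5)
  same <- mcnemar_sens_spec(y, pred, pred)
  expect_equal(same$p_value, c(1, 1))

  # among positives: model A uniquely correct on 10, B never -> 2 * (1/2)^10
  y2 <- rep(1, 12)
  a <- c(rep(1, 10), 0, 0)      # correct on 10, wrong on 2
  b <- rep(0, 12)               # always wrong
  r <- mcnemar_sens_spec(c(y2, 0), c(a, 0), c(b, 0))   # pad one negative
  sens <- r[r$metric == "sensitivity", ]
  expect_equal(sens$b, 10L)
  expect_equal(sens$c, 0L)
  expect_equal(sens$p_value, 2 * (1 / 2)^10, tolerance = 1e-12)
  expect_equal(sens$method, "exact")

  # symmetric discordance (3, 3) among negatives -> p = 1
  y3 <- rep(0, 10)
  p1 <- c(rep(0, 3), rep(1, 3), rep(0, 4))
  p2 <- c(rep(1, 3), rep(0, 3), rep(0, 4))
  r3 <- mcnemar_sens_spec(c(y3, 1), c(p1, 1), c(p2, 1))
  spec <- r3[r3$metric == "specificity", ]
  expect_equal(spec$p_value, 1)

  # large discordance switches to the continuity-corrected chi-square
  y4 <- rep(1, 60)
  a4 <- c(rep(1, 40), rep(0, 20))
  b4 <- c(rep(0, 40), rep(1, 20))
  r4 <- mcnemar_sens_spec(c(y4, 0), c(a4, 0), c(b4, 0))
  s4 <- r4[r4$metric == "sensitivity", ]
  expect_equal(s4$method, "chi-square")
  expect_equal(s4$p_value,
               stats::pchisq((abs(40 - 20) - 1)^2 / 60, 1, lower.tail = FALSE))
})

test_that("uncertainty-percentile curve reduces to the full-sample AUC", {
  set.seed(12)
  y <- c(0, 1, rbinom(48, 1, 0.4))
  mu <- runif(50)
  full <- roc_auc(y, mu)
  d_equal <- make_dist(mu, rep(0.1, 50))
  cur <- uncertainty_percentile_auc(y, d_equal)
  expect_equal(cur$auc, rep(full, nrow(cur)))     # all s identical
  d_var <- make_dist(mu, runif(50))
  cur2 <- uncertainty_percentile_auc(y, d_var)
  expect_equal(cur2$auc[cur2$percentile == 0], full)
  expect_true(all(diff(cur2$n) <= 0))
  # subsets losing a class are emitted as missing, not dropped
  d_one <- make_dist(mu, c(rep(0, 49), 1))
  cur3 <- uncertainty_percentile_auc(y, d_one, percentiles = c(0, 99))
  expect_equal(cur3$n[cur3$percentile == 99], 1)
  expect_true(is.na(cur3$auc[cur3$percentile == 99]))
})
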