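test_that("a single full-sample model has zero uncertainty", {
  co <- make_test_cohort(seed = 21)
  X <- stage1_matrix(co); y <- cohort_labels(co)
  ens <- fit_ensemble(X, y, ensemble_config(n_base_models = 1, sample_fraction = 1,
                                            bootstrap = FALSE, seed = 1))
  d <- predict_distribution(ens, X)
  expect_true(all(d$s == 0))
  expect_true(all(d$mu >= 0 & d$mu <= 1))
})

test_that("fitting and prediction are deterministic under the seed", {
  co <- make_test_cohort(seed = 22)
  X <- stage1_matrix(co); y <- cohort_labels(co)
  cfg <- ensemble_config(n_base_models = 10, seed = 99)
  d1 <- predict_distribution(fit_ensemble(X, y, cfg), X)
  d2 <- predict_distribution(fit_ensemble(X, y, cfg), X)
  expect_identical(d1, d2)
})

test_that("bootstrap diversity produces strictly positive mean uncertainty", {
  co <- make_test_cohort(seed = 23)
  X <- cbind(stage1_matrix(co), stage2_matrix(co)); y <- cohort_labels(co)
  ens <- fit_ensemble(X, y, ensemble_config(n_base_models = 25,
                                            sample_fraction = 0.8, seed = 5))
  d <- predict_distribution(ens, X)
  expect_gt(mean(d$s), 0)
  # every base model trained on round(f * n) resampled rows
  expect_true(all(lengths(ens$draws) == round(0.8 * nrow(X))))
})

test_that("mu and s always satisfy their definitions on the stored B-vector", {
  co <- make_test_cohort(seed = 24)
  X <- stage1_matrix(co); y <- cohort_labels(co)
  d <- predict_distribution(fit_ensemble(X, y, ensemble_config(n_base_models = 7,
                                                               seed = 2)), X)
  P <- attr(d, "prob_matrix")
  expect_equal(dim(P), c(nrow(X), 7))
  expect_equal(d$mu, rowMeans(P), tolerance = 1e-12)
  expect_equal(d$s, apply(P, 1, stats::sd), tolerance = 1e-12)
  # two-point sanity: sd of {0.4, 0.6} is 0.1414...
  expect_equal(stats::sd(c(0.4, 0.6)), 0.1414, tolerance = 1e-3)
})

test_that("single-class training data is rejected", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_ensemble(X, rep(1L, 20), ensemble_config()), "single class")
})

test_that("feature importance averages |importance| and zeroes masked features", {
  co <- inject_degeneracies(make_test_cohort(seed = 25), n_duplicate = 1, seed = 4)
  X <- stage1_matrix(co); y <- cohort_labels(co)
  ens <- fit_ensemble(X, y, ensemble_config(n_base_models = 3, seed = 3))
  imp <- feature_importance(ens)
  expect_equal(imp$feature, colnames(X))
  removed <- !ens$pipe$mask$keep
  expect_true(any(removed))                       # the duplicate was filtered
  expect_true(all(imp$importance[removed] == 0))
  # mean of per-model absolute importances, recomputed independently
  learner <- stagedrisk:::get_learner("ridge")
  per_model <- sapply(ens$models, function(m) abs(learner$importance(m)))
  expect_equal(imp$importance[ens$pipe$mask$keep], unname(rowMeans(per_model)),
               tolerance = 1e-12)

  # B = 1 linear model: importance equals that model's |coefficients|
  e1 <- fit_ensemble(X, y, ensemble_config(n_base_models = 1, bootstrap = FALSE,
                                           seed = 1))
  i1 <- feature_importance(e1)
  expect_equal(i1$importance[e1$pipe$mask$keep],
               unname(abs(e1$models[[1]]$beta[-1])), tolerance = 1e-12)
})

test_that("uncertainty concentrates near the decision boundary", {
  wins <- 0
  for (sd in 1:20) {
    co <- generate_cohort(cohort_config(seed = sd))
    X <- cbind(stage1_matrix(co), stage2_matrix(co)); y <- cohort_labels(co)
    oz <- cohort_oracle(co)$z
    tr <- 1:400; te <- 401:547
    ens <- fit_ensemble(X[tr, ], y[tr], ensemble_config(seed = sd))
    d <- predict_distribution(ens, X[te, ])
    cut <- sort(oz, decreasing = TRUE)[94]        # label threshold on the latent
    dist_from_boundary <- abs(oz[te] - cut)
    q <- stats::quantile(dist_from_boundary, c(1 / 3, 2 / 3))
    wins <- wins + (mean(d$s[dist_from_boundary <= q[1]]) >
                      mean(d$s[dist_from_boundary >= q[2]]))
  }
  expect_gte(wins, 16)
})

test_that("more base models reduce the Monte-Carlo variance of mu", {
  co <- make_test_cohort(seed = 26, n = 300, npos = 60)
  X <- cbind(stage1_matrix(co), stage2_matrix(co)); y <- cohort_labels(co)
  tr <- 1:220; te <- 221:260
  mc_var <- function(B) {
    mus <- sapply(1:8, function(r) {
      predict_distribution(
        fit_ensemble(X[tr, ], y[tr],
                     ensemble_config(n_base_models = B, seed = 3000 + r)),
        X[te, ])$mu
    })
    mean(apply(mus, 1, stats::var))
  }
  expect_lt(mc_var(40), mc_var(5))
})

test_that("inner hyperparameter CV selects from the grid deterministically", {
  co <- make_test_cohort(seed = 27)
  X <- stage1_matrix(co); y <- cohort_labels(co)
  cfg <- ensemble_config(n_base_models = 3, seed = 8,
                         hyper_grid = list(list(lambda = 0.1), list(lambda = 10)))
  e1 <- fit_ensemble(X, y, cfg)
  e2 <- fit_ensemble(X, y, cfg)
  expect_true(e1$params$lambda %in% c(0.1, 10))
  expect_identical(e1$params, e2$params)
})
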