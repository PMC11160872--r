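test_that("the deferral rule retains only confident, decisive predictions", {
  thr <- staged_thresholds(0.05, 0.20)
  expect_equal(route(make_dist(0.95, 0.01), thr), "STAGE1")
  expect_equal(route(make_dist(0.50, 0.00), staged_thresholds(0.05, 0.01)), "STAGE2")
  expect_equal(route(make_dist(0.95, 0.30), thr), "STAGE2")
  # boundary: s equal to the threshold passes, |mu - 0.5| equal does not
  expect_equal(route(make_dist(0.8, 0.05), thr), "STAGE1")
  expect_equal(route(make_dist(0.70, 0.01), thr), "STAGE2")
  expect_error(staged_thresholds(-0.1, 0.2), "sigma_thr")
  expect_error(staged_thresholds(0.1, 0.7), "halfway_thr")
})

test_that("the STAGE1 set is monotone in both thresholds", {
  for (sd in 1:10) {
    set.seed(sd)
    d <- make_dist(runif(60), runif(60, 0, 0.3))
    sig <- sort(runif(4, 0, 0.3)); hws <- sort(runif(4, 0, 0.5))
    for (hw in hws) {
      sets <- lapply(sig, function(s) which(route(d, staged_thresholds(s, hw)) == "STAGE1"))
      for (i in seq_len(length(sets) - 1)) {
        expect_true(all(sets[[i]] %in% sets[[i + 1]]))   # grows with sigma_thr
      }
    }
    for (s in sig) {
      sets <- lapply(hws, function(hw) which(route(d, staged_thresholds(s, hw)) == "STAGE1"))
      for (i in seq_len(length(sets) - 1)) {
        expect_true(all(sets[[i + 1]] %in% sets[[i]]))   # shrinks with halfway_thr
      }
    }
  }
})

test_that("staged prediction honors the gate and the cost semantics", {
  co <- make_test_cohort(seed = 31, easy_fraction = 0.5)
  X1 <- stage1_matrix(co); X2 <- stage2_matrix(co); y <- cohort_labels(co)
  ens1 <- fit_ensemble(X1, y, ensemble_config(seed = 1))
  ens2 <- fit_ensemble(cbind(X1, X2), y, ensemble_config(seed = 2))
  d1 <- predict_distribution(ens1, X1)

  # permissive gate: everything retained (all |mu - 0.5| > 0 here)
  stopifnot(all(abs(d1$mu - 0.5) > 0))
  sp_all1 <- staged_predict(ens1, ens2, X1, X2, staged_thresholds(Inf, 0))
  expect_equal(attr(sp_all1, "stage2_rate"), 0)
  expect_equal(sp_all1$p_final, d1$mu)
  expect_equal(attr(sp_all1, "n_stage2_calls"), 0)

  # blocking gate: nothing can beat a halfway threshold of 0.5
  sp_all2 <- staged_predict(ens1, ens2, X1, X2, staged_thresholds(0, 0.5))
  expect_equal(attr(sp_all2, "stage2_rate"), 1)
  d2 <- predict_distribution(ens2, cbind(X1, X2))
  expect_equal(sp_all2$p_final, d2$mu)

  # mid-grid thresholds: strictly partial routing on an easy-rich cohort
  sp_mid <- staged_predict(ens1, ens2, X1, X2,
                           staged_thresholds(stats::median(d1$s), 0.1))
  expect_gt(attr(sp_mid, "stage2_rate"), 0)
  expect_lt(attr(sp_mid, "stage2_rate"), 1)

  # cost consistency: stage-2 base-model calls = B2 x cascaded rows
  n_casc <- sum(sp_mid$route == "STAGE2")
  expect_equal(attr(sp_mid, "n_stage2_calls"),
               ens2$config$n_base_models * n_casc)
  expect_true(all(is.na(sp_mid$mu2[sp_mid$route == "STAGE1"])))
  expect_equal(sp_mid$p_final[sp_mid$route == "STAGE1"],
               sp_mid$mu1[sp_mid$route == "STAGE1"])

  expect_error(staged_predict(ens1, ens2, X1, X2[-1, ], staged_thresholds(1, 0)),
               "row-aligned")
})

test_that("scaled weighted AUC is the size-weighted mean of subset AUCs", {
  y <- c(0, 0, 1, 1, 0, 1)
  p <- c(0.1, 0.2, 0.8, 0.9, 0.3, 0.7)
  all1 <- rep("STAGE1", 6); all2 <- rep("STAGE2", 6)
  expect_equal(scaled_weighted_auc(y, p, all1), roc_auc(y, p))
  expect_equal(scaled_weighted_auc(y, p, all2), roc_auc(y, p))
  # half/half with both subset AUCs 1 -> J = 1
  routes <- c("STAGE1", "STAGE1", "STAGE1", "STAGE2", "STAGE2", "STAGE2")
  expect_equal(scaled_weighted_auc(y, p, routes), 1)
  # single-class subset contributes its size at AUC 0.5
  y2 <- c(0, 0, 1, 1)
  r2 <- c("STAGE1", "STAGE1", "STAGE2", "STAGE2")
  p2 <- c(0.1, 0.2, 0.3, 0.9)
  expect_equal(scaled_weighted_auc(y2, p2, r2), 0.5)
  expect_error(scaled_weighted_auc(integer(0), numeric(0), character(0)), "empty")
})

test_that("threshold tuning maximizes the objective over the grid", {
  co <- make_test_cohort(seed = 32)
  X1 <- stage1_matrix(co); X2 <- stage2_matrix(co); y <- cohort_labels(co)
  ens1 <- fit_ensemble(X1, y, ensemble_config(seed = 1))
  ens2 <- fit_ensemble(cbind(X1, X2), y, ensemble_config(seed = 2))

  one <- tune_thresholds(ens1, ens2, X1, X2, y, sigma_grid = 0.07,
                         halfway_grid = 0.2)
  expect_equal(one$sigma_thr, 0.07)
  expect_equal(one$halfway_thr, 0.2)

  tuned <- tune_thresholds(ens1, ens2, X1, X2, y)
  trace <- attr(tuned, "trace")
  expect_true(all(c("sigma_thr", "halfway_thr", "objective", "retention") %in%
                    names(trace)))
  best <- trace$objective[trace$sigma_thr == tuned$sigma_thr &
                            trace$halfway_thr == tuned$halfway_thr]
  expect_equal(max(trace$objective), max(best))
  expect_error(tune_thresholds(ens1, ens2, X1, X2, rep(1, nrow(X1))), "single class")
})

test_that("tuning routes toward the informative stage", {
  run_case <- function(beta1, beta2, sd) {
    co <- generate_cohort(cohort_config(n_subjects = 300, n_positives = 60,
                                        beta1 = beta1, beta2 = beta2, seed = sd))
    X1 <- stage1_matrix(co); X2 <- stage2_matrix(co); y <- cohort_labels(co)
    tr <- 1:200; va <- 201:300
    e1 <- fit_ensemble(X1[tr, ], y[tr], ensemble_config(seed = sd))
    e2 <- fit_ensemble(cbind(X1, X2)[tr, ], y[tr], ensemble_config(seed = sd + 1))
    thr <- tune_thresholds(e1, e2, X1[va, ], X2[va, ], y[va])
    attr(staged_predict(e1, e2, X1[va, ], X2[va, ], thr), "stage2_rate")
  }
  noise_stage2 <- vapply(1:20, function(s) run_case(1.5, 0, s), numeric(1))
  noise_stage1 <- vapply(1:20, function(s) run_case(0, 2.5, s), numeric(1))
  expect_gte(sum(noise_stage2 < 0.5), 16)
  expect_gte(sum(noise_stage1 > 0.5), 16)
})

test_that("scan-requirement summaries count routes correctly", {
  expect_equal(dxa_requirement_rate(rep("STAGE1", 10))$per_fold$retention, 1)
  r <- dxa_requirement_rate(c("STAGE1", "STAGE1", "STAGE2", "STAGE2"))
  expect_equal(r$per_fold$stage2_rate, 0.5)
  folds <- list(c(rep("STAGE1", 2), rep("STAGE2", 8)),
                c(rep("STAGE1", 5), rep("STAGE2", 5)),
                c(rep("STAGE1", 8), rep("STAGE2", 2)))
  rr <- dxa_requirement_rate(folds)
  expect_equal(unname(rr$retention_quantiles["50%"]), 0.5)
  expect_equal(rr$mean_retention, 0.5)
  tb <- tibble::tibble(fold = rep(1:2, each = 4),
                       route = c("STAGE1", "STAGE2", "STAGE2", "STAGE2",
                                 "STAGE1", "STAGE1", "STAGE1", "STAGE2"))
  expect_equal(dxa_requirement_rate(tb)$per_fold$stage2_rate, c(0.75, 0.25))
})
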