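#' Cross-validation configuration
#'
#' Outer stratified k-fold evaluation (default 10 folds, so a 547-subject
#' cohort yields ~492-sample outer-training folds and 54–55-sample test
#' folds). Inside each outer-training fold, two stratified validation sets
#' (default 45 subjects each) are carved out: the first tunes the deferral
#' thresholds, the second is held out and reported separately.
#'
#' @param n_outer_folds Outer fold count.
#' @param n_validation Size of each of the two validation sets.
#' @param inner_folds Folds for inner hyperparameter CV (used only when an
#'   ensemble config carries a `hyper_grid`).
#' @param seed Integer seed governing every split.
#' @return A list of class `"cv_config"`.
#' @export
cv_config <- function(n_outer_folds = 10, n_validation = 45, inner_folds = 5,
                      seed = 1L) {
  check_config(n_outer_folds >= 2, "n_outer_folds")
  check_config(n_validation >= 2, "n_validation")
  check_config(inner_folds >= 2, "inner_folds")
  structure(list(n_outer_folds = as.integer(n_outer_folds),
                 n_validation = as.integer(n_validation),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "cv_config")
}

# Deterministic stratified fold assignment. Within each class the per-fold
# counts differ by at most one, and remainders go to the folds with the
# smallest running totals, so overall fold sizes also differ by at most one.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  totals <- numeric(k)
  for (cls in sort(unique(y))) {
    idx <- sample(which(y == cls))
    n_c <- length(idx)
    cnt <- rep(n_c %/% k, k)
    r <- n_c %% k
    if (r > 0) {
      ord <- order(totals, stats::runif(k))
      cnt[ord[seq_len(r)]] <- cnt[ord[seq_len(r)]] + 1
    }
    folds[idx] <- rep(seq_len(k), cnt)
    totals <- totals + cnt
  }
  folds
}

#' Outer fold assignment for a cohort
#'
#' Exposed so callers (and leakage checks) can reconstruct exactly the
#' outer folds [nested_cv()] will use for a given configuration.
#'
#' @param y Binary outcome vector.
#' @param cv A [cv_config()].
#' @return Integer fold id per subject.
#' @export
cv_folds <- function(y, cv = cv_config()) {
  stratified_folds(as.integer(y), cv$n_outer_folds, seed = cv$seed)
}

# Stratified sample of size m (without replacement) from idx, preserving
# class proportions of y[idx].
stratified_sample <- function(idx, y, m) {
  pos <- idx[y[idx] == 1]; neg <- idx[y[idx] == 0]
  mp <- max(1L, round(m * length(pos) / length(idx)))
  mp <- min(mp, length(pos) - 1L)         # keep both classes available downstream
  c(sample(pos, mp), sample(neg, m - mp))
}

#' Nested cross-validation of the staged model
#'
#' The full evaluation harness. Per outer fold: two stratified validation
#' sets are carved from the outer-training fold; both ensembles are fit on
#' the remaining inner-training rows (the feature pipeline and any inner
#' hyperparameter CV run strictly inside those rows); validation set 1
#' tunes the deferral thresholds by [tune_thresholds()]; the outer test
#' fold then scores three models — Ensemble 1 alone, Ensemble 2 alone, and
#' the staged cascade. Metrics are summarized as across-fold average (AVG)
#' and standard deviation (STD); pooled outer-test predictions feed the
#' headline DeLong and McNemar comparisons (per-fold DeLong p-values are
#' also emitted).
#'
#' @param cohort A `"cohort_tbl"` (or tibble with `y`, `clin_*`, `img_*`).
#' @param cv A [cv_config()].
#' @param cfg1,cfg2 [ensemble_config()]s for Stage 1 and Stage 2.
#' @param pipeline [pipeline_options()] refit inside every fold.
#' @param sigma_grid,halfway_grid Threshold grids for [tune_thresholds()]
#'   (`NULL` = its defaults).
#' @return An object of class `"staged_cv"`; see [tidy.staged_cv()],
#'   [glance.staged_cv()], [cv_summary()], [autoplot.staged_cv()].
#' @export
nested_cv <- function(cohort, cv = cv_config(),
                      cfg1 = ensemble_config(), cfg2 = ensemble_config(),
                      pipeline = pipeline_options(),
                      sigma_grid = NULL, halfway_grid = NULL) {
  X1 <- stage1_matrix(cohort); X2 <- stage2_matrix(cohort)
  y <- cohort_labels(cohort)
  X12 <- cbind(X1, X2)
  folds <- cv_folds(y, cv)
  models <- c("ensemble1", "ensemble2", "staged")

  fold_metrics <- list(); fold_info <- list(); preds <- list()
  imp1 <- list(); imp2 <- list(); val2_metrics <- list()

  for (k in seq_len(cv$n_outer_folds)) {
    test <- which(folds == k)
    train <- which(folds != k)
    set.seed(cv$seed + 131L * k)
    val1 <- stratified_sample(train, y, cv$n_validation)
    rest <- setdiff(train, val1)
    val2 <- stratified_sample(rest, y, cv$n_validation)
    inner <- setdiff(rest, val2)
    if (length(unique(y[inner])) < 2 || length(unique(y[test])) < 2) {
      stop("configuration error: fold ", k, " too small to stratify", call. = FALSE)
    }

    c1 <- cfg1; c1$seed <- cfg1$seed + 1000L * k
    c2 <- cfg2; c2$seed <- cfg2$seed + 1000L * k + 500L
    ens1 <- fit_ensemble(X1[inner, , drop = FALSE], y[inner], c1, pipeline)
    ens2 <- fit_ensemble(X12[inner, , drop = FALSE], y[inner], c2, pipeline)

    thr <- tune_thresholds(ens1, ens2, X1[val1, , drop = FALSE],
                           X2[val1, , drop = FALSE], y[val1],
                           sigma_grid, halfway_grid)

    d1 <- predict_distribution(ens1, X1[test, , drop = FALSE])
    d2 <- predict_distribution(ens2, X12[test, , drop = FALSE])
    staged <- staged_predict(ens1, ens2, X1[test, , drop = FALSE],
                             X2[test, , drop = FALSE], thr)
    score <- list(ensemble1 = d1$mu, ensemble2 = d2$mu, staged = staged$p_final)

    fold_metrics[[k]] <- purrr::imap_dfr(score, function(p, nm) {
      dplyr::bind_cols(tibble::tibble(fold = k, model = nm,
                                      auc = roc_auc(y[test], p)),
                       binary_metrics(y[test], p))
    })
    fold_info[[k]] <- tibble::tibble(
      fold = k, n_test = length(test), n_train = length(train),
      n_inner = length(inner), sigma_thr = thr$sigma_thr,
      halfway_thr = thr$halfway_thr,
      stage2_rate = attr(staged, "stage2_rate"),
      p_delong_e1_staged = delong_safe(y[test], d1$mu, staged$p_final),
      p_delong_e2_staged = delong_safe(y[test], d2$mu, staged$p_final),
      p_delong_e1_e2 = delong_safe(y[test], d1$mu, d2$mu)
    )
    preds[[k]] <- tibble::tibble(row = test, fold = k, y = y[test],
                                 mu1 = d1$mu, s1 = d1$s, mu2 = d2$mu,
                                 route = staged$route, p_staged = staged$p_final)
    imp1[[k]] <- feature_importance(ens1)
    imp2[[k]] <- feature_importance(ens2)

    # held-out second validation set, reported but unused by the tuning
    dv1 <- predict_distribution(ens1, X1[val2, , drop = FALSE])
    sv <- staged_predict(ens1, ens2, X1[val2, , drop = FALSE],
                         X2[val2, , drop = FALSE], thr)
    val2_metrics[[k]] <- tibble::tibble(fold = k,
                                        auc_staged_val2 = roc_auc(y[val2], sv$p_final),
                                        auc_e1_val2 = roc_auc(y[val2], dv1$mu))
  }

  metrics <- dplyr::bind_rows(fold_metrics)
  summary <- metrics |>
    tidyr::pivot_longer(c("auc", "accuracy", "sensitivity", "specificity"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::summarise(avg = mean(.data$value), std = stats::sd(.data$value),
                     .groups = "drop")

  pred <- dplyr::bind_rows(preds)
  pooled_tests <- dplyr::bind_rows(
    dplyr::mutate(delong_test(pred$y, pred$mu1, pred$p_staged),
                  comparison = "ensemble1 vs staged"),
    dplyr::mutate(delong_test(pred$y, pred$mu2, pred$p_staged),
                  comparison = "ensemble2 vs staged"),
    dplyr::mutate(delong_test(pred$y, pred$mu1, pred$mu2),
                  comparison = "ensemble1 vs ensemble2")
  )
  mcnemar <- dplyr::bind_rows(
    dplyr::mutate(mcnemar_sens_spec(pred$y, pred$mu1 > 0.5, pred$p_staged > 0.5),
                  comparison = "ensemble1 vs staged"),
    dplyr::mutate(mcnemar_sens_spec(pred$y, pred$mu2 > 0.5, pred$p_staged > 0.5),
                  comparison = "ensemble2 vs staged")
  )

  structure(list(
    metrics = metrics, summary = summary,
    folds = dplyr::bind_rows(fold_info),
    predictions = pred,
    delong = pooled_tests, mcnemar = mcnemar,
    retention = dxa_requirement_rate(dplyr::select(pred, "fold", "route")),
    importance = list(ensemble1 = aggregate_importance(imp1),
                      ensemble2 = aggregate_importance(imp2)),
    validation2 = dplyr::bind_rows(val2_metrics),
    cv = cv, models = models, n = length(y)
  ), class = "staged_cv")
}

delong_safe <- function(y, s1, s2) {
  tryCatch(delong_test(y, s1, s2)$p_value, error = function(e) NA_real_)
}

#' Across-fold metric summary in report layout
#'
#' One row per model and metric with the across-fold average and standard
#' deviation — the layout of the headline performance table.
#'
#' @param x A `"staged_cv"`.
#' @return A tibble: `model`, `metric`, `avg`, `std`.
#' @export
cv_summary <- function(x) {
  stopifnot(inherits(x, "staged_cv"))
  dplyr::arrange(x$summary,
                 factor(.data$model, levels = x$models),
                 factor(.data$metric,
                        levels = c("auc", "accuracy", "sensitivity", "specificity")))
}

#' Tidy per-fold metrics of a nested-CV run
#'
#' @param x A `"staged_cv"`.
#' @param ... Unused.
#' @return Long tibble: `fold`, `model`, `metric`, `value`.
#' @method tidy staged_cv
#' @export
tidy.staged_cv <- function(x, ...) {
  tidyr::pivot_longer(x$metrics,
                      c("auc", "accuracy", "sensitivity", "specificity"),
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a nested-CV run
#'
#' @param x A `"staged_cv"`.
#' @param ... Unused.
#' @return One-row tibble with the average AUC of the three models, the
#'   mean Stage-1 retention, and the pooled DeLong p-values.
#' @method glance staged_cv
#' @export
glance.staged_cv <- function(x, ...) {
  avg_auc <- function(m) x$summary$avg[x$summary$model == m & x$summary$metric == "auc"]
  tibble::tibble(
    n = x$n, n_folds = x$cv$n_outer_folds,
    auc_ensemble1 = avg_auc("ensemble1"),
    auc_ensemble2 = avg_auc("ensemble2"),
    auc_staged = avg_auc("staged"),
    stage1_retention = x$retention$mean_retention,
    p_delong_staged_vs_e1 = x$delong$p_value[x$delong$comparison == "ensemble1 vs staged"],
    p_delong_staged_vs_e2 = x$delong$p_value[x$delong$comparison == "ensemble2 vs staged"]
  )
}

#' @export
print.staged_cv <- function(x, ...) {
  cat("<staged_cv> ", x$cv$n_outer_folds, "-fold nested CV on n = ", x$n, "\n", sep = "")
  s <- cv_summary(x)
  auc <- s[s$metric == "auc", ]
  for (i in seq_len(nrow(auc))) {
    cat(sprintf("  %-9s AUC %.4f (sd %.4f)\n", auc$model[i], auc$avg[i], auc$std[i]))
  }
  print(x$retention)
  invisible(x)
}

#' Mean ROC curves with across-fold variability
#'
#' Interpolates each fold's ROC step curve on a common false-positive-rate
#' grid and draws the across-fold mean true-positive rate with a +-1 sd
#' ribbon, one panel per model.
#'
#' @param object A `"staged_cv"`.
#' @param fpr_grid Grid of false-positive rates.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot staged_cv
#' @export
autoplot.staged_cv <- function(object, fpr_grid = seq(0, 1, by = 0.02), ...) {
  curves <- roc_fold_curves(object, fpr_grid)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$tpr_mean - .data$tpr_sd),
                                      ymax = pmin(1, .data$tpr_mean + .data$tpr_sd)),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "Mean ROC across outer folds (±1 sd)") +
    ggplot2::theme_minimal()
}

#' Fold-averaged ROC coordinates
#'
#' @param x A `"staged_cv"`.
#' @param fpr_grid Grid of false-positive rates.
#' @return Tibble: `model`, `fpr`, `tpr_mean`, `tpr_sd`.
#' @export
roc_fold_curves <- function(x, fpr_grid = seq(0, 1, by = 0.02)) {
  score_cols <- c(ensemble1 = "mu1", ensemble2 = "mu2", staged = "p_staged")
  purrr::imap_dfr(score_cols, function(col, model) {
    x$predictions |>
      dplyr::group_by(.data$fold) |>
      dplyr::group_map(~ tibble::tibble(
        fpr = fpr_grid,
        tpr = roc_interpolate(roc_points(.x$y, .x[[col]]), fpr_grid))) |>
      dplyr::bind_rows() |>
      dplyr::group_by(.data$fpr) |>
      dplyr::summarise(tpr_mean = mean(.data$tpr), tpr_sd = stats::sd(.data$tpr),
                       .groups = "drop") |>
      dplyr::mutate(model = model, .before = 1)
  })
}

#' Bar plot of fold-aggregated ensemble feature importance
#'
#' @param x A `"staged_cv"`.
#' @param stage `"ensemble1"` or `"ensemble2"`.
#' @param top_n Number of features shown.
#' @return A ggplot object.
#' @export
plot_importance <- function(x, stage = "ensemble2", top_n = 20) {
  imp <- dplyr::slice_head(x$importance[[stage]], n = top_n)
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance,
                                    y = stats::reorder(.data$feature, .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Ensemble-averaged |importance| (fold mean)", y = NULL,
                  title = paste("Feature importance:", stage)) +
    ggplot2::theme_minimal()
}

#' Plot AUC against uncertainty percentile
#'
#' @param curve Output of [uncertainty_percentile_auc()].
#' @return A ggplot object.
#' @export
plot_uncertainty_auc <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$percentile, y = .data$auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(color = "steelblue") + ggplot2::geom_point() +
    ggplot2::labs(x = "Uncertainty percentile (subset: s ≥ percentile)",
                  y = "AUC (DeLong CI)",
                  title = "Performance across uncertainty percentiles") +
    ggplot2::theme_minimal()
}
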