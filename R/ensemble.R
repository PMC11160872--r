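#' Configuration of a bootstrap uncertainty ensemble
#'
#' @param n_base_models Number of base models B (>= 1).
#' @param sample_fraction Fraction f in (0, 1] of training rows drawn *with
#'   replacement* for each base model (`round(f * n)` rows).
#' @param base_spec Registered base-learner name (see [base_learners()]).
#' @param params Base-learner hyperparameters (named list).
#' @param hyper_grid Optional list of named lists; if supplied, the setting
#'   maximizing inner stratified-CV AUC on the training rows is selected
#'   before the ensemble is fit.
#' @param inner_folds Folds for that inner CV (default 5).
#' @param stratified Draw bootstrap samples within class (option for
#'   imbalanced cohorts; off by default).
#' @param bootstrap Set `FALSE` to fit every base model on the full
#'   training set (useful with `n_base_models = 1` for a deterministic
#'   single model).
#' @param seed Integer seed; fitting is deterministic given the seed.
#' @return A list of class `"ensemble_config"`.
#' @export
ensemble_config <- function(n_base_models = 25, sample_fraction = 0.8,
                            base_spec = "ridge", params = list(),
                            hyper_grid = NULL, inner_folds = 5,
                            stratified = FALSE, bootstrap = TRUE, seed = 1L) {
  check_config(n_base_models >= 1, "n_base_models")
  check_config(sample_fraction > 0 && sample_fraction <= 1, "sample_fraction")
  check_config(is.character(base_spec) && length(base_spec) == 1, "base_spec")
  structure(list(n_base_models = as.integer(n_base_models),
                 sample_fraction = sample_fraction, base_spec = base_spec,
                 params = params, hyper_grid = hyper_grid,
                 inner_folds = as.integer(inner_folds),
                 stratified = isTRUE(stratified), bootstrap = isTRUE(bootstrap),
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Fit a bootstrap ensemble with per-sample uncertainty
#'
#' Fits the feature pipeline on the training rows, then `B` base models on
#' independent bootstrap draws of `round(f * n)` rows (with replacement).
#' A draw containing a single outcome class is redrawn (up to 100 retries).
#' If a hyperparameter grid is supplied, the setting with the best inner
#' stratified-CV AUC is chosen first, on the training rows only.
#'
#' @param X Numeric feature matrix (original, pre-selection space).
#' @param y Binary 0/1 outcome; both classes must be present.
#' @param config An [ensemble_config()].
#' @param pipeline [pipeline_options()] applied inside the training set.
#' @return An object of class `"uq_ensemble"`.
#' @export
fit_ensemble <- function(X, y, config = ensemble_config(),
                         pipeline = pipeline_options()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("data error: y contains a single class", call. = FALSE)
  stopifnot(nrow(X) == length(y))
  set.seed(config$seed)

  params <- config$params
  if (!is.null(config$hyper_grid) && length(config$hyper_grid) > 0) {
    params <- tune_base_params(X, y, config, pipeline)
  }

  pipe <- fit_pipeline(X, y, pipeline, estimator = config$base_spec, params = params)
  Z <- apply_pipeline(pipe, X)
  learner <- get_learner(config$base_spec)

  n <- nrow(X)
  m <- round(config$sample_fraction * n)
  draws <- vector("list", config$n_base_models)
  models <- vector("list", config$n_base_models)
  for (b in seq_len(config$n_base_models)) {
    idx <- draw_bootstrap(y, m, stratified = config$stratified,
                          bootstrap = config$bootstrap)
    draws[[b]] <- idx
    models[[b]] <- learner$fit(Z[idx, , drop = FALSE], y[idx], params)
  }
  structure(list(models = models, draws = draws, pipe = pipe,
                 config = config, params = params,
                 columns = colnames(X), n_train = n),
            class = "uq_ensemble")
}

draw_bootstrap <- function(y, m, stratified = FALSE, bootstrap = TRUE) {
  n <- length(y)
  if (!bootstrap) return(seq_len(n))
  for (try in seq_len(100)) {
    idx <- if (stratified) {
      pos <- which(y == 1); neg <- which(y == 0)
      mp <- max(1L, round(m * length(pos) / n))
      c(sample(pos, mp, replace = TRUE), sample(neg, m - mp, replace = TRUE))
    } else {
      sample.int(n, m, replace = TRUE)
    }
    if (length(unique(y[idx])) == 2) return(idx)
  }
  stop("data error: could not draw a bootstrap sample with both classes", call. = FALSE)
}

tune_base_params <- function(X, y, config, pipeline) {
  folds <- stratified_folds(y, config$inner_folds, seed = config$seed + 7919L)
  scores <- vapply(config$hyper_grid, function(par) {
    aucs <- vapply(seq_len(config$inner_folds), function(k) {
      tr <- folds != k; te <- folds == k
      if (length(unique(y[te])) < 2) return(NA_real_)
      pipe <- fit_pipeline(X[tr, , drop = FALSE], y[tr], pipeline,
                           estimator = config$base_spec, params = par)
      learner <- get_learner(config$base_spec)
      fit <- learner$fit(apply_pipeline(pipe, X[tr, , drop = FALSE]), y[tr], par)
      p <- learner$predict(fit, apply_pipeline(pipe, X[te, , drop = FALSE]))
      roc_auc(y[te], p)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  config$hyper_grid[[which.max(scores)]]
}

#' Per-sample prediction distribution of an ensemble
#'
#' Applies the ensemble's bound selection mask and preprocessor, collects
#' the B base-model probabilities for every row, and summarizes them as a
#' mean `mu` (the risk estimate) and sample standard deviation `s` (the
#' uncertainty; defined as 0 when B = 1).
#'
#' @param model A `"uq_ensemble"`.
#' @param X Feature matrix in the training (pre-selection) space.
#' @return A tibble of class `"prediction_distribution"` with columns
#'   `.row`, `mu`, `s`; the full n-by-B probability matrix is attached as
#'   attribute `"prob_matrix"`.
#' @export
predict_distribution <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$columns) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$columns)) {
    stop("schema error: columns do not match the fitted ensemble", call. = FALSE)
  }
  Z <- apply_pipeline(model$pipe, X)
  learner <- get_learner(model$config$base_spec)
  P <- vapply(model$models, function(m) learner$predict(m, Z), numeric(nrow(Z)))
  P <- matrix(P, nrow = nrow(Z))
  mu <- rowMeans(P)
  s <- if (ncol(P) == 1) rep(0, nrow(P)) else apply(P, 1, stats::sd)
  out <- tibble::tibble(.row = seq_len(nrow(P)), mu = mu, s = s)
  attr(out, "prob_matrix") <- P
  class(out) <- c("prediction_distribution", class(out))
  out
}

#' Ensemble-averaged absolute feature importance
#'
#' The importance of feature j is the mean over base models of the absolute
#' per-model importance (|coefficient| for linear learners, gain for
#' trees). Features removed by the selection mask score 0.
#'
#' @param model A `"uq_ensemble"`.
#' @return A tibble with columns `feature` and `importance`.
#' @export
feature_importance <- function(model) {
  learner <- get_learner(model$config$base_spec)
  imp_kept <- rowMeans(vapply(model$models,
                              function(m) abs(learner$importance(m)),
                              numeric(sum(model$pipe$mask$keep))))
  imp <- rep(0, length(model$pipe$mask$keep))
  imp[model$pipe$mask$keep] <- imp_kept
  tibble::tibble(feature = model$pipe$mask$columns %||%
                   paste0("V", seq_along(imp)),
                 importance = imp)
}

#' Across-fold aggregation of feature importances
#'
#' Averages per-fold [feature_importance()] tibbles feature-by-feature.
#'
#' @param imp_list List of importance tibbles from different folds.
#' @return A tibble with `feature` and the across-fold mean `importance`,
#'   sorted decreasing.
#' @export
aggregate_importance <- function(imp_list) {
  dplyr::bind_rows(imp_list) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(importance = mean(.data$importance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @export
print.uq_ensemble <- function(x, ...) {
  cat("<uq_ensemble> B =", x$config$n_base_models,
      "| learner:", x$config$base_spec,
      "| features:", sum(x$pipe$mask$keep), "/", length(x$pipe$mask$keep), "kept\n")
  invisible(x)
}

#' Export a prediction distribution as CSV
#'
#' @param dist A `"prediction_distribution"`.
#' @param path Output path.
#' @param ids Optional subject identifiers.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path, ids = NULL) {
  out <- tibble::tibble(id = ids %||% dist$.row, mu = dist$mu, s = dist$s)
  P <- attr(dist, "prob_matrix")
  colnames(P) <- paste0("b", seq_len(ncol(P)))
  readr::write_csv(dplyr::bind_cols(out, tibble::as_tibble(P)), path)
  invisible(path)
}
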