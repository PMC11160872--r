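#' Deferral-rule thresholds
#'
#' The staged model retains a Stage-1 prediction when its ensemble
#' uncertainty is low (`s <= sigma_thr`) *and* its mean probability is far
#' enough from the 0.50 decision midpoint (`|mu - 0.5| > halfway_thr`);
#' otherwise the subject cascades to Stage 2.
#'
#' @param sigma_thr Standard-deviation threshold (>= 0).
#' @param halfway_thr Distance-from-0.5 threshold in [0, 0.5].
#' @return A list of class `"staged_thresholds"`.
#' @export
staged_thresholds <- function(sigma_thr, halfway_thr) {
  check_config(is.numeric(sigma_thr) && sigma_thr >= 0, "sigma_thr")
  check_config(is.numeric(halfway_thr) && halfway_thr >= 0 && halfway_thr <= 0.5,
               "halfway_thr")
  structure(list(sigma_thr = sigma_thr, halfway_thr = halfway_thr),
            class = "staged_thresholds")
}

#' Route samples by the uncertainty gate
#'
#' @param dist1 Stage-1 [predict_distribution()] output (or any tibble with
#'   `mu` and `s` columns).
#' @param thresholds A [staged_thresholds()].
#' @return Character vector, `"STAGE1"` where the prediction is retained
#'   and `"STAGE2"` where the subject is deferred.
#' @export
route <- function(dist1, thresholds) {
  stopifnot(nrow(dist1) > 0)
  retained <- dist1$s <= thresholds$sigma_thr &
    abs(dist1$mu - 0.5) > thresholds$halfway_thr
  ifelse(retained, "STAGE1", "STAGE2")
}

#' Staged prediction with deferral
#'
#' Computes the Stage-1 distribution for every subject, applies the gate,
#' and evaluates the Stage-2 ensemble *only* on the cascaded rows (the cost
#' semantics of the design: a retained subject never needs the expensive
#' feature block). The final probability is the Stage-1 mean for retained
#' rows and the Stage-2 mean for cascaded rows.
#'
#' @param ens1 Ensemble fit on the Stage-1 block.
#' @param ens2 Ensemble fit on the combined Stage-1 + Stage-2 block.
#' @param X1 Stage-1 feature matrix.
#' @param X2 Stage-2 feature matrix, row-aligned with `X1`.
#' @param thresholds A [staged_thresholds()].
#' @return A tibble of class `"routing_result"` with columns `.row`,
#'   `route`, `mu1`, `s1`, `mu2` (NA for retained rows) and `p_final`.
#'   Attributes: `stage2_rate`, `thresholds`, `n_stage2_calls` (exactly
#'   `B2 * #cascaded`).
#' @export
staged_predict <- function(ens1, ens2, X1, X2, thresholds) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (nrow(X1) != nrow(X2)) {
    stop("schema error: X1 and X2 are not row-aligned", call. = FALSE)
  }
  d1 <- predict_distribution(ens1, X1)
  routes <- route(d1, thresholds)
  casc <- which(routes == "STAGE2")
  mu2 <- rep(NA_real_, nrow(X1))
  if (length(casc) > 0) {
    d2 <- predict_distribution(ens2, cbind(X1, X2)[casc, , drop = FALSE])
    mu2[casc] <- d2$mu
  }
  out <- tibble::tibble(.row = seq_len(nrow(X1)), route = routes,
                        mu1 = d1$mu, s1 = d1$s, mu2 = mu2,
                        p_final = ifelse(routes == "STAGE1", d1$mu, mu2))
  attr(out, "stage2_rate") <- length(casc) / nrow(X1)
  attr(out, "thresholds") <- thresholds
  attr(out, "n_stage2_calls") <- ens2$config$n_base_models * length(casc)
  class(out) <- c("routing_result", class(out))
  out
}

#' Scaled weighted AUC of a routed prediction set
#'
#' The tuning objective for the deferral thresholds: the size-weighted mean
#' of the AUC computed on retained (STAGE1) rows and the AUC computed on
#' cascaded (STAGE2) rows,
#' \deqn{J = (n_r \mathrm{AUC}_r + n_c \mathrm{AUC}_c) / (n_r + n_c).}
#' A subset containing a single outcome class (or fewer than 2 rows)
#' contributes its size with its AUC taken as 0.5 — an explicit,
#' documented fallback so the objective is defined on every grid point.
#'
#' @param y Binary 0/1 outcome.
#' @param p_final Final staged probabilities.
#' @param routes Character vector of `"STAGE1"` / `"STAGE2"`.
#' @return The objective value in [0, 1].
#' @export
scaled_weighted_auc <- function(y, p_final, routes) {
  if (length(y) == 0) stop("data error: empty input", call. = FALSE)
  subset_auc <- function(idx) {
    if (length(idx) < 2 || length(unique(y[idx])) < 2) return(0.5)
    roc_auc(y[idx], p_final[idx])
  }
  r <- which(routes == "STAGE1"); c_ <- which(routes == "STAGE2")
  (length(r) * subset_auc(r) + length(c_) * subset_auc(c_)) / length(y)
}

#' Tune the deferral thresholds on a validation set
#'
#' Exhaustive grid search over (`sigma_thr`, `halfway_thr`) maximizing
#' [scaled_weighted_auc()] on a validation set. Both stages' distributions
#' are computed once; each grid point then only re-routes. Ties are broken
#' by (1) larger Stage-1 retention, (2) smaller `sigma_thr`, (3) grid
#' order — the rule prefers the gate that avoids the expensive block most.
#'
#' @param ens1,ens2 Fitted ensembles (Stage-1 space; combined space).
#' @param X1_val,X2_val Row-aligned validation feature blocks.
#' @param y_val Binary validation outcome (both classes required).
#' @param sigma_grid Candidate `sigma_thr` values; default = deciles of the
#'   observed Stage-1 uncertainties.
#' @param halfway_grid Candidate `halfway_thr` values; default
#'   `seq(0, 0.45, by = 0.05)`.
#' @return The winning [staged_thresholds()], with the full tuning trace
#'   (grid point, objective, retention) attached as attribute `"trace"`.
#' @export
tune_thresholds <- function(ens1, ens2, X1_val, X2_val, y_val,
                            sigma_grid = NULL, halfway_grid = NULL) {
  y_val <- as.integer(y_val)
  if (length(unique(y_val)) < 2) {
    stop("data error: validation outcome contains a single class", call. = FALSE)
  }
  X1_val <- as.matrix(X1_val); X2_val <- as.matrix(X2_val)
  d1 <- predict_distribution(ens1, X1_val)
  d2 <- predict_distribution(ens2, cbind(X1_val, X2_val))
  if (is.null(sigma_grid)) {
    sigma_grid <- unique(stats::quantile(d1$s, probs = seq(0.1, 1, by = 0.1),
                                         names = FALSE))
  }
  if (is.null(halfway_grid)) halfway_grid <- seq(0, 0.45, by = 0.05)
  stopifnot(length(sigma_grid) > 0, length(halfway_grid) > 0)

  grid <- tidyr::expand_grid(sigma_thr = sigma_grid, halfway_thr = halfway_grid)
  eval_point <- function(sig, hw) {
    thr <- staged_thresholds(sig, hw)
    routes <- route(d1, thr)
    p_final <- ifelse(routes == "STAGE1", d1$mu, d2$mu)
    c(objective = scaled_weighted_auc(y_val, p_final, routes),
      retention = mean(routes == "STAGE1"))
  }
  res <- purrr::map2(grid$sigma_thr, grid$halfway_thr, eval_point)
  trace <- dplyr::mutate(grid,
                         objective = purrr::map_dbl(res, "objective"),
                         retention = purrr::map_dbl(res, "retention"),
                         order = dplyr::row_number())
  best <- trace |>
    dplyr::arrange(dplyr::desc(.data$objective), dplyr::desc(.data$retention),
                   .data$sigma_thr, .data$order) |>
    dplyr::slice(1)
  out <- staged_thresholds(best$sigma_thr, best$halfway_thr)
  attr(out, "trace") <- dplyr::select(trace, -"order")
  out
}

#' Expensive-modality requirement across folds
#'
#' Summarizes per-fold routing: the fraction of subjects cascaded to
#' Stage 2 (those who would require the expensive scan) and its
#' complement, the Stage-1 retention (scan-avoidance) rate, with the mean
#' and 25th/50th/75th percentiles of the retention across folds.
#'
#' @param routes A character vector of routes (one fold), a list of such
#'   vectors, or a tibble with `fold` and `route` columns.
#' @return A list of class `"dxa_rate"`: `per_fold` (tibble of fold,
#'   `stage2_rate`, `retention`), `mean_retention`, and
#'   `retention_quantiles` (named 25%/50%/75%).
#' @export
dxa_requirement_rate <- function(routes) {
  per_fold <- if (is.data.frame(routes)) {
    routes |>
      dplyr::group_by(fold = .data$fold) |>
      dplyr::summarise(stage2_rate = mean(.data$route == "STAGE2"), .groups = "drop")
  } else {
    if (!is.list(routes)) routes <- list(routes)
    tibble::tibble(fold = seq_along(routes),
                   stage2_rate = purrr::map_dbl(routes, ~ mean(.x == "STAGE2")))
  }
  per_fold$retention <- 1 - per_fold$stage2_rate
  structure(list(per_fold = per_fold,
                 mean_retention = mean(per_fold$retention),
                 retention_quantiles = stats::quantile(per_fold$retention,
                                                       c(0.25, 0.5, 0.75))),
            class = "dxa_rate")
}

#' @export
print.dxa_rate <- function(x, ...) {
  cat(sprintf("Stage-1 retention (scan avoided): mean %.2f%% | quartiles %.2f%% / %.2f%% / %.2f%% over %d fold(s)\n",
              100 * x$mean_retention,
              100 * x$retention_quantiles[1], 100 * x$retention_quantiles[2],
              100 * x$retention_quantiles[3], nrow(x$per_fold)))
  invisible(x)
}

#' Export a routing result as CSV
#'
#' @param result A `"routing_result"`.
#' @param path Output path.
#' @param ids Optional subject identifiers.
#' @return `path`, invisibly.
#' @export
write_routing <- function(result, path, ids = NULL) {
  readr::write_csv(tibble::tibble(id = ids %||% result$.row,
                                  route = result$route, mu1 = result$mu1,
                                  s1 = result$s1, p_final = result$p_final),
                   path)
  invisible(path)
}
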