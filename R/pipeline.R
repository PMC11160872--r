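#' Fit a centering/scaling (+ spatial sign) preprocessor
#'
#' Learns per-column means and standard deviations on the training rows
#' only. Columns with zero standard deviation are flagged (`zero_scale`)
#' rather than scaled; they are expected to be removed by [nzv_filter()].
#'
#' @param X_train Numeric training matrix (>= 2 rows, no missing values).
#' @param apply_spatial_sign If `TRUE`, [apply_preprocessor()] additionally
#'   projects each standardized row onto the unit sphere (spatial sign), a
#'   robust transform that blunts multivariate outliers. All-zero rows are
#'   left unchanged.
#' @return An object of class `"preprocessor"`.
#' @export
fit_preprocessor <- function(X_train, apply_spatial_sign = TRUE) {
  X_train <- as.matrix(X_train)
  if (nrow(X_train) < 2) stop("data error: need at least 2 training rows", call. = FALSE)
  if (anyNA(X_train)) stop("data error: missing values in training matrix", call. = FALSE)
  center <- colMeans(X_train)
  scale_ <- apply(X_train, 2, stats::sd)
  structure(
    list(center = center, scale = ifelse(scale_ == 0, 1, scale_),
         zero_scale = scale_ == 0,
         columns = colnames(X_train),
         apply_spatial_sign = isTRUE(apply_spatial_sign)),
    class = "preprocessor"
  )
}

#' Apply a fitted preprocessor
#'
#' Standardizes columns with the training-set center/scale, then (if the
#' preprocessor was fit with `apply_spatial_sign = TRUE`) divides each row
#' by its Euclidean norm so nonzero rows land on the unit sphere.
#'
#' @param model A `"preprocessor"` from [fit_preprocessor()].
#' @param X Numeric matrix with the same columns as the training matrix.
#' @return The transformed matrix.
#' @export
apply_preprocessor <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$columns) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$columns)) {
    stop("schema error: columns do not match the fitted preprocessor", call. = FALSE)
  }
  if (ncol(X) != length(model$center)) {
    stop("schema error: column count does not match the fitted preprocessor", call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  if (model$apply_spatial_sign) {
    nrm <- sqrt(rowSums(Z^2))
    nz <- nrm > 0
    Z[nz, ] <- Z[nz, , drop = FALSE] / nrm[nz]
  }
  Z
}

new_selection_mask <- function(keep, removed_by, columns = NULL) {
  stopifnot(length(keep) == length(removed_by), all(!keep == (removed_by != "none")))
  structure(list(keep = keep, removed_by = removed_by, columns = columns),
            class = "selection_mask")
}

#' Near-zero-variance filter
#'
#' Removes constant columns, and columns that are simultaneously dominated
#' by one value (ratio of the most common to the second most common value
#' `>= freq_ratio`) and nearly unvarying (`100 * distinct/n <= unique_pct`).
#' Defaults follow the widely used caret convention (19, 10).
#'
#' @param X Numeric matrix.
#' @param freq_ratio Frequency-ratio threshold (> 0).
#' @param unique_pct Percent-unique threshold (> 0).
#' @return A `"selection_mask"` with `keep` and `removed_by` (`"nzv"` for
#'   removed columns, `"none"` otherwise).
#' @export
nzv_filter <- function(X, freq_ratio = 19, unique_pct = 10) {
  X <- as.matrix(X)
  if (nrow(X) == 0 || ncol(X) == 0) stop("data error: empty matrix", call. = FALSE)
  stopifnot(freq_ratio > 0, unique_pct > 0)
  n <- nrow(X)
  bad <- apply(X, 2, function(x) {
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) == 1) return(TRUE)              # constant
    ratio <- tab[1] / tab[2]
    pct_unique <- 100 * length(tab) / n
    (ratio >= freq_ratio) && (pct_unique <= unique_pct)
  })
  new_selection_mask(keep = !bad,
                     removed_by = ifelse(bad, "nzv", "none"),
                     columns = colnames(X))
}

#' Greedy pairwise correlation filter
#'
#' While any absolute pairwise Pearson correlation exceeds `r_threshold`,
#' the worst offending pair is located and the member with the larger mean
#' absolute correlation to all other columns is removed (ties keep the
#' lower column index). Deterministic given column order; run
#' [nzv_filter()] first so no constant column is present.
#'
#' @param X Numeric matrix with no constant columns.
#' @param r_threshold Correlation threshold in (0, 1].
#' @return A `"selection_mask"` (`removed_by == "correlation"` for dropped
#'   columns). Retained columns are guaranteed to have no pair with
#'   `|r| > r_threshold`.
#' @export
correlation_filter <- function(X, r_threshold = 0.9) {
  X <- as.matrix(X)
  stopifnot(r_threshold > 0, r_threshold <= 1)
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("ordering error: constant column present; apply nzv_filter() first",
         call. = FALSE)
  }
  p <- ncol(X)
  keep <- rep(TRUE, p)
  if (p >= 2) {
    R <- abs(stats::cor(X))
    diag(R) <- 0
    repeat {
      Ra <- R[keep, keep, drop = FALSE]
      if (all(Ra <= r_threshold)) break
      alive <- which(keep)
      worst <- which(Ra == max(Ra), arr.ind = TRUE)[1, ]  # first = lowest index pair
      i <- alive[worst[1]]; j <- alive[worst[2]]
      mi <- mean(R[i, keep & (seq_len(p) != i)])
      mj <- mean(R[j, keep & (seq_len(p) != j)])
      drop_col <- if (mj > mi) j else if (mi > mj) i else max(i, j)
      keep[drop_col] <- FALSE
    }
  }
  new_selection_mask(keep = keep,
                     removed_by = ifelse(keep, "none", "correlation"),
                     columns = colnames(X))
}

#' Recursive feature elimination
#'
#' Backward multivariate selection: repeatedly fits the base learner,
#' removes the `step` features with the smallest importance, and stops when
#' `n_target` features remain. Returns the full elimination-order ranking
#' (rank 1 = survived longest / most relevant).
#'
#' @param X Numeric matrix (already preprocessed).
#' @param y Binary 0/1 outcome.
#' @param n_target Number of features to retain (>= 1).
#' @param step Features removed per round (>= 1; the final round removes
#'   just enough to land exactly on `n_target`).
#' @param estimator Registered base-learner name (see [base_learners()]).
#' @param params Optional learner hyperparameters.
#' @return Integer vector of ranks, one per column of `X` (1 = best).
#' @export
rfe <- function(X, y, n_target, step = 1, estimator = "ridge", params = list()) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (n_target > p) stop("configuration error: n_target exceeds feature count", call. = FALSE)
  stopifnot(n_target >= 1, step >= 1)
  learner <- get_learner(estimator)
  rank_out <- integer(p)
  active <- seq_len(p)
  next_rank <- p
  while (length(active) > n_target) {
    fit <- learner$fit(X[, active, drop = FALSE], y, params)
    imp <- learner$importance(fit)
    k <- min(step, length(active) - n_target)
    worst <- order(imp, seq_along(imp))[seq_len(k)]  # lowest importance first
    # eliminated features take the worst outstanding ranks, least important first
    for (w in order(imp[worst])) {
      rank_out[active[worst[w]]] <- next_rank
      next_rank <- next_rank - 1
    }
    active <- active[-worst]
  }
  rank_out[active] <- seq_len(length(active))
  rank_out
}

#' Options for the fold-level feature pipeline
#'
#' Bundles the preprocessing / selection settings applied inside every
#' training fold (never on test rows): near-zero-variance filter,
#' correlation filter, centering/scaling with spatial sign, and optional
#' recursive feature elimination.
#'
#' @param center_scale,spatial_sign Standardize columns; project rows onto
#'   the unit sphere.
#' @param nzv,freq_ratio,unique_pct Near-zero-variance filter and its
#'   thresholds.
#' @param cor_filter,r_threshold Correlation filter and its threshold.
#' @param rfe_n Target feature count for RFE, or `NULL` to skip RFE.
#' @param rfe_step RFE step size.
#' @return A list of class `"pipeline_options"`.
#' @export
pipeline_options <- function(center_scale = TRUE, spatial_sign = TRUE,
                             nzv = TRUE, freq_ratio = 19, unique_pct = 10,
                             cor_filter = TRUE, r_threshold = 0.9,
                             rfe_n = NULL, rfe_step = 1) {
  structure(list(center_scale = center_scale, spatial_sign = spatial_sign,
                 nzv = nzv, freq_ratio = freq_ratio, unique_pct = unique_pct,
                 cor_filter = cor_filter, r_threshold = r_threshold,
                 rfe_n = rfe_n, rfe_step = rfe_step),
            class = "pipeline_options")
}

# Fit the full pipeline on training data; returns the artifacts needed to
# transform new data identically. Order: NZV -> correlation -> scale/spatial
# sign -> RFE, so RFE never sees a constant or duplicated feature.
fit_pipeline <- function(X, y, opts = pipeline_options(),
                         estimator = "ridge", params = list()) {
  X <- as.matrix(X)
  p <- ncol(X)
  removed_by <- rep("none", p)
  keep <- rep(TRUE, p)

  if (isTRUE(opts$nzv)) {
    m <- nzv_filter(X, opts$freq_ratio, opts$unique_pct)
    removed_by[!m$keep] <- "nzv"
    keep <- m$keep
  }
  if (isTRUE(opts$cor_filter) && sum(keep) >= 2) {
    m <- correlation_filter(X[, keep, drop = FALSE], opts$r_threshold)
    removed_by[which(keep)[!m$keep]] <- "correlation"
    keep[which(keep)[!m$keep]] <- FALSE
  }
  prep <- fit_preprocessor(X[, keep, drop = FALSE],
                           apply_spatial_sign = isTRUE(opts$spatial_sign) &&
                             isTRUE(opts$center_scale))
  if (!isTRUE(opts$center_scale)) {
    prep$center[] <- 0; prep$scale[] <- 1
  }
  if (!is.null(opts$rfe_n) && opts$rfe_n < sum(keep)) {
    Z <- apply_preprocessor(prep, X[, keep, drop = FALSE])
    rk <- rfe(Z, y, n_target = opts$rfe_n, step = opts$rfe_step,
              estimator = estimator, params = params)
    drop_idx <- which(keep)[rk > opts$rfe_n]
    removed_by[drop_idx] <- "rfe"
    keep[drop_idx] <- FALSE
    prep <- fit_preprocessor(X[, keep, drop = FALSE],
                             apply_spatial_sign = prep$apply_spatial_sign)
  }
  list(mask = new_selection_mask(keep, removed_by, colnames(X)), prep = prep)
}

apply_pipeline <- function(pipe, X) {
  X <- as.matrix(X)
  if (!is.null(pipe$mask$columns) && !is.null(colnames(X))) {
    if (!identical(colnames(X), pipe$mask$columns)) {
      stop("schema error: columns do not match the fitted pipeline", call. = FALSE)
    }
  }
  apply_preprocessor(pipe$prep, X[, pipe$mask$keep, drop = FALSE])
}

#' @export
print.selection_mask <- function(x, ...) {
  cat("<selection_mask> ", sum(x$keep), "/", length(x$keep), " features kept (",
      paste0(names(table(x$removed_by[x$removed_by != "none"])), ": ",
             as.integer(table(x$removed_by[x$removed_by != "none"])),
             collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Serialize a selection mask to JSON
#'
#' @param mask A `"selection_mask"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_mask <- function(mask, path) {
  jsonlite::write_json(list(columns = mask$columns, keep = mask$keep,
                            removed_by = mask$removed_by),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
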