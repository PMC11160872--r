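#' Configuration for a synthetic two-block cohort
#'
#' Describes a cohort with a weakly informative "clinical" feature block
#' (Stage 1) and a strongly informative, internally correlated
#' "imaging-derived" block (Stage 2), plus a binary outcome assigned by
#' exact-count thresholding of a noisy latent risk score.
#'
#' The latent risk of subject \eqn{i} is
#' \deqn{z_i = b_i \beta_1 w_1^\top x_{1i} + \beta_2 w_2^\top x_{2i} + \epsilon_i}
#' where \eqn{w_1, w_2} are fixed unit weight vectors, \eqn{\epsilon_i} is
#' Gaussian noise with standard deviation `noise_sd`, and \eqn{b_i} is an
#' inflation factor (`easy_boost`) applied to a random `easy_fraction` of
#' subjects so that part of the cohort is confidently classifiable from the
#' Stage-1 block alone — the subpopulation a deferral rule can retain.
#' The `n_positives` subjects with the largest \eqn{z_i} receive label 1,
#' so the case count is exact for every seed.
#'
#' @param n_subjects Number of subjects (default 547).
#' @param n_positives Exact number of positive labels (default 94).
#'   Mutually exclusive with `prevalence`.
#' @param prevalence Optional fraction in (0,1); if supplied,
#'   `n_positives = round(prevalence * n_subjects)`.
#' @param n_stage1,n_stage2 Number of Stage-1 / Stage-2 features.
#' @param n_binary Number of Stage-1 features emitted as 0/1 indicators
#'   (dummy-coded categoricals); must be `<= n_stage1`.
#' @param beta1,beta2 Signal strength of each block on the latent scale.
#' @param rho2 Within-block equicorrelation of the Stage-2 features, in [0,1).
#' @param easy_fraction Fraction of subjects whose Stage-1 contribution is
#'   inflated, in [0,1].
#' @param easy_boost Inflation factor for easy subjects (default 3).
#' @param noise_sd Latent noise standard deviation.
#' @param seed Integer seed; generation is bit-reproducible given the config.
#'
#' @return A validated list of class `"cohort_config"`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 100, n_positives = 20, seed = 1)
#' cohort <- generate_cohort(cfg)
cohort_config <- function(n_subjects = 547, n_positives = 94, prevalence = NULL,
                          n_stage1 = 10, n_stage2 = 40, n_binary = 3,
                          beta1 = 0.25, beta2 = 2.5, rho2 = 0.5,
                          easy_fraction = 0.3, easy_boost = 3,
                          noise_sd = 1, seed = 1L) {
  if (!is.null(prevalence)) {
    check_config(is.numeric(prevalence) && length(prevalence) == 1 &&
                   prevalence > 0 && prevalence < 1, "prevalence")
    n_positives <- round(prevalence * n_subjects)
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_positives = as.integer(n_positives),
    n_stage1 = as.integer(n_stage1), n_stage2 = as.integer(n_stage2),
    n_binary = as.integer(n_binary), beta1 = beta1, beta2 = beta2,
    rho2 = rho2, easy_fraction = easy_fraction, easy_boost = easy_boost,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  check_config(cfg$n_subjects >= 2, "n_subjects")
  check_config(cfg$n_positives > 0 && cfg$n_positives < cfg$n_subjects, "n_positives")
  check_config(cfg$n_stage1 >= 1, "n_stage1")
  check_config(cfg$n_stage2 >= 1, "n_stage2")
  check_config(cfg$n_binary >= 0 && cfg$n_binary <= cfg$n_stage1, "n_binary")
  check_config(is.numeric(cfg$beta1) && cfg$beta1 >= 0, "beta1")
  check_config(is.numeric(cfg$beta2) && cfg$beta2 >= 0, "beta2")
  check_config(cfg$rho2 >= 0 && cfg$rho2 < 1, "rho2")
  check_config(cfg$easy_fraction >= 0 && cfg$easy_fraction <= 1, "easy_fraction")
  check_config(cfg$easy_boost > 0, "easy_boost")
  check_config(cfg$noise_sd >= 0, "noise_sd")
  check_config(!is.na(cfg$seed), "seed")
  structure(cfg, class = "cohort_config")
}

check_config <- function(ok, field) {
  if (!isTRUE(ok)) {
    stop("invalid configuration: field `", field, "` fails its constraint",
         call. = FALSE)
  }
}

#' Generate a synthetic two-block cohort
#'
#' Draws a cohort under [cohort_config()]: a Stage-1 clinical block mixing
#' 0/1 indicator columns and continuous columns, an equicorrelated Gaussian
#' Stage-2 imaging block (single-factor construction with correlation
#' `rho2`), and binary labels assigned to the `n_positives` subjects with
#' the largest latent risk.
#'
#' @param config A [cohort_config()].
#' @return A tibble of class `"cohort_tbl"` with columns `id`, `y`, the
#'   Stage-1 columns (`clin_*`) and Stage-2 columns (`img_*`). Attributes:
#'   `config`, `stage1_cols`, `stage2_cols`, and `oracle` — a tibble with the
#'   latent pieces (`s1`, `s2`, `z`, `easy`) useful for oracle checks.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  n <- config$n_subjects
  p1 <- config$n_stage1; p2 <- config$n_stage2; nb <- config$n_binary
  set.seed(config$seed)

  prev <- rep_len(c(0.5, 0.4, 0.2), nb)
  Xb <- if (nb > 0) vapply(prev, function(p) stats::rbinom(n, 1L, p), numeric(n)) else NULL
  Xc <- if (p1 > nb) matrix(stats::rnorm(n * (p1 - nb)), n) else NULL
  X1 <- cbind(Xb, Xc)
  colnames(X1) <- paste0("clin_", sprintf("%02d", seq_len(p1)))

  g <- stats::rnorm(n)
  X2 <- sqrt(config$rho2) * g + sqrt(1 - config$rho2) * matrix(stats::rnorm(n * p2), n)
  colnames(X2) <- paste0("img_", sprintf("%02d", seq_len(p2)))

  w1 <- stats::rnorm(p1); w1 <- w1 / sqrt(sum(w1^2))
  w2 <- stats::rnorm(p2); w2 <- w2 / sqrt(sum(w2^2))

  # latent pieces use standardized blocks so beta1/beta2 are comparable scales
  X1s <- safe_scale(X1)
  X2s <- safe_scale(X2)
  easy <- rep(FALSE, n)
  easy[sample.int(n, floor(config$easy_fraction * n))] <- TRUE
  boost <- ifelse(easy, config$easy_boost, 1)
  s1 <- config$beta1 * boost * drop(X1s %*% w1)
  s2 <- config$beta2 * drop(X2s %*% w2)
  z <- s1 + s2 + config$noise_sd * stats::rnorm(n)

  y <- integer(n)
  y[rank(-z, ties.method = "first") <= config$n_positives] <- 1L

  out <- tibble::as_tibble(cbind(as.data.frame(X1), as.data.frame(X2)))
  out <- tibble::add_column(out, id = sprintf("S%04d", seq_len(n)), y = y,
                            .before = 1)
  attr(out, "config") <- config
  attr(out, "stage1_cols") <- colnames(X1)
  attr(out, "stage2_cols") <- colnames(X2)
  attr(out, "oracle") <- tibble::tibble(s1 = s1, s2 = s2, z = z, easy = easy)
  class(out) <- c("cohort_tbl", class(out))
  out
}

safe_scale <- function(X) {
  s <- apply(X, 2, stats::sd)
  s[s == 0] <- 1
  scale(X, center = TRUE, scale = s)
}

#' Extract feature blocks and labels from a cohort
#'
#' @param cohort A `"cohort_tbl"` (or any tibble with `clin_*` / `img_*`
#'   columns and a `y` column).
#' @return `stage1_matrix()` / `stage2_matrix()` return numeric matrices;
#'   `cohort_labels()` the integer 0/1 outcome; `cohort_oracle()` the latent
#'   oracle tibble (or `NULL` for cohorts read from disk).
#' @export
stage1_matrix <- function(cohort) {
  cols <- attr(cohort, "stage1_cols") %||% grep("^clin_", names(cohort), value = TRUE)
  as.matrix(cohort[, cols, drop = FALSE])
}

#' @rdname stage1_matrix
#' @export
stage2_matrix <- function(cohort) {
  cols <- attr(cohort, "stage2_cols") %||% grep("^img_", names(cohort), value = TRUE)
  as.matrix(cohort[, cols, drop = FALSE])
}

#' @rdname stage1_matrix
#' @export
cohort_labels <- function(cohort) as.integer(cohort$y)

#' @rdname stage1_matrix
#' @export
cohort_oracle <- function(cohort) attr(cohort, "oracle")

#' Raw clinical table for baseline statistics
#'
#' Re-expresses the cohort's Stage-1 block as the mixed categorical /
#' continuous table that [baseline_tables()] consumes: 0/1 indicator columns
#' become yes/no factors, continuous columns pass through.
#'
#' @param cohort A `"cohort_tbl"`.
#' @return A tibble of clinical variables (no `id`, no outcome).
#' @export
cohort_clinical_table <- function(cohort) {
  X1 <- as.data.frame(stage1_matrix(cohort))
  is_bin <- vapply(X1, function(x) all(x %in% c(0, 1)), logical(1))
  X1[is_bin] <- lapply(X1[is_bin], function(x) factor(ifelse(x == 1, "yes", "no"),
                                                      levels = c("no", "yes")))
  tibble::as_tibble(X1)
}

#' Append degenerate columns to a cohort's Stage-1 block
#'
#' Fixture helper for the near-zero-variance and correlation filters:
#' appends `n_constant` constant columns and `n_duplicate` exact copies of
#' randomly chosen existing Stage-1 columns. Provenance is recorded in the
#' new column names (`clin_const_*`, `clin_dup*_of_<source>`).
#'
#' @param cohort A `"cohort_tbl"`.
#' @param n_constant,n_duplicate Counts (>= 0) of columns to append.
#' @param seed Seed for choosing which columns to duplicate.
#' @return The cohort with extra Stage-1 columns; other blocks unchanged.
#' @export
inject_degeneracies <- function(cohort, n_constant = 0, n_duplicate = 0, seed = 1L) {
  stopifnot(n_constant >= 0, n_duplicate >= 0)
  if (n_constant == 0 && n_duplicate == 0) return(cohort)
  s1_cols <- attr(cohort, "stage1_cols") %||% grep("^clin_", names(cohort), value = TRUE)
  set.seed(seed)
  extra <- list()
  for (k in seq_len(n_constant)) {
    extra[[paste0("clin_const_", k)]] <- rep(1, nrow(cohort))
  }
  if (n_duplicate > 0) {
    src <- sample(s1_cols, n_duplicate, replace = TRUE)
    for (k in seq_len(n_duplicate)) {
      extra[[paste0("clin_dup", k, "_of_", src[k])]] <- cohort[[src[k]]]
    }
  }
  out <- tibble::add_column(cohort, !!!extra,
                            .after = s1_cols[length(s1_cols)])
  attr(out, "stage1_cols") <- c(s1_cols, names(extra))
  attr(out, "stage2_cols") <- attr(cohort, "stage2_cols")
  attr(out, "config") <- attr(cohort, "config")
  attr(out, "oracle") <- attr(cohort, "oracle")
  class(out) <- unique(c("cohort_tbl", class(out)))
  out
}

#' Write / read a cohort as delimited text
#'
#' Writes `stage1.csv`, `stage2.csv` and `labels.csv` (column 1 = subject
#' id, header row) plus `config.json` with the generating configuration.
#'
#' @param cohort A `"cohort_tbl"`.
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` returns the directory invisibly; `read_cohort()`
#'   returns a `"cohort_tbl"` rebuilt from the files.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s1 <- tibble::as_tibble(cbind(id = cohort$id, as.data.frame(stage1_matrix(cohort))))
  s2 <- tibble::as_tibble(cbind(id = cohort$id, as.data.frame(stage2_matrix(cohort))))
  lb <- tibble::tibble(id = cohort$id, y = cohort$y)
  readr::write_csv(s1, file.path(dir, "stage1.csv"))
  readr::write_csv(s2, file.path(dir, "stage2.csv"))
  readr::write_csv(lb, file.path(dir, "labels.csv"))
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  s1 <- readr::read_csv(file.path(dir, "stage1.csv"), show_col_types = FALSE)
  s2 <- readr::read_csv(file.path(dir, "stage2.csv"), show_col_types = FALSE)
  lb <- readr::read_csv(file.path(dir, "labels.csv"), show_col_types = FALSE)
  stopifnot(identical(s1$id, lb$id), identical(s2$id, lb$id))
  out <- dplyr::bind_cols(tibble::tibble(id = lb$id, y = as.integer(lb$y)),
                          s1[-1], s2[-1])
  attr(out, "stage1_cols") <- names(s1)[-1]
  attr(out, "stage2_cols") <- names(s2)[-1]
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) {
    attr(out, "config") <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  }
  class(out) <- c("cohort_tbl", class(out))
  out
}
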