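as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("data error: expected a 2x2 table", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("data error: counts must be non-negative integers", call. = FALSE)
  }
  if (sum(m) == 0) stop("data error: empty table", call. = FALSE)
  m
}

#' Fisher's exact test on a 2x2 table (two-sided)
#'
#' Two-sided p-value summing the hypergeometric probabilities (margins
#' fixed) of every table at most as probable as the observed one. A table
#' with a zero margin carries no evidence and returns p = 1.
#'
#' @param table 2x2 matrix of counts (rows = outcome group, columns =
#'   category level).
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_p(matrix(c(1, 452, 4, 90), 2, byrow = TRUE))
fisher_exact_p <- function(table) {
  m <- as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Pearson chi-square test on a 2x2 table
#'
#' Yates continuity correction (`max(0, |O - E| - 0.5)` per cell) is
#' applied by default; disable it with `continuity_correction = FALSE`.
#'
#' @param table 2x2 matrix of counts.
#' @param continuity_correction Apply the Yates correction (default TRUE).
#' @return The p-value (1 df).
#' @export
chi_square_p <- function(table, continuity_correction = TRUE) {
  m <- as_2x2(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) stop("data error: zero expected count", call. = FALSE)
  suppressWarnings(
    stats::chisq.test(m, correct = continuity_correction)$p.value
  )
}

#' Welch t-test from group summary statistics
#'
#' Two-sided unequal-variance t-test computed directly from per-group
#' means, standard deviations and sizes, with Welch–Satterthwaite degrees
#' of freedom — for comparing continuous variables between outcome groups
#' when only summary tables are available.
#'
#' @param mean1,sd1,n1 Summary of group 1 (`n1 >= 2`, `sd1 >= 0`).
#' @param mean2,sd2,n2 Summary of group 2.
#' @return The two-sided p-value.
#' @export
#' @examples
#' welch_t_p(4.96, 0.99, 453, 4.48, 1.12, 94)
welch_t_p <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  if (v1 + v2 == 0) stop("degenerate error: zero variance in both groups", call. = FALSE)
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df)
}

#' Baseline-characteristics tables for a labeled cohort
#'
#' Produces the four standard baseline reports for a clinical table split
#' by a binary outcome: per-level counts with within-group percentages for
#' categorical variables; group means and standard deviations for
#' continuous variables; per-level chi-square (Yates) and Fisher exact
#' p-values from one-level-versus-rest 2x2 tables (binary variables get an
#' additional collapsed row, which carries the same p-value); and Welch
#' t-test p-values for continuous variables. Degenerate cases (constant
#' feature, zero expected count) are emitted with missing p-values rather
#' than dropped.
#'
#' @param clinical Data frame; factor/character columns are treated as
#'   categorical, numeric columns as continuous.
#' @param y Binary 0/1 outcome (1 = event).
#' @return A list of class `"baseline_tables"` with tibbles `categorical`,
#'   `continuous`, `categorical_tests`, `continuous_tests`.
#' @export
baseline_tables <- function(clinical, y) {
  y <- as.integer(y)
  stopifnot(nrow(clinical) == length(y), all(y %in% 0:1))
  is_cat <- vapply(clinical, function(x) is.factor(x) || is.character(x), logical(1))

  cat_rows <- list(); cat_tests <- list()
  for (nm in names(clinical)[is_cat]) {
    x <- as.factor(clinical[[nm]])
    for (lev in levels(x)) {
      in_lev <- x == lev
      a <- sum(in_lev & y == 0); b <- sum(!in_lev & y == 0)
      c_ <- sum(in_lev & y == 1); d <- sum(!in_lev & y == 1)
      tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
      cat_rows[[length(cat_rows) + 1]] <- tibble::tibble(
        feature = nm, level = lev,
        count_no = a, pct_no = 100 * a / sum(y == 0),
        count_yes = c_, pct_yes = 100 * c_ / sum(y == 1))
      cat_tests[[length(cat_tests) + 1]] <- tibble::tibble(
        feature = nm, level = lev,
        chi_square_p = tryCatch(chi_square_p(tab), error = function(e) NA_real_),
        fisher_p = tryCatch(fisher_exact_p(tab), error = function(e) NA_real_))
    }
    if (nlevels(x) == 2) {   # collapsed row for binary features
      cat_tests[[length(cat_tests) + 1]] <-
        dplyr::mutate(cat_tests[[length(cat_tests)]], level = "(overall)")
    }
  }

  cont_rows <- list(); cont_tests <- list()
  for (nm in names(clinical)[!is_cat]) {
    x <- clinical[[nm]]
    g0 <- x[y == 0]; g1 <- x[y == 1]
    cont_rows[[length(cont_rows) + 1]] <- tibble::tibble(
      feature = nm, mean_no = mean(g0), mean_yes = mean(g1),
      sd_no = stats::sd(g0), sd_yes = stats::sd(g1))
    cont_tests[[length(cont_tests) + 1]] <- tibble::tibble(
      feature = nm,
      p_value = tryCatch(
        welch_t_p(mean(g0), stats::sd(g0), length(g0),
                  mean(g1), stats::sd(g1), length(g1)),
        error = function(e) NA_real_))
  }

  structure(list(categorical = dplyr::bind_rows(cat_rows),
                 continuous = dplyr::bind_rows(cont_rows),
                 categorical_tests = dplyr::bind_rows(cat_tests),
                 continuous_tests = dplyr::bind_rows(cont_tests)),
            class = "baseline_tables")
}

#' @export
print.baseline_tables <- function(x, ...) {
  cat("<baseline_tables>",
      nrow(x$continuous), "continuous and",
      length(unique(x$categorical$feature)), "categorical feature(s)\n")
  invisible(x)
}

md_table <- function(df) {
  if (nrow(df) == 0) return(character(0))
  fmt <- function(v) ifelse(is.na(v), "",
                            ifelse(vapply(v, is.numeric, logical(1)),
                                   as.character(v), as.character(v)))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Write baseline tables as CSV and Markdown
#'
#' @param tables A `"baseline_tables"` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_baseline_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(categorical = "table_categorical_counts.csv",
             continuous = "table_continuous_summary.csv",
             categorical_tests = "table_categorical_tests.csv",
             continuous_tests = "table_continuous_tests.csv")
  for (nm in names(files)) {
    readr::write_csv(tables[[nm]], file.path(dir, files[nm]))
    writeLines(md_table(tables[[nm]]),
               file.path(dir, sub("\\.csv$", ".md", files[nm])))
  }
  invisible(dir)
}
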