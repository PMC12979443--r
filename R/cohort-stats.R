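# Baseline-table statistics: two-sample pooled-variance (Student) t tests,
# computable from raw vectors or from printed mean/SD/n summaries, and the
# uncorrected Pearson chi-square test. Matches the conventions of clinical
# baseline tables (SPSS defaults: pooled t, no Yates correction).

#' Group summary for a summary-statistics t test
#'
#' @param mean,sd Sample mean and sample standard deviation (n - 1
#'   denominator); `sd >= 0`.
#' @param n Group size (>= 2).
#' @return Object of class `"group_summary"`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

new_test_result <- function(statistic, df, p, method) {
  structure(list(statistic = statistic, df = df,
                 p_two_tailed = p, method = method),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4f, df %g, two-tailed p %s\n", x$method,
              x$statistic, x$df,
              if (x$p_two_tailed < 0.001) "< 0.001"
              else sprintf("%.3f", x$p_two_tailed)))
  invisible(x)
}

#' Pooled two-sample t test from printed summaries
#'
#' Student's t with pooled variance
#' `sp^2 = ((na-1) sa^2 + (nb-1) sb^2) / (na + nb - 2)`,
#' `t = (ma - mb) / (sp * sqrt(1/na + 1/nb))`, `df = na + nb - 2`, two-tailed
#' p from the t distribution. Lets published baseline tables (mean +/- SD
#' per group) be re-tested without raw data.
#'
#' @param a,b [group_summary()] objects.
#' @return A `"cohort_test"` with `statistic`, `df`, `p_two_tailed`.
#' @examples
#' pooled_t_from_summary(group_summary(67.35, 14.23, 360),
#'                       group_summary(61.85, 13.77, 181))
#' @export
pooled_t_from_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 == 0) {
    if (a$mean == b$mean)
      return(new_test_result(0, df, 1, "pooled two-sample t"))
    stop("zero pooled variance with unequal means: t statistic is infinite")
  }
  t <- (a$mean - b$mean) / (sqrt(sp2) * sqrt(1 / a$n + 1 / b$n))
  new_test_result(t, df, 2 * pt(-abs(t), df), "pooled two-sample t")
}

#' Pooled two-sample t test from raw vectors
#'
#' Identical formula to [pooled_t_from_summary()], applied to the sample
#' summaries of the raw data.
#'
#' @param xa,xb Numeric vectors, each of length >= 2.
#' @return A `"cohort_test"`.
#' @export
pooled_t_from_raw <- function(xa, xb) {
  stopifnot(length(xa) >= 2, length(xb) >= 2,
            all(is.finite(xa)), all(is.finite(xb)))
  pooled_t_from_summary(group_summary(mean(xa), sd(xa), length(xa)),
                        group_summary(mean(xb), sd(xb), length(xb)))
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the row/column marginals; `df = (r - 1)(c - 1)`. No continuity
#' correction (the convention of the baseline tables this reproduces).
#'
#' @param counts Non-negative integer matrix, at least 2 x 2, all marginals
#'   positive.
#' @return A `"cohort_test"`.
#' @examples
#' chi_square(matrix(c(78, 86, 282, 95), 2, 2))  # ~38.09
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all row and column marginals must be positive")
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  new_test_result(stat, df, pchisq(stat, df, lower.tail = FALSE),
                  "Pearson chi-square")
}

#' Baseline comparison table for a grouped cohort
#'
#' For every feature column, compares the two groups defined by a binary
#' grouping column: continuous variables by pooled t test, categorical and
#' binary variables by Pearson chi-square on the full cross-tabulation.
#' Output rows follow the input column order.
#'
#' @param cohort Data frame, one row per patient.
#' @param group_col Name of the binary 0/1 grouping column.
#' @return Data frame with columns `variable`, `type`, `summary_g1`,
#'   `summary_g0`, `statistic`, `df`, `p`.
#' @export
baseline_table <- function(cohort, group_col = "caf") {
  stopifnot(is.data.frame(cohort), group_col %in% names(cohort))
  g <- cohort[[group_col]]
  if (!all(g %in% c(0, 1)) || length(unique(g)) != 2)
    stop("grouping column must be binary 0/1 with both groups present")
  vars <- setdiff(names(cohort), group_col)
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x) && !all(x %in% c(0, 1))) {
      tr <- pooled_t_from_raw(x[g == 1], x[g == 0])
      data.frame(variable = v, type = "continuous",
                 summary_g1 = sprintf("%.2f ± %.2f",
                                      mean(x[g == 1]), sd(x[g == 1])),
                 summary_g0 = sprintf("%.2f ± %.2f",
                                      mean(x[g == 0]), sd(x[g == 0])),
                 statistic = tr$statistic, df = tr$df, p = tr$p_two_tailed)
    } else {
      tab <- table(factor(g, levels = c(1, 0)), x)
      tr <- chi_square(unclass(tab))
      data.frame(variable = v, type = "categorical",
                 summary_g1 = paste(colnames(tab), tab[1, ],
                                    sep = ":", collapse = " "),
                 summary_g0 = paste(colnames(tab), tab[2, ],
                                    sep = ":", collapse = " "),
                 statistic = tr$statistic, df = tr$df, p = tr$p_two_tailed)
    }
  })
  do.call(rbind, rows)
}
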