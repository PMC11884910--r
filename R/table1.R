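# Baseline-table comparisons computable from printed summaries: the
# Yates-corrected chi-square on 2x2 counts and the Welch t statistic from
# group means, SDs and sizes. Authored directly from the closed forms so
# they can be applied to published tables without raw data; cross-checked
# against stats::chisq.test()/t.test() in the test suite.

#' Yates-corrected chi-square for a 2x2 table
#'
#' Computes `n * (max(0, |ad - bc| - n/2))^2 / (r1 r2 c1 c2)` where r and c
#' are the margin totals. The continuity correction term `|ad - bc| - n/2`
#' is floored at 0, so perfectly proportional tables give exactly 0.
#'
#' @param a,b Successes and failures in group 1.
#' @param c,d Successes and failures in group 2.
#' @return A list with `statistic`, `df` (always 1) and `p_value` from the
#'   chi-square(1) reference distribution.
#' @export
#' @examples
#' chi_square_corrected(68, 31, 35, 25)$statistic  # 1.33
chi_square_corrected <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_noa("cell counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop_noa("table is empty")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) {
    stop_noa("zero margin: the chi-square statistic is undefined")
  }
  num <- max(0, abs(a * d - b * c) - n / 2)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, df = 1L, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

#' Group summary for a Welch t test
#'
#' @param mean Group mean.
#' @param sd Group standard deviation (non-negative).
#' @param n Group size (>= 2).
#' @return A list of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (sd < 0) stop_noa("sd must be >= 0")
  if (n < 2) stop_noa("n must be >= 2")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Welch t statistic from group summaries
#'
#' `t = (mean2 - mean1) / sqrt(sd1^2/n1 + sd2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom. Swapping the groups negates t and
#' leaves df unchanged.
#'
#' @param group1,group2 [group_summary()] objects.
#' @return A list with `t`, `df`, and the two-sided `p_value` from the t(df)
#'   reference distribution.
#' @export
#' @examples
#' welch_t(group_summary(25.9, 8.0, 100), group_summary(25.6, 6.7, 61))
welch_t <- function(group1, group2) {
  stopifnot(inherits(group1, "group_summary"), inherits(group2, "group_summary"))
  v1 <- group1$sd^2 / group1$n
  v2 <- group2$sd^2 / group2$n
  if (v1 + v2 == 0) {
    stop_noa("both standard deviations are 0: the t statistic is undefined")
  }
  t <- (group2$mean - group1$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (group1$n - 1) + v2^2 / (group2$n - 1))
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Baseline comparison table by outcome group
#'
#' Summarises the cohort the way baseline tables in treatment studies do:
#' per item (and for the total score), mean and SD within remitters and
#' non-remitters plus the Welch t comparison between them.
#'
#' @param cohort A [cohort_table()] with both outcome classes present.
#' @return A data frame with one row per item plus a `total_score` row:
#'   group means/SDs, `t`, `df`, `p_value`; the remission percentage is
#'   attached as `attr(, "remission_percent")`.
#' @export
cohort_summary_table <- function(cohort) {
  if (length(unique(cohort$outcome)) < 2L) {
    stop_noa("both outcome classes must be present")
  }
  rem <- cohort$outcome == 1L
  vars <- cbind(cohort$scores, total_score = rowSums(cohort$scores))
  rows <- lapply(colnames(vars), function(v) {
    x1 <- vars[rem, v]; x0 <- vars[!rem, v]
    w <- welch_t(group_summary(mean(x1), sd(x1), length(x1)),
                 group_summary(mean(x0), sd(x0), length(x0)))
    data.frame(variable = v,
               mean_remitters = mean(x1), sd_remitters = sd(x1),
               mean_nonremitters = mean(x0), sd_nonremitters = sd(x0),
               t = w$t, df = w$df, p_value = w$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "remission_percent") <- 100 * mean(rem)
  out
}
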