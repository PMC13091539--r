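#' Mean, s.e.m. and n of a set of per-unit values
#'
#' The reporting convention used throughout: arithmetic mean with the
#' standard error of the mean, `sd/sqrt(n)` with the n-1 variance. The
#' s.e.m. of a single value is undefined and returned as NA.
#'
#' @param values Numeric vector (one value per cell / experiment /
#'   profile).
#' @return A one-row tibble with `n`, `mean`, `sem`.
#' @examples
#' describe_values(c(1, 2, 3))  # mean 2, sem 0.5774
#' @export
describe_values <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop_invalid("No non-missing values to summarize.")
  tibble(n = n, mean = mean(values),
         sem = if (n > 1L) sd(values) / sqrt(n) else NA_real_)
}

#' Significance stars for p values
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns`
#' otherwise. Vectorized.
#'
#' @param p P value(s).
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Unpaired two-tailed two-sample comparison
#'
#' The statistical test used for all group comparisons: an unpaired
#' two-tailed Student's t-test assuming equal variances (`var_equal =
#' FALSE` switches to Welch's test). No multiple-testing correction is
#' applied. Both groups need at least two values.
#'
#' @param group_a,group_b Numeric vectors of per-unit values.
#' @param labels Length-2 character vector of group labels.
#' @param metric Optional metric name carried to the output.
#' @param var_equal Assume equal variances (Student) or not (Welch).
#' @return A one-row tibble: labels, per-group `n`/`mean`/`sem`,
#'   `t_statistic`, `df`, `p_value`, `stars`.
#' @examples
#' t_test_groups(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p = 0.0214, *
#' @export
t_test_groups <- function(group_a, group_b, labels = c("A", "B"),
                          metric = NA_character_, var_equal = TRUE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_invalid("Each group needs at least 2 values for a t-test.")
  }
  tt <- t.test(group_a, group_b, var.equal = var_equal,
               alternative = "two.sided")
  da <- describe_values(group_a)
  db <- describe_values(group_b)
  tibble(
    metric = metric,
    group1 = labels[1], group2 = labels[2],
    n1 = da$n, mean1 = da$mean, sem1 = da$sem,
    n2 = db$n, mean2 = db$mean, sem2 = db$sem,
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    stars = p_stars(tt$p.value)
  )
}

#' Data-frame-first group comparison
#'
#' Tidy front end to [t_test_groups()]: compares the values of one metric
#' column between exactly two levels of a grouping column. The unit of
#' analysis (cell, experiment, synaptic profile) is whatever one row of
#' `data` represents — aggregation to that unit must happen upstream.
#'
#' @param data A data frame with one row per analysis unit.
#' @param value Name of the value column (string).
#' @param group Name of the grouping column (string); must have exactly
#'   two levels present.
#' @param var_equal Student (TRUE) or Welch (FALSE).
#' @return A one-row tibble as in [t_test_groups()].
#' @export
compare_groups <- function(data, value, group, var_equal = TRUE) {
  levs <- unique(data[[group]])
  if (length(levs) != 2L) {
    stop_invalid("`group` must have exactly two levels present in `data`.")
  }
  t_test_groups(
    data[[value]][data[[group]] == levs[1]],
    data[[value]][data[[group]] == levs[2]],
    labels = as.character(levs), metric = value, var_equal = var_equal
  )
}
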