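## Distribution summaries and comparisons for simulated null dN/dS
## distributions: moments/percentiles, add-one empirical p-values against an
## observed omega, and a rank-based omnibus test across models.

.defined_values <- function(null) {
  if (inherits(null, "null_distribution")) null <- null$values
  if (!is.numeric(null)) dnds_parameter_error("expected a null_distribution or numeric vector")
  null[!is.na(null) & is.finite(null)]
}

#' Summarize a null dN/dS distribution
#'
#' Moments and percentiles are computed over the defined omega values;
#' degenerate (undefined-omega) replicates are counted separately and never
#' silently dropped.
#'
#' @param null A `null_distribution` (see [run_context()]) or numeric vector
#'   of omega values with `NA` marking degenerate replicates.
#' @return A list: `mean`, `sd`, `min`, `p2.5`, `p25`, `median`, `p75`,
#'   `p97.5`, `n_defined`, `n_degenerate`.
#' @export
summarize_null <- function(null) {
  vals <- .defined_values(null)
  total <- if (inherits(null, "null_distribution")) null$reps else length(null)
  if (length(vals) == 0L)
    dnds_empty_error("all replicates are degenerate; nothing to summarize")
  q <- stats::quantile(vals, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  list(mean = mean(vals), sd = stats::sd(vals), min = min(vals),
       p2.5 = q[1], p25 = q[2], median = q[3], p75 = q[4], p97.5 = q[5],
       n_defined = length(vals), n_degenerate = total - length(vals))
}

#' Empirical percentile of an observed omega against a null
#'
#' Add-one empirical p-values: under `alternative = "greater"`,
#' `p = (1 + #\{null >= observed\}) / (1 + n)`; `"less"` is symmetric; the
#' two-sided p is twice the smaller one-sided p, capped at 1. The add-one
#' rule bounds p below by `1/(n + 1)`, so a finite simulation never reports
#' p = 0.
#'
#' @param observed Observed omega value.
#' @param null A `null_distribution` or numeric vector of null omega values.
#' @param alternative `"greater"`, `"less"`, or `"two-sided"`.
#' @return A list: `observed_omega`, `empirical_p`, `alternative`,
#'   `n_defined`.
#' @export
empirical_percentile <- function(observed, null,
                                 alternative = c("greater", "less", "two-sided")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(observed) || length(observed) != 1L || is.na(observed))
    dnds_parameter_error("'observed' must be a single omega value")
  vals <- .defined_values(null)
  n <- length(vals)
  if (n == 0L) dnds_empty_error("no defined null values to compare against")
  p_greater <- (1 + sum(vals >= observed)) / (1 + n)
  p_less <- (1 + sum(vals <= observed)) / (1 + n)
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              `two-sided` = min(1, 2 * min(p_greater, p_less)))
  list(observed_omega = observed, empirical_p = p,
       alternative = alternative, n_defined = n)
}

#' Omnibus comparison of null distributions across models
#'
#' Kruskal-Wallis rank test across the defined omega values of two or more
#' null distributions (distribution-free; no assumption on the shape of the
#' simulated distributions).
#'
#' @param nulls List of `null_distribution` objects or numeric vectors.
#' @return A list: `statistic` (Kruskal-Wallis chi-squared), `p_value`, `df`,
#'   `method`, `group_sizes`.
#' @export
compare_models <- function(nulls) {
  if (!is.list(nulls) || length(nulls) < 2L)
    dnds_parameter_error("'nulls' must be a list of at least two distributions")
  groups <- lapply(nulls, .defined_values)
  usable <- lengths(groups) >= 2L
  if (sum(usable) < 2L)
    dnds_parameter_error("need at least two distributions with >= 2 defined values each")
  groups <- groups[usable]
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), method = "Kruskal-Wallis rank sum test",
       group_sizes = lengths(groups))
}
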