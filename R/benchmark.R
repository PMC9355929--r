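# Top-percentile benchmarking: scope for farm-level improvement.

#' Top-20th-percentile benchmark of one indicator cell
#'
#' The benchmark `P_fy` is the mean of the best `ceiling(0.2 * n)` values
#' among the `n` households of one stratum x system cell, where "best"
#' means largest for higher-is-better indicators and smallest for the GHG
#' footprint. Values tied with the cutoff are all included, so the set is
#' deterministic. Cells with fewer than 5 usable values are skipped
#' (returns NA).
#'
#' @param values Household indicator values of one cell; NAs are dropped.
#' @param direction `"higher"` or `"lower"`: which tail is best.
#' @param min_n Minimum usable values; smaller cells are skipped.
#' @return The benchmark value, or NA if the cell is too small.
#' @export
benchmark_top <- function(values, direction = c("higher", "lower"),
                          min_n = 5) {
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < min_n) return(NA_real_)
  m <- ceiling(0.2 * n)
  sorted <- sort(values, decreasing = (direction == "higher"))
  cutoff <- sorted[m]
  top <- if (direction == "higher") values[values >= cutoff] else
    values[values <= cutoff]
  mean(top)
}

#' Scope for improvement, percent
#'
#' Signed percent gap between the benchmark (top-percentile mean `P_fy`)
#' and the household's own value `A_FY`:
#' `(P_fy - A_FY) / A_FY * 100`. Undefined (NA) when the household value
#' is zero.
#'
#' @param p_fy Benchmark value (recycled).
#' @param a_fy Household value.
#' @return Percent gap; positive means room for improvement for
#'   higher-is-better indicators.
#' @export
scope_percent <- function(p_fy, a_fy) {
  ifelse(is.na(a_fy) | a_fy == 0, NA_real_, (p_fy - a_fy) / a_fy * 100)
}

#' Benchmark every household against top performers
#'
#' For each stratum x system x indicator cell, computes the
#' top-20th-percentile benchmark and each household's percent gap to it.
#' For the GHG footprint (lower is better) the benchmark is the
#' bottom-quintile mean and the magnitude of a negative gap is the
#' potential reduction; the `direction` column flags this prominently.
#'
#' @param indicators Output of [compute_indicators()].
#' @param indicators_used Indicator columns to benchmark.
#' @param directions Direction table, [indicator_directions()] by default.
#' @param min_n Minimum households per cell; smaller cells are skipped
#'   with a diagnostic message.
#' @return Tibble: household_id, stratum, system_label, indicator,
#'   direction, p_fy (benchmark), a_fy (household value), scope_pct, and
#'   `potential_reduction_pct` (GHG footprint only, `abs(scope_pct)`).
#' @export
benchmark_scope <- function(indicators,
                            indicators_used = croppsi_index_indicators,
                            directions = indicator_directions(),
                            min_n = 5) {
  long <- indicators %>%
    select(all_of(c("household_id", "stratum", "system_label",
                    indicators_used))) %>%
    tidyr::pivot_longer(all_of(indicators_used),
                        names_to = "indicator", values_to = "a_fy") %>%
    mutate(direction = unname(directions[.data$indicator]))

  out <- long %>%
    group_by(.data$stratum, .data$system_label, .data$indicator) %>%
    mutate(p_fy = benchmark_top(.data$a_fy, .data$direction[1],
                                min_n = min_n)) %>%
    ungroup()

  skipped <- out %>%
    filter(is.na(.data$p_fy)) %>%
    distinct(.data$stratum, .data$system_label, .data$indicator)
  if (nrow(skipped) > 0) {
    inform(paste0(nrow(skipped), " stratum x system x indicator cell(s) ",
                  "skipped (fewer than ", min_n, " usable values)"))
  }

  out %>%
    filter(!is.na(.data$p_fy)) %>%
    mutate(
      scope_pct = scope_percent(.data$p_fy, .data$a_fy),
      potential_reduction_pct = ifelse(.data$direction == "lower",
                                       abs(.data$scope_pct), NA_real_)
    ) %>%
    select("household_id", "stratum", "system_label", "indicator",
           "direction", "p_fy", "a_fy", "scope_pct",
           "potential_reduction_pct")
}
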