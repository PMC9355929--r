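# Within-household synergy / trade-off analysis against the FFA baseline.

#' Relative change of an indicator against a baseline
#'
#' `(system - baseline) * 100 / baseline`, in percent. The sign convention
#' follows the raw formula even for negative baselines (a change from -1
#' to 1 is -200%); baselines of exactly zero are undefined (NA).
#'
#' @param system_value,baseline_value Numeric vectors (recycled), same
#'   household and indicator.
#' @return Percent change, NA where the baseline is zero or missing.
#' @export
relative_change <- function(system_value, baseline_value) {
  ifelse(is.na(baseline_value) | baseline_value == 0, NA_real_,
         (system_value - baseline_value) * 100 / baseline_value)
}

#' Within-household relative changes of every indicator vs the FFA baseline
#'
#' For each double-cropped system observation, computes the relative change
#' of each performance indicator against the same household's single-aman
#' (FFA) value. Households lacking an FFA baseline are excluded with a
#' diagnostic message; indicators masked (NA) in either the system or the
#' baseline propagate NA for that indicator only.
#'
#' @param indicators Output of [compute_indicators()].
#' @param indicators_used Character vector of indicator columns to compare.
#' @return Long tibble: household_id, stratum, system_label, indicator,
#'   system_value, baseline_value, change_pct.
#' @export
tradeoff_changes <- function(indicators,
                             indicators_used = croppsi_index_indicators) {
  long <- indicators %>%
    select(all_of(c("household_id", "stratum", "system_label",
                    indicators_used))) %>%
    tidyr::pivot_longer(all_of(indicators_used),
                        names_to = "indicator", values_to = "system_value")
  baseline <- long %>%
    filter(.data$system_label == "FFA") %>%
    select("household_id", "stratum", "indicator",
           baseline_value = "system_value")
  systems <- long %>% filter(.data$system_label != "FFA")

  no_baseline <- dplyr::anti_join(
    distinct(systems, .data$household_id, .data$stratum),
    distinct(baseline, .data$household_id, .data$stratum),
    by = c("household_id", "stratum"))
  if (nrow(no_baseline) > 0) {
    inform(paste0(nrow(no_baseline), " household(s) without an FFA baseline ",
                  "excluded from the trade-off comparison: ",
                  paste(utils::head(no_baseline$household_id, 5),
                        collapse = ", ")))
  }

  dplyr::inner_join(systems, baseline,
                    by = c("household_id", "stratum", "indicator")) %>%
    mutate(change_pct = relative_change(.data$system_value,
                                        .data$baseline_value))
}

#' Summarize synergies and trade-offs per stratum x system x indicator
#'
#' Mean household-level relative change with a t-based 95% CI and a
#' synergy/trade-off label: a mean change in the desirable direction
#' (higher for all indicators except the GHG footprint, where lower is
#' desirable) is a synergy, otherwise a trade-off. Because the mean of
#' household-level relative changes generally differs from the relative
#' change of group means, the latter is reported alongside as
#' `change_of_group_means_pct`.
#'
#' @param changes Output of [tradeoff_changes()].
#' @param directions Desirability direction per indicator,
#'   [indicator_directions()] by default.
#' @param conf_level Confidence level for the t interval.
#' @return Tibble per stratum x system x indicator: n, mean change, CI
#'   bounds, change of group means, label. Cells with fewer than 2
#'   households carry NA confidence bounds; empty cells are omitted.
#' @export
summarize_tradeoffs <- function(changes, directions = indicator_directions(),
                                conf_level = 0.95) {
  out <- changes %>%
    filter(!is.na(.data$change_pct)) %>%
    group_by(.data$stratum, .data$system_label, .data$indicator) %>%
    summarise(
      n = dplyr::n(),
      mean_change_pct = mean(.data$change_pct),
      sd_change = sd(.data$change_pct),
      change_of_group_means_pct = relative_change(
        mean(.data$system_value), mean(.data$baseline_value)),
      .groups = "drop"
    ) %>%
    mutate(
      se = ifelse(.data$n >= 2, .data$sd_change / sqrt(.data$n), NA_real_),
      tcrit = qt(1 - (1 - conf_level) / 2, pmax(.data$n - 1, 1)),
      ci_lower = .data$mean_change_pct - .data$tcrit * .data$se,
      ci_upper = .data$mean_change_pct + .data$tcrit * .data$se,
      direction = unname(directions[.data$indicator]),
      label = ifelse(
        (.data$direction == "higher") == (.data$mean_change_pct >= 0),
        "synergy", "trade-off")
    ) %>%
    select("stratum", "system_label", "indicator", "n", "mean_change_pct",
           "ci_lower", "ci_upper", "change_of_group_means_pct",
           "direction", "label")
  out
}

#' Bar-chart helper for trade-off summaries
#'
#' Simple grouped bar chart of mean relative changes with CI whiskers,
#' faceted by stratum. Requires ggplot2.
#'
#' @param summary Output of [summarize_tradeoffs()].
#' @return A ggplot object.
#' @export
plot_tradeoffs <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plot_tradeoffs()")
  }
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$indicator, y = .data$mean_change_pct,
                               fill = .data$system_label)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::facet_wrap(~ .data$stratum, ncol = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Relative change vs FFA baseline (%)",
                  fill = "System") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
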