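# One-way ANOVA with LS means, Tukey-Kramer separation and compact letters.

#' One-way ANOVA with Tukey-Kramer mean separation
#'
#' Fixed-effects one-way ANOVA of an indicator against cropping-system
#' groups. Group (LS) means equal arithmetic means in the one-way layout;
#' 95% confidence intervals use the pooled error mean square with
#' per-group sample size, `mean +/- t(0.975, df_error) * sqrt(MSE / n_g)`.
#' Pairwise comparisons use the Tukey-Kramer studentized-range procedure
#' (exact for unequal n), and a compact letter display is assembled so
#' that groups sharing a letter are not significantly different at
#' `alpha`.
#'
#' @param values Numeric vector (NAs dropped with their group labels).
#' @param groups Group labels, same length.
#' @param alpha Significance level for mean separation.
#' @param conf_level Confidence level for the group CIs.
#' @return List: `f_value`, `p_value`, `df`, `mse`, `groups` (tibble with
#'   n, lsmean, ci_lower, ci_upper, letters), `pairwise` (tibble of
#'   Tukey-Kramer adjusted p-values).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05, conf_level = 0.95) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups)[keep]

  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    inform(paste0("Dropping group(s) with fewer than 2 observations: ",
                  paste(small, collapse = ", ")))
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- groups[keep]
    sizes <- table(groups)
  }
  if (length(sizes) < 2) {
    abort("anova_tukey needs at least 2 groups with >= 2 observations")
  }

  g <- factor(groups)
  fit <- aov(values ~ g)
  tab <- summary(fit)[[1]]
  f_value <- tab[1, "F value"]
  p_value <- tab[1, "Pr(>F)"]
  df_error <- tab[2, "Df"]
  mse <- tab[2, "Mean Sq"]

  lev <- levels(g)
  n_g <- as.numeric(table(g))
  means <- tapply(values, g, mean)
  tcrit <- qt(1 - (1 - conf_level) / 2, df_error)
  half <- tcrit * sqrt(mse / n_g)

  # Tukey-Kramer adjusted p-values for all pairs.
  k <- length(lev)
  pairs <- utils::combn(k, 2)
  pw <- tibble::tibble(
    group1 = lev[pairs[1, ]],
    group2 = lev[pairs[2, ]],
    diff = as.numeric(means[pairs[2, ]] - means[pairs[1, ]]),
    se = sqrt(mse / 2 * (1 / n_g[pairs[1, ]] + 1 / n_g[pairs[2, ]]))
  )
  pw$p_adj <- ptukey(abs(pw$diff) / pw$se, nmeans = k, df = df_error,
                     lower.tail = FALSE)

  signif_mat <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  sig <- pw$p_adj < alpha
  for (i in seq_len(nrow(pw))) {
    if (sig[i]) {
      signif_mat[pw$group1[i], pw$group2[i]] <- TRUE
      signif_mat[pw$group2[i], pw$group1[i]] <- TRUE
    }
  }
  letters_vec <- compact_letters(lev[order(-means)], signif_mat)[lev]

  list(
    f_value = f_value,
    p_value = p_value,
    df = c(between = tab[1, "Df"], error = df_error),
    mse = mse,
    groups = tibble::tibble(
      group = lev, n = n_g, lsmean = as.numeric(means),
      ci_lower = as.numeric(means) - half,
      ci_upper = as.numeric(means) + half,
      letters = unname(letters_vec)
    ),
    pairwise = pw
  )
}

# Compact letter display by insert-and-absorb. `order` gives the group
# sequence for letter assignment (conventionally decreasing mean);
# `signif` is a symmetric logical matrix of significant differences.
compact_letters <- function(ord, signif) {
  cols <- list(setNames(rep(TRUE, length(ord)), ord))
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (j <= i) next
      a <- ord[i]
      b <- ord[j]
      if (!signif[a, b]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[a] && col[b]) {
          col_a <- col
          col_a[b] <- FALSE
          col_b <- col
          col_b[a] <- FALSE
          cols[[ci]] <- col_a
          cols[[length(cols) + 1]] <- col_b
        }
      }
      # Absorb: drop columns whose membership is a subset of another's.
      drop <- rep(FALSE, length(cols))
      for (ci in seq_along(cols)) {
        for (cj in seq_along(cols)) {
          if (ci == cj || drop[cj]) next
          if (all(cols[[cj]] >= cols[[ci]]) &&
              any(cols[[cj]] != cols[[ci]])) {
            drop[ci] <- TRUE
            break
          }
        }
      }
      cols <- cols[!drop]
    }
  }
  # Letter columns ordered by their first member in the mean ordering.
  first <- vapply(cols, function(col) min(which(col[ord])), integer(1))
  cols <- cols[order(first)]
  out <- setNames(rep("", length(ord)), ord)
  for (ci in seq_along(cols)) {
    member <- names(cols[[ci]])[cols[[ci]]]
    out[member] <- paste0(out[member], letters[ci])
  }
  out
}

#' Format a share of households as a percentage string
#'
#' One-decimal percentage formatter used by the prevalence table:
#' `format_percent(276, 297)` is `"92.9"`.
#'
#' @param count,total Non-negative counts.
#' @return Character, percent to one decimal.
#' @export
format_percent <- function(count, total) {
  sprintf("%.1f", 100 * count / total)
}

#' Cropping-system prevalence table
#'
#' Households practicing each system per stratum, as count and percent of
#' the stratum's surveyed households (the FFA count, since every household
#' grows the aman baseline), formatted `count (percent)`.
#'
#' @param survey A validated survey tibble.
#' @return Tibble: stratum, system_label, n_households, percent, display.
#' @export
prevalence_table <- function(survey) {
  hh <- distinct(survey, .data$stratum, .data$system_label,
                 .data$household_id)
  totals <- hh %>%
    filter(.data$system_label == "FFA") %>%
    group_by(.data$stratum) %>%
    summarise(total = dplyr::n(), .groups = "drop")
  hh %>%
    group_by(.data$stratum, .data$system_label) %>%
    summarise(n_households = dplyr::n(), .groups = "drop") %>%
    left_join(totals, by = "stratum") %>%
    mutate(
      percent = format_percent(.data$n_households, .data$total),
      display = paste0(.data$n_households, " (", .data$percent, ")")
    ) %>%
    arrange(.data$stratum, .data$system_label)
}

#' Per-indicator ANOVA table across systems
#'
#' Runs [anova_tukey()] for each indicator within each stratum and
#' assembles the group-mean table with CIs, letters and F values.
#'
#' @param indicators Output of [compute_indicators()].
#' @param indicators_used Indicator columns to analyse.
#' @param alpha Mean-separation level.
#' @return List of two tibbles: `groups` (stratum x system x indicator
#'   LS means, CIs, letters) and `tests` (F and p per stratum x
#'   indicator).
#' @export
indicator_anova <- function(indicators,
                            indicators_used = croppsi_index_indicators,
                            alpha = 0.05) {
  groups_out <- list()
  tests_out <- list()
  for (st in unique(indicators$stratum)) {
    sub <- indicators %>% filter(.data$stratum == st)
    for (ind in indicators_used) {
      res <- anova_tukey(sub[[ind]], sub$system_label, alpha = alpha)
      groups_out[[length(groups_out) + 1]] <- res$groups %>%
        mutate(stratum = st, indicator = ind, .before = 1)
      tests_out[[length(tests_out) + 1]] <- tibble::tibble(
        stratum = st, indicator = ind,
        f_value = res$f_value, p_value = res$p_value,
        df_between = res$df[["between"]], df_error = res$df[["error"]])
    }
  }
  list(groups = bind_rows(groups_out), tests = bind_rows(tests_out))
}
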