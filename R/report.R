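# Report bundle: human-readable tables + machine-readable CSV/JSON.

#' Assemble the analysis report bundle
#'
#' Collects the stage outputs into a report directory: a prevalence table
#' (counts and one-decimal percentages per stratum), an indicator table
#' with LS means, 95% CIs, compact letters and F values, a factor-loading
#' table per stratum, the trade-off and scope summaries, per-observation
#' index scores, and a `run_metadata.json` carrying provenance (package
#' version, seed, coefficient-table hash). Missing stages produce a
#' partial report with the gap named in the metadata.
#'
#' @param out_dir Output directory (created if needed).
#' @param survey,indicators,index_models,tradeoffs,scope Stage outputs;
#'   any may be NULL for a partial report. `index_models` is a list of
#'   [build_index()] fits.
#' @param seed Seed used for the run (recorded in metadata).
#' @param coefficients Coefficient table used (hashed into metadata).
#' @return `out_dir`, invisibly; files are written as side effect.
#' @export
assemble_report <- function(out_dir, survey = NULL, indicators = NULL,
                            index_models = NULL, tradeoffs = NULL,
                            scope = NULL, seed = NULL,
                            coefficients = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gaps <- character(0)

  if (!is.null(survey)) {
    write_table(prevalence_table(survey), file.path(out_dir, "prevalence.csv"))
  } else gaps <- c(gaps, "survey")

  if (!is.null(indicators)) {
    write_table(indicators, file.path(out_dir, "indicators.csv"))
    anova_res <- indicator_anova(indicators)
    write_table(anova_res$groups, file.path(out_dir, "indicator_means.csv"))
    write_table(anova_res$tests, file.path(out_dir, "indicator_tests.csv"))
  } else gaps <- c(gaps, "indicators")

  if (!is.null(index_models)) {
    loadings <- bind_rows(lapply(index_models, function(m) {
      tibble::tibble(
        stratum = m$stratum,
        indicator = rownames(m$loadings),
        loading = m$loadings[, 1],
        kmo_overall = m$kmo_overall,
        ss_loading = m$ss_loadings[1],
        proportion_variance = m$proportion_variance[1],
        rmsr = m$rmsr,
        n_obs = m$n_obs
      )
    }))
    write_table(loadings, file.path(out_dir, "index_loadings.csv"))
    scores <- bind_rows(lapply(index_models, function(m) m$scores))
    write_table(scores, file.path(out_dir, "index_scores.csv"))
    idx_anova <- scores %>%
      group_by(.data$stratum) %>%
      dplyr::group_map(function(sub, key) {
        res <- anova_tukey(sub$mcpi, sub$system_label)
        mutate(res$groups, stratum = key$stratum, .before = 1)
      }) %>%
      bind_rows()
    write_table(idx_anova, file.path(out_dir, "index_group_means.csv"))
  } else gaps <- c(gaps, "index")

  if (!is.null(tradeoffs)) {
    write_table(tradeoffs, file.path(out_dir, "tradeoffs.csv"))
  } else gaps <- c(gaps, "tradeoffs")

  if (!is.null(scope)) {
    write_table(scope, file.path(out_dir, "scope.csv"))
  } else gaps <- c(gaps, "scope")

  meta <- list(
    package = "croppsi",
    version = as.character(utils::packageVersion("croppsi")),
    seed = seed,
    coefficients_hash = if (!is.null(coefficients)) {
      rlang::hash(coefficients)
    } else NULL,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    missing_stages = if (length(gaps) > 0) gaps else NULL
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (length(gaps) > 0) {
    warn(paste0("Partial report; missing stages: ",
                paste(gaps, collapse = ", ")))
  }
  invisible(out_dir)
}
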