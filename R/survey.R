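# Survey table: column dictionary, reader with validation, tidy writer.

#' Survey column dictionary
#'
#' One row per expected survey column, with unit and meaning. This is the
#' mapping template for external survey exports: rename the source columns
#' to these names (or pass a `schema` map to [read_survey()]).
#'
#' @return A tibble with columns `column`, `unit`, `description`.
#' @export
survey_columns <- function() {
  tibble::tribble(
    ~column,               ~unit,            ~description,
    "household_id",        "-",              "opaque household identifier",
    "stratum",             "-",              "within_polder or outside_polder",
    "system_label",        "-",              "annual cropping system (FFA/MFA/LFA/GFA/BFA/CFA)",
    "season",              "-",              "rabi, kharif1 or kharif2",
    "crop",                "-",              "crop grown this season (or fallow)",
    "grain_yield",         "t/ha",           "grain (or fresh produce) yield",
    "straw_yield",         "t/ha",           "straw yield, rice crops only",
    "crop_price",          "BDT/t",          "farm-gate price of the produce",
    "straw_price",         "BDT/t",          "farm-gate price of rice straw",
    "n_rate",              "kg N/ha",        "fertilizer nitrogen applied",
    "p_rate",              "kg P2O5/ha",     "fertilizer phosphorus applied",
    "k_rate",              "kg K2O/ha",      "fertilizer potassium applied",
    "pesticide",           "kg a.i./ha",     "pesticide active ingredient",
    "fuel",                "L/ha",           "diesel for land prep + irrigation pumping",
    "labor_total",         "person-h/ha",    "total labor, family + hired",
    "labor_hired",         "person-day/ha",  "hired labor only",
    "cost_inputs",         "BDT/ha",         "seeds, fertilizer, pesticide cost",
    "cost_labor",          "BDT/ha",         "labor cost",
    "cost_landprep",       "BDT/ha",         "land preparation cost",
    "cost_irrigation",     "BDT/ha",         "irrigation cost",
    "rice_price_household","BDT/t",          "household's own aman selling price (P_r)"
  )
}

# Fertilizer product -> nutrient conversion fractions (urea/TSP/MoP).
product_nutrient_fractions <- c(urea = 0.46, tsp = 0.46, mop = 0.60)

#' Read a cropping-system survey table
#'
#' Reads a CSV with one row per household x system x season, validates the
#' structural invariants (controlled vocabularies, non-negative quantities,
#' all-zero fallow rows, straw on rice only, exactly one kharif-2 aman
#' record per household x system, positive household rice price) and
#' returns a typed tibble. Rows violating invariants are reported with
#' row-level diagnostics and the read fails.
#'
#' @param path CSV file path.
#' @param schema Optional named character vector mapping the dictionary
#'   names in [survey_columns()] to the file's column names, for surveys
#'   exported under different headers.
#' @param fertilizer_products If `TRUE`, the file carries fertilizer product
#'   columns `urea`, `tsp`, `mop` (kg product/ha) instead of nutrient rates;
#'   they are converted with fractions 0.46, 0.46 and 0.60.
#' @param pesticide_product_mass If `TRUE`, the pesticide column is product
#'   mass rather than active ingredient; it is taken as-is but flagged via
#'   the `pesticide_basis` attribute so reports can state the basis.
#' @return A validated survey tibble (class `croppsi_survey`).
#' @export
read_survey <- function(path, schema = NULL, fertilizer_products = FALSE,
                        pesticide_product_mass = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    present <- intersect(unname(schema), names(df))
    df <- rename(df, !!!setNames(present, names(schema)[match(present, schema)]))
  }
  if (fertilizer_products) {
    prod_cols <- names(product_nutrient_fractions)
    missing <- setdiff(prod_cols, names(df))
    if (length(missing) > 0) {
      abort(paste0("fertilizer_products = TRUE but columns missing: ",
                   paste(missing, collapse = ", ")))
    }
    df$n_rate <- df$urea * product_nutrient_fractions["urea"]
    df$p_rate <- df$tsp * product_nutrient_fractions["tsp"]
    df$k_rate <- df$mop * product_nutrient_fractions["mop"]
    df <- select(df, -all_of(prod_cols))
  }
  out <- validate_survey(df)
  attr(out, "pesticide_basis") <-
    if (pesticide_product_mass) "product_mass" else "active_ingredient"
  out
}

#' Validate a survey tibble against the structural invariants
#'
#' @param df A data frame shaped as in [survey_columns()].
#' @return The validated tibble, classed `croppsi_survey`.
#' @export
validate_survey <- function(df) {
  missing <- setdiff(survey_required_cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("Survey is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)[survey_required_cols]
  if (nrow(df) == 0) {
    return(structure(df, class = c("croppsi_survey", class(df))))
  }

  problems <- character(0)
  bad_enum <- function(col, allowed) {
    rows <- which(!(df[[col]] %in% allowed))
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(
        "rows ", paste(utils::head(rows, 5), collapse = ","),
        ": invalid ", col, " (allowed: ", paste(allowed, collapse = "/"), ")"))
    }
  }
  bad_enum("stratum", croppsi_strata)
  bad_enum("season", croppsi_seasons)
  bad_enum("crop", croppsi_crops)
  bad_enum("system_label", names(croppsi_systems))

  num_cols <- c(record_quantity_cols, "rice_price_household")
  for (col in num_cols) {
    if (!is.numeric(df[[col]])) {
      problems <- c(problems, paste0("column ", col, " is not numeric"))
    }
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid survey:\n  ", paste(problems, collapse = "\n  ")))
  }

  # Missing straw on rice is interpreted as zero, with a warning.
  rice <- df$crop %in% croppsi_rice_crops
  na_straw <- rice & (is.na(df$straw_yield) | is.na(df$straw_price))
  if (any(na_straw)) {
    warn(paste0(sum(na_straw), " rice row(s) with missing straw data; ",
                "straw_yield/straw_price set to 0"))
    df$straw_yield[na_straw & is.na(df$straw_yield)] <- 0
    df$straw_price[na_straw & is.na(df$straw_price)] <- 0
  }

  neg <- which(rowSums(is.na(df[num_cols]) | df[num_cols] < 0) > 0)
  if (length(neg) > 0) {
    problems <- c(problems, paste0(
      "rows ", paste(utils::head(neg, 5), collapse = ","),
      ": negative or missing quantities"))
  }

  fallow <- df$crop == "fallow"
  fallow_qty <- record_quantity_cols
  nonzero_fallow <- which(fallow & rowSums(abs(df[fallow_qty]), na.rm = TRUE) > 0)
  if (length(nonzero_fallow) > 0) {
    problems <- c(problems, paste0(
      "rows ", paste(utils::head(nonzero_fallow, 5), collapse = ","),
      ": fallow rows must have all quantities zero"))
  }

  straw_nonrice <- which(!rice & (df$straw_yield > 0 | df$straw_price > 0))
  if (length(straw_nonrice) > 0) {
    problems <- c(problems, paste0(
      "rows ", paste(utils::head(straw_nonrice, 5), collapse = ","),
      ": straw fields used on a non-rice crop"))
  }

  # One kharif-2 record per household x system, and it is aman rice.
  k2 <- df %>%
    group_by(.data$household_id, .data$stratum, .data$system_label) %>%
    summarise(
      n_k2 = sum(.data$season == "kharif2"),
      n_k2_aman = sum(.data$season == "kharif2" & .data$crop == "aman_rice"),
      p_r = .data$rice_price_household[1],
      .groups = "drop"
    )
  bad_k2 <- k2 %>% filter(.data$n_k2 != 1 | .data$n_k2_aman != 1)
  if (nrow(bad_k2) > 0) {
    problems <- c(problems, paste0(
      "household(s) without exactly one kharif2 aman_rice record: ",
      paste(utils::head(unique(bad_k2$household_id), 5), collapse = ", ")))
  }
  bad_pr <- k2 %>% filter(!(.data$p_r > 0))
  if (nrow(bad_pr) > 0) {
    problems <- c(problems, paste0(
      "household(s) with non-positive rice_price_household: ",
      paste(utils::head(unique(bad_pr$household_id), 5), collapse = ", ")))
  }

  # System label must match the rabi crop actually recorded.
  rabi <- df %>%
    filter(.data$season == "rabi") %>%
    mutate(expected = unname(croppsi_systems[.data$system_label])) %>%
    filter(.data$crop != .data$expected)
  if (nrow(rabi) > 0) {
    problems <- c(problems, paste0(
      "household(s) whose rabi crop contradicts system_label: ",
      paste(utils::head(unique(rabi$household_id), 5), collapse = ", ")))
  }

  if (length(problems) > 0) {
    abort(paste0("Invalid survey:\n  ", paste(problems, collapse = "\n  ")))
  }
  structure(df, class = c("croppsi_survey", class(df)))
}

#' Write a tidy result table to CSV
#'
#' Writes any stage output (survey, indicators, trade-offs, scope, report
#' tables) as UTF-8 CSV with a stable column order, one row per unit of
#' analysis.
#'
#' @param rows A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  readr::write_csv(tibble::as_tibble(rows), path, progress = FALSE)
  invisible(path)
}
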