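# Energy / GHG coefficient table: loader, defaults, validation.

# Input kinds every survey record can carry; each must have an energy and a
# GHG factor or the loader refuses the table.
input_kinds <- c("n", "p2o5", "k2o", "pesticide", "fuel")

# Maps record quantity columns to coefficient input kinds.
input_kind_of_column <- c(
  n_rate = "n", p_rate = "p2o5", k_rate = "k2o",
  pesticide = "pesticide", fuel = "fuel"
)

n2o_defaults <- list(
  ef1 = 0.01, ef4 = 0.010, ef5 = 0.0075,
  frac_gasf = 0.10, frac_leach = 0.30, gwp_n2o = 265
)

known_coef_keys <- c("energy_per_input", "energy_labor", "energy_rice_grain",
                     "energy_grain_by_crop", "ghg_per_input", "n2o_factors",
                     "usd_per_bdt")

#' Load an energy/GHG coefficient table
#'
#' Reads a YAML file of conversion coefficients: embedded energy per unit of
#' input (MJ/kg or MJ/L), energy content of produce (MJ/kg), embedded
#' greenhouse-gas emissions per unit of input (kg CO2e/kg or /L), the IPCC
#' Tier-1 fertilizer N2O factors, and the BDT/USD exchange rate. Any
#' `n2o_factors` entry not present in the file is filled with the IPCC
#' Tier-1 default (EF1 = 0.01, EF4 = 0.010, EF5 = 0.0075,
#' FracGASF = 0.10, FracLEACH = 0.30, GWP = 265).
#'
#' @param path Path to a YAML coefficient file; see
#'   `system.file("extdata", "coefficients.yaml", package = "croppsi")`
#'   for the annotated default table.
#' @return A `croppsi_coefficients` list.
#' @export
load_coefficients <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), known_coef_keys)
  if (length(unknown) > 0) {
    warn(paste0("Ignoring unknown coefficient keys: ",
                paste(unknown, collapse = ", ")))
    raw <- raw[intersect(names(raw), known_coef_keys)]
  }
  as_coefficients(raw)
}

#' @rdname load_coefficients
#' @export
default_coefficients <- function() {
  load_coefficients(system.file("extdata", "coefficients.yaml",
                                package = "croppsi", mustWork = TRUE))
}

# Validate and class a raw coefficient list.
as_coefficients <- function(raw) {
  for (key in c("energy_per_input", "ghg_per_input")) {
    vals <- unlist(raw[[key]])
    missing_kinds <- setdiff(input_kinds, names(vals))
    if (length(missing_kinds) > 0) {
      abort(paste0("Coefficient table is missing ", key, " factors for: ",
                   paste(missing_kinds, collapse = ", ")))
    }
    if (any(vals <= 0)) {
      abort(paste0("All ", key, " factors must be > 0"))
    }
  }
  for (key in c("energy_labor", "energy_rice_grain", "usd_per_bdt")) {
    v <- raw[[key]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || v <= 0) {
      abort(paste0("Coefficient '", key, "' must be a single positive number"))
    }
  }
  gy <- unlist(raw[["energy_grain_by_crop"]])
  if (any(gy <= 0)) abort("energy_grain_by_crop factors must be > 0")

  n2o <- modifyList(n2o_defaults, as.list(raw[["n2o_factors"]] %||% list()))
  extra <- setdiff(names(n2o), names(n2o_defaults))
  if (length(extra) > 0) {
    warn(paste0("Ignoring unknown n2o_factors: ", paste(extra, collapse = ", ")))
    n2o <- n2o[names(n2o_defaults)]
  }
  n2o_num <- unlist(n2o)
  if (any(n2o_num < 0)) abort("n2o_factors must be non-negative")
  fracs <- n2o_num[c("ef1", "ef4", "ef5", "frac_gasf", "frac_leach")]
  if (any(fracs > 1)) abort("N2O emission factors and fractions must lie in [0, 1]")

  structure(
    list(
      energy_per_input = unlist(raw$energy_per_input)[input_kinds],
      energy_labor = raw$energy_labor,
      energy_rice_grain = raw$energy_rice_grain,
      energy_grain_by_crop = gy,
      ghg_per_input = unlist(raw$ghg_per_input)[input_kinds],
      n2o_factors = as.list(n2o_num),
      usd_per_bdt = raw$usd_per_bdt
    ),
    class = "croppsi_coefficients"
  )
}

#' @export
print.croppsi_coefficients <- function(x, ...) {
  cat("<croppsi_coefficients>\n")
  cat("  energy (MJ/unit):",
      paste(names(x$energy_per_input), x$energy_per_input,
            sep = "=", collapse = ", "), "\n")
  cat("  labor:", x$energy_labor, "MJ/h; rice grain:",
      x$energy_rice_grain, "MJ/kg\n")
  cat("  non-rice grain (MJ/kg):",
      paste(names(x$energy_grain_by_crop), x$energy_grain_by_crop,
            sep = "=", collapse = ", "), "\n")
  cat("  GHG (kg CO2e/unit):",
      paste(names(x$ghg_per_input), x$ghg_per_input,
            sep = "=", collapse = ", "), "\n")
  cat("  N2O Tier-1:",
      paste(names(x$n2o_factors), unlist(x$n2o_factors),
            sep = "=", collapse = ", "), "\n")
  cat("  1 BDT =", x$usd_per_bdt, "USD\n")
  invisible(x)
}

# Grain energy factor (MJ/kg) per crop vector, vectorized over crops.
grain_energy_factor <- function(crop, table) {
  out <- numeric(length(crop))
  is_rice <- crop %in% croppsi_rice_crops
  out[is_rice] <- table$energy_rice_grain
  nonrice <- !is_rice & crop != "fallow"
  if (any(nonrice)) {
    f <- table$energy_grain_by_crop[crop[nonrice]]
    if (anyNA(f)) {
      abort(paste0("No grain energy factor for crop(s): ",
                   paste(unique(crop[nonrice][is.na(f)]), collapse = ", ")))
    }
    out[nonrice] <- f
  }
  out
}
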