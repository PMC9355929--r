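# Seeded synthetic survey generator.
#
# Emulates the two-strata (within / outside polder) household survey
# structure: every household grows kharif-2 aman rice (the FFA baseline),
# and practices each double-cropped system independently with the observed
# marginal prevalence. Positive quantities are drawn from a log-normal (or
# gamma) distribution with configured mean and CV; a shared household
# multiplier on yields and prices induces within-household correlation.

# Default residual coefficient of variation per record quantity. Input
# rates, labor and costs additionally track the record's own yield draw
# through the input-yield elasticity, so their total variation is larger.
cv_defaults <- c(
  grain_yield = 0.25, straw_yield = 0.25,
  crop_price = 0.08, straw_price = 0.08,
  n_rate = 0.15, p_rate = 0.15, k_rate = 0.15, pesticide = 0.15, fuel = 0.15,
  labor_total = 0.15, labor_hired = 0.20,
  cost_inputs = 0.12, cost_labor = 0.12,
  cost_landprep = 0.12, cost_irrigation = 0.12
)

# Columns the shared household multiplier applies to.
household_scaled_cols <- c("grain_yield", "straw_yield",
                           "crop_price", "straw_price")

# Columns coupled to the record's own yield draw through the input-yield
# elasticity (management intensity tracks expected production).
yield_coupled_cols <- c("n_rate", "p_rate", "k_rate", "pesticide", "fuel",
                        "labor_total", "labor_hired", "cost_inputs",
                        "cost_labor", "cost_landprep", "cost_irrigation")

crop_param <- function(..., cv = NULL) {
  means <- c(...)
  full <- setNames(numeric(length(record_quantity_cols)), record_quantity_cols)
  full[names(means)] <- means
  cvs <- cv_defaults
  if (!is.null(cv)) cvs[names(cv)] <- cv
  list(mean = full, cv = cvs[record_quantity_cols])
}

#' Default generator configuration
#'
#' Two strata sized as in the source survey (297 households within polders,
#' 204 outside), system prevalences matching the observed shares (e.g.
#' mungbean systems practiced by 92.9% of polder households and 79.4%
#' outside; lathyrus by 37.7% and 51.0%), and per-crop input, yield, price,
#' labor and cost means calibrated so that the implied group mean
#' indicators reproduce the published group ordering: rice-equivalent
#' yield increasing from the single-aman baseline through lathyrus,
#' mungbean, groundnut/boro to chili systems, the boro system worst on
#' every efficiency indicator, and the baseline best on energy efficiency
#' and N productivity.
#'
#' `targets$rey` records the group-mean rice-equivalent yields (t/ha/yr)
#' the calibration aims at.
#'
#' @return A generator configuration list accepted by [generate_survey()].
#' @export
default_config <- function() {
  aman_w <- crop_param(
    grain_yield = 2.30, straw_yield = 2.0,
    crop_price = 17000, straw_price = 1500,
    n_rate = 31, p_rate = 10, k_rate = 12, pesticide = 0.4, fuel = 8,
    labor_total = 400, labor_hired = 25,
    cost_inputs = 9500, cost_labor = 14000, cost_landprep = 6000
  )
  aman_o <- crop_param(
    grain_yield = 2.00, straw_yield = 1.8,
    crop_price = 17000, straw_price = 1500,
    n_rate = 32, p_rate = 10, k_rate = 12, pesticide = 0.4, fuel = 8,
    labor_total = 400, labor_hired = 25,
    cost_inputs = 9500, cost_labor = 14500, cost_landprep = 6000
  )
  mungbean <- crop_param(
    grain_yield = 0.90, crop_price = 44000,
    n_rate = 17, p_rate = 12, k_rate = 3, pesticide = 0.6, fuel = 12,
    labor_total = 300, labor_hired = 30,
    cost_inputs = 4500, cost_labor = 9000, cost_landprep = 2500
  )
  lathyrus <- crop_param(
    grain_yield = 0.75, crop_price = 35000,
    n_rate = 13, p_rate = 6, k_rate = 2, pesticide = 0.4, fuel = 6,
    labor_total = 160, labor_hired = 12,
    cost_inputs = 2500, cost_labor = 6500, cost_landprep = 1500
  )
  groundnut <- crop_param(
    grain_yield = 1.40, crop_price = 44500,
    n_rate = 15, p_rate = 20, k_rate = 15, pesticide = 0.6, fuel = 10,
    labor_total = 350, labor_hired = 15,
    cost_inputs = 15000, cost_labor = 20000, cost_landprep = 5000,
    cost_irrigation = 3500
  )
  boro <- crop_param(
    grain_yield = 3.65, straw_yield = 3.0,
    crop_price = 16000, straw_price = 1500,
    n_rate = 120, p_rate = 30, k_rate = 45, pesticide = 1.0, fuel = 120,
    labor_total = 600, labor_hired = 70,
    cost_inputs = 25000, cost_labor = 22000, cost_landprep = 6000,
    cost_irrigation = 23000
  )
  chili <- crop_param(
    grain_yield = 7.50, crop_price = 12000,
    n_rate = 60, p_rate = 35, k_rate = 22, pesticide = 2.5, fuel = 25,
    labor_total = 700, labor_hired = 45,
    cost_inputs = 24000, cost_labor = 28000, cost_landprep = 4400,
    cost_irrigation = 6500
  )
  boro_o <- boro
  boro_o$mean["grain_yield"] <- 3.94

  list(
    seed = 1L,
    family = "lognormal",
    household_sigma = 0.12,
    input_yield_elasticity = 0.8,
    strata = list(
      within_polder = list(
        n_households = 297L,
        prevalence = c(FFA = 1, MFA = 0.929, LFA = 0.377,
                       GFA = 0.148, BFA = 0.037, CFA = 0.077),
        crops = list(aman_rice = aman_w, mungbean = mungbean,
                     lathyrus = lathyrus, groundnut = groundnut,
                     boro_rice = boro, chili = chili)
      ),
      outside_polder = list(
        n_households = 204L,
        prevalence = c(FFA = 1, MFA = 0.794, LFA = 0.510, BFA = 0.083),
        crops = list(aman_rice = aman_o,
                     mungbean = modifyList(mungbean, list(
                       mean = replace(mungbean$mean, "grain_yield", 0.92))),
                     lathyrus = modifyList(lathyrus, list(
                       mean = replace(lathyrus$mean, "grain_yield", 0.76))),
                     boro_rice = boro_o)
      )
    ),
    targets = list(
      rey = list(
        within_polder = c(FFA = 2.48, LFA = 4.03, MFA = 4.80,
                          GFA = 6.15, BFA = 6.18, CFA = 7.78),
        outside_polder = c(FFA = 2.16, LFA = 3.73, MFA = 4.55, BFA = 6.13)
      )
    )
  )
}

#' Group-mean rice-equivalent yields implied by a generator configuration
#'
#' Evaluates the REY formula at the configured quantity means (the
#' household multiplier has mean one and price ratios are unchanged by it),
#' giving the large-sample group means the generator should approach.
#'
#' @param config A generator configuration.
#' @return Named list per stratum of named numeric vectors (t/ha/yr).
#' @export
config_rey_targets <- function(config) {
  lapply(config$strata, function(st) {
    aman <- st$crops$aman_rice$mean
    p_r <- aman[["crop_price"]]
    aman_rey <- aman[["grain_yield"]] +
      aman[["straw_yield"]] * aman[["straw_price"]] / p_r
    vapply(names(st$prevalence), function(sys) {
      crop <- unname(croppsi_systems[sys])
      if (crop == "fallow") return(aman_rey)
      cp <- st$crops[[crop]]$mean
      y <- cp[["grain_yield"]]
      if (crop %in% croppsi_rice_crops && cp[["crop_price"]] > 0) {
        y <- y + cp[["straw_yield"]] * cp[["straw_price"]] / cp[["crop_price"]]
      }
      aman_rey + y * cp[["crop_price"]] / p_r
    }, numeric(1))
  })
}

validate_generator_config <- function(config) {
  if (!is.list(config$strata) || length(config$strata) == 0) {
    abort("config$strata must be a non-empty list")
  }
  if (!config$family %in% c("lognormal", "gamma", "degenerate")) {
    abort("family must be lognormal, gamma or degenerate")
  }
  if (config$household_sigma < 0) abort("household_sigma must be >= 0")
  b <- config$input_yield_elasticity %||% 0
  if (b < 0 || b > 1) abort("input_yield_elasticity must lie in [0, 1]")
  for (sname in names(config$strata)) {
    st <- config$strata[[sname]]
    if (st$n_households < 0) abort("n_households must be >= 0")
    prev <- st$prevalence
    if (any(prev < 0 | prev > 1)) abort("prevalences must lie in [0, 1]")
    if (is.na(prev["FFA"]) || prev[["FFA"]] != 1) {
      abort("prevalence of FFA must be 1 (every household grows aman rice)")
    }
    bad <- setdiff(names(prev), names(croppsi_systems))
    if (length(bad) > 0) {
      abort(paste0("unknown system label(s) in prevalence: ",
                   paste(bad, collapse = ", ")))
    }
    for (sys in setdiff(names(prev), "FFA")) {
      crop <- unname(croppsi_systems[sys])
      if (is.null(st$crops[[crop]])) {
        abort(paste0("stratum ", sname, ": no crop parameters for ", crop))
      }
    }
    if (is.null(st$crops$aman_rice)) {
      abort(paste0("stratum ", sname, ": aman_rice parameters required"))
    }
    for (cp in st$crops) {
      if (any(cp$mean < 0) || any(cp$cv < 0)) {
        abort("crop parameter means and CVs must be >= 0")
      }
    }
  }
  invisible(config)
}

# One vector of positive draws with given mean/cv under the chosen family.
draw_quantity <- function(n, mu, cv, family) {
  if (n == 0) return(numeric(0))
  if (mu == 0 || family == "degenerate" || cv == 0) return(rep(mu, n))
  if (family == "lognormal") {
    s2 <- log(1 + cv^2)
    rlnorm(n, meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
  } else {
    rgamma(n, shape = 1 / cv^2, scale = mu * cv^2)
  }
}

# Draw a block of records for one crop: one row per element of `mult`
# (the household multipliers of the receiving households). Yields and
# prices carry the household multiplier; input rates, labor and costs are
# additionally scaled by (yield draw / configured mean)^elasticity, mean-
# corrected so the configured marginal means are preserved exactly.
draw_crop_block <- function(params, mult, family, elasticity = 0,
                            sigma_h = 0) {
  n <- length(mult)
  cols <- vector("list", length(record_quantity_cols))
  names(cols) <- record_quantity_cols
  for (q in household_scaled_cols) {
    v <- draw_quantity(n, params$mean[[q]], params$cv[[q]], family)
    cols[[q]] <- v * mult
  }
  mu_y <- params$mean[["grain_yield"]]
  coupling <- if (elasticity > 0 && mu_y > 0 && family == "lognormal") {
    s2_y <- log(1 + params$cv[["grain_yield"]]^2) + sigma_h^2
    ratio <- cols[["grain_yield"]] / mu_y
    ratio^elasticity / exp((elasticity^2 - elasticity) * s2_y / 2)
  } else rep(1, n)
  for (q in setdiff(record_quantity_cols, household_scaled_cols)) {
    v <- draw_quantity(n, params$mean[[q]], params$cv[[q]], family)
    cols[[q]] <- if (q %in% yield_coupled_cols) v * coupling else v
  }
  tibble::as_tibble(cols)
}

fallow_block <- function(n) {
  cols <- lapply(record_quantity_cols, function(q) rep(0, n))
  names(cols) <- record_quantity_cols
  tibble::as_tibble(cols)
}

#' Generate a synthetic survey
#'
#' Draws a complete household survey under `config`: each household receives
#' the FFA baseline plus each double-cropped system with its configured
#' prevalence (independent Bernoulli draws; the source survey reports only
#' marginal prevalences). Each household grows a single aman crop, shared
#' across all of its systems, and its aman selling price is the household
#' rice price P_r. Output always satisfies [validate_survey()].
#'
#' @param config Generator configuration, see [default_config()].
#' @param seed Integer seed; overrides `config$seed`. Same seed, same output.
#' @return A validated survey tibble.
#' @export
generate_survey <- function(config = default_config(), seed = NULL) {
  validate_generator_config(config)
  seed <- seed %||% config$seed
  if (is.null(seed)) abort("a seed is required (config$seed or seed argument)")

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  family <- config$family
  sigma <- if (family == "degenerate") 0 else config$household_sigma
  elasticity <- config$input_yield_elasticity %||% 0
  out <- list()

  for (sname in names(config$strata)) {
    st <- config$strata[[sname]]
    n_hh <- st$n_households
    if (n_hh == 0) next
    hh_id <- sprintf("%s_%04d", toupper(substr(sname, 1, 1)), seq_len(n_hh))
    mult <- if (sigma > 0) {
      rlnorm(n_hh, meanlog = -sigma^2 / 2, sdlog = sigma)
    } else rep(1, n_hh)

    aman <- draw_crop_block(st$crops$aman_rice, mult, family,
                            elasticity, sigma)
    p_r <- aman$crop_price

    systems <- names(st$prevalence)
    for (sys in systems) {
      members <- if (sys == "FFA") seq_len(n_hh) else {
        which(rbinom(n_hh, 1, st$prevalence[[sys]]) == 1)
      }
      if (length(members) == 0) next
      crop <- unname(croppsi_systems[sys])
      rabi <- if (crop == "fallow") {
        fallow_block(length(members))
      } else {
        draw_crop_block(st$crops[[crop]], mult[members], family,
                        elasticity, sigma)
      }
      base <- tibble::tibble(
        household_id = hh_id[members],
        stratum = sname,
        system_label = sys,
        rice_price_household = p_r[members]
      )
      out[[length(out) + 1]] <- bind_rows(
        dplyr::bind_cols(base, season = "rabi", crop = crop, rabi),
        dplyr::bind_cols(base, season = "kharif1", crop = "fallow",
                         fallow_block(length(members))),
        dplyr::bind_cols(base, season = "kharif2", crop = "aman_rice",
                         aman[members, ])
      )
    }
  }

  if (length(out) == 0) {
    empty <- tibble::as_tibble(
      setNames(rep(list(numeric(0)), length(survey_required_cols)),
               survey_required_cols))
    empty$household_id <- character(0)
    empty$stratum <- character(0)
    empty$system_label <- character(0)
    empty$season <- character(0)
    empty$crop <- character(0)
    return(validate_survey(empty))
  }

  survey <- bind_rows(out) %>%
    arrange(.data$stratum, .data$household_id, .data$system_label,
            match(.data$season, croppsi_seasons)) %>%
    select(all_of(survey_required_cols))
  validate_survey(survey)
}

#' Simulate indicator rows with a single latent performance factor
#'
#' Draws `n` observations of the seven index indicators from a one-factor
#' model: each standardized indicator is `lambda * f + sqrt(1 - lambda^2) * e`
#' with `f` and `e` standard normal. By default six indicators load
#' positively and the GHG footprint loads negatively, the structure the
#' index-recovery tests exercise.
#'
#' @param n Number of observations.
#' @param loadings Named vector of true loadings for the seven indicators.
#' @param seed Integer seed.
#' @return Tibble with the seven indicator columns plus `household_id`,
#'   `stratum` and `system_label` so it can be fed to [build_index()].
#' @export
simulate_latent_indicators <- function(n,
                                       loadings = c(rey = 0.6, pnp = 0.8,
                                                    pkp = 0.7,
                                                    energy_efficiency = 0.8,
                                                    bcr = 0.6,
                                                    ghg_footprint = -0.75,
                                                    hlep = 0.7),
                                       seed = 1L) {
  stopifnot(setequal(names(loadings), croppsi_index_indicators),
            all(abs(loadings) <= 1))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  f <- rnorm(n)
  cols <- lapply(croppsi_index_indicators, function(v) {
    lam <- loadings[[v]]
    lam * f + sqrt(1 - lam^2) * rnorm(n)
  })
  names(cols) <- croppsi_index_indicators
  dplyr::bind_cols(
    tibble::tibble(household_id = sprintf("S_%05d", seq_len(n)),
                   stratum = "within_polder", system_label = "FFA"),
    tibble::as_tibble(cols)
  )
}
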