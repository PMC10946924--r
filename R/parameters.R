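#' Default model parameter set
#'
#' Constructs the full set of scalar inputs of the SSB-tax dental caries
#' model: intervention effect sizes, the sugar-dose DMFT slope, caries
#' severity, disability weights and symptom durations, unit costs from the
#' societal and healthcare perspectives, intervention (tax administration)
#' costs, and analysis settings (discount rate, willingness-to-pay).
#' Central values are the published 2020-AUD estimates; the standard
#' deviations drive the probabilistic sensitivity analysis and are carried
#' in the `psa` component together with the sampling family used for each
#' parameter (gamma for costs and durations, beta for probabilities and
#' disability weights, zero-truncated normal for effect sizes).
#'
#' @param ... named overrides for any scalar component or any entry of the
#'   `psa` table addressed as `<name>_sd`.
#' @return An object of class `ssb_parameters`: a named list of scalars plus
#'   a `psa` data frame with columns `name`, `sd`, `family`.
#' @examples
#' p <- default_parameters()
#' p$net_consumption_reduction   # 0.1152
#' default_parameters(effectiveness_decay = 0.5)$effectiveness_decay
#' @export
default_parameters <- function(...) {
  values <- list(
    # intervention effect: net reduction in SSB volume under a 20% valoric tax
    net_consumption_reduction = 0.1152,
    # linear sugar-dose relationship: DMFT change per 10 g sugar/day
    dmft_slope_per_10g = 0.010,
    # caries severity: decayed teeth per incident case
    teeth_per_case = 1.64,
    # disability weights and symptom durations (YLD machinery)
    dw_caries = 0.010,
    dw_edentulism = 0.067,
    caries_duration_child_days = 28,
    caries_duration_adult_days = 55,
    adult_age_cutoff = 17,
    # healthcare unit costs, 2020 AUD
    cost_checkup = 54.69,
    cost_restoration = 189.61,
    cost_denture_pair = 2798.08,
    denture_survival_10y = 0.41,
    # societal (time and travel) unit costs
    cost_travel_per_visit = 20.71,
    time_value_per_hour = 49.22,
    minutes_travel_per_visit = 60,
    minutes_treatment_caries = 60,
    minutes_treatment_denture = 60,  # total across denture visits (see mode)
    denture_visits = 3,
    denture_minutes_mode = "total",  # "total" or "per_visit"
    restoration_cost_mode = "per_tooth",  # or "per_episode"
    private_care_share = 0.85,
    # tax legislation + administration costs, whole population
    intervention_cost_year1 = 5.8e6,
    intervention_cost_subsequent = 4.47e6,
    # analysis settings
    discount_rate = 0.03,
    wtp_per_daly = 50000,
    effectiveness_decay = 1.0,
    min_ssb_age = 2,
    grams_sugar_per_cup = 26.0
  )
  psa <- data.frame(
    name = c("net_consumption_reduction", "dmft_slope_per_10g",
             "teeth_per_case", "dw_caries", "dw_edentulism",
             "cost_checkup", "cost_restoration", "cost_denture_pair",
             "denture_survival_10y",
             "intervention_cost_year1", "intervention_cost_subsequent"),
    sd = c(0.0962, 0.028, 1.262, 0.004, 0.008,
           3.19, 17.95, 433.37, 0.064, 0.679e6, 0.679e6),
    family = c("tnorm", "tnorm", "gamma", "beta", "beta",
               "gamma", "gamma", "gamma", "beta", "gamma", "gamma"),
    stringsAsFactors = FALSE
  )
  p <- c(values, list(psa = psa))
  class(p) <- "ssb_parameters"
  dots <- list(...)
  if (length(dots)) p <- modify_parameters(p, dots)
  validate_parameters(p)
}

modify_parameters <- function(p, dots) {
  if (is.null(names(dots)) || any(names(dots) == ""))
    stop("parameter overrides must be named", call. = FALSE)
  for (nm in names(dots)) {
    if (grepl("_sd$", nm) && sub("_sd$", "", nm) %in% p$psa$name) {
      p$psa$sd[p$psa$name == sub("_sd$", "", nm)] <- dots[[nm]]
    } else if (nm %in% names(p)) {
      p[[nm]] <- dots[[nm]]
    } else {
      warning("unknown parameter '", nm, "' ignored", call. = FALSE)
    }
  }
  p
}

#' Validate a parameter set
#'
#' Range-checks every scalar: probabilities in \[0, 1\], costs, durations and
#' standard deviations non-negative, effectiveness decay in \[0, 1\].
#' Errors name the offending field and its value.
#'
#' @param p an `ssb_parameters` object.
#' @return `p`, invisibly unchanged, if valid.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "ssb_parameters"))
  prob_fields <- c("net_consumption_reduction", "dw_caries", "dw_edentulism",
                   "denture_survival_10y", "private_care_share",
                   "effectiveness_decay")
  for (f in prob_fields) check_prob(p[[f]], f)
  nonneg_fields <- c("dmft_slope_per_10g", "teeth_per_case",
                     "caries_duration_child_days", "caries_duration_adult_days",
                     "cost_checkup", "cost_restoration", "cost_denture_pair",
                     "cost_travel_per_visit", "time_value_per_hour",
                     "minutes_travel_per_visit", "minutes_treatment_caries",
                     "minutes_treatment_denture", "denture_visits",
                     "intervention_cost_year1", "intervention_cost_subsequent",
                     "discount_rate", "wtp_per_daly", "min_ssb_age",
                     "grams_sugar_per_cup", "adult_age_cutoff")
  for (f in nonneg_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", f, "' must be a non-negative number, got ", v,
           call. = FALSE)
  }
  if (any(p$psa$sd < 0))
    stop("parameter '", p$psa$name[which(p$psa$sd < 0)[1]],
         "_sd' must be non-negative", call. = FALSE)
  if (!p$denture_minutes_mode %in% c("total", "per_visit"))
    stop("denture_minutes_mode must be 'total' or 'per_visit'", call. = FALSE)
  if (!p$restoration_cost_mode %in% c("per_tooth", "per_episode"))
    stop("restoration_cost_mode must be 'per_tooth' or 'per_episode'",
         call. = FALSE)
  invisible(p)
}

check_prob <- function(v, field) {
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
    stop("parameter '", field, "' must be a probability in [0, 1], got ", v,
         call. = FALSE)
  invisible(v)
}

#' @export
print.ssb_parameters <- function(x, ...) {
  cat("SSB-tax dental caries model parameters\n")
  cat(sprintf("  net consumption reduction: %.4f (SD %.4f)\n",
              x$net_consumption_reduction,
              x$psa$sd[x$psa$name == "net_consumption_reduction"]))
  cat(sprintf("  DMFT slope per 10 g sugar/day: %.3f\n", x$dmft_slope_per_10g))
  cat(sprintf("  decayed teeth per case: %.2f\n", x$teeth_per_case))
  cat(sprintf("  discount rate: %.1f%%, WTP: AUD %s/DALY\n",
              100 * x$discount_rate, format(x$wtp_per_daly, big.mark = ",")))
  cat(sprintf("  %d parameters with PSA uncertainty\n", nrow(x$psa)))
  invisible(x)
}

#' Convert a multi-year probability to an annual probability
#'
#' Uses the compounding (exponential) form `1 - (1 - p)^(1/years)`, the
#' standard rate-to-probability conversion for decision models; linear
#' scaling is never used. Composing the annual probability over `years`
#' cycles recovers the multi-year probability.
#'
#' @param p_multi probability of the event over `years` years, in \[0, 1\].
#' @param years positive number of years.
#' @return the equivalent one-year probability.
#' @examples
#' annualize_probability(1 - 0.41, 10)  # annual denture failure probability
#' @export
annualize_probability <- function(p_multi, years) {
  if (!is.numeric(p_multi) || any(is.na(p_multi)) ||
      any(p_multi < 0) || any(p_multi > 1))
    stop("p_multi must be a probability in [0, 1]", call. = FALSE)
  if (!is.numeric(years) || length(years) != 1L || years < 1)
    stop("years must be >= 1", call. = FALSE)
  1 - (1 - p_multi)^(1 / years)
}

# ---- quintile profiles -------------------------------------------------

#' Construct a quintile consumption profile
#'
#' One row of the SSB consumption table by IRSD (Index of Relative
#' Socio-economic Disadvantage) quintile: the share of the quintile
#' population who consume SSBs, the mean daily consumption in cups over the
#' whole quintile population (consumers and non-consumers), and the
#' quintile's share of the total population. Quintile 1 is the most
#' disadvantaged.
#'
#' @param quintile_id integer 1-5, or the string `"total"`.
#' @param prop_consumers share of the population consuming SSBs, in \[0, 1\].
#' @param mean_cups_per_day population-mean daily SSB consumption, cups.
#' @param population_share quintile share of the total population, in \[0, 1\].
#' @return a one-row data frame of class `quintile_profile`.
#' @export
quintile_profile <- function(quintile_id, prop_consumers, mean_cups_per_day,
                             population_share) {
  if (!(identical(quintile_id, "total") ||
        (is.numeric(quintile_id) && quintile_id %in% 1:5)))
    stop("quintile_id must be 1-5 or 'total', got ", quintile_id,
         call. = FALSE)
  check_prob(prop_consumers, "prop_consumers")
  check_prob(population_share, "population_share")
  if (!is.numeric(mean_cups_per_day) || mean_cups_per_day < 0)
    stop("parameter 'mean_cups_per_day' must be >= 0, got ",
         mean_cups_per_day, call. = FALSE)
  out <- data.frame(quintile = as.character(quintile_id),
                    prop_consumers = prop_consumers,
                    mean_cups_per_day = mean_cups_per_day,
                    population_share = population_share,
                    stringsAsFactors = FALSE)
  class(out) <- c("quintile_profile", "data.frame")
  out
}

#' Validate a table of quintile profiles
#'
#' @param profiles data frame with one row per quintile (and optionally a
#'   `"total"` row) as produced by [quintile_profile()] or
#'   [generate_quintile_profiles()].
#' @return `profiles`, invisibly, if valid.
#' @export
validate_profiles <- function(profiles) {
  need <- c("quintile", "prop_consumers", "mean_cups_per_day",
            "population_share")
  miss <- setdiff(need, names(profiles))
  if (length(miss))
    stop("quintile profile table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  q <- profiles[profiles$quintile != "total", ]
  if (!setequal(q$quintile, as.character(1:5)))
    stop("quintile profiles must cover quintiles 1-5", call. = FALSE)
  for (i in seq_len(nrow(profiles))) {
    check_prob(profiles$prop_consumers[i], "prop_consumers")
    check_prob(profiles$population_share[i], "population_share")
    if (profiles$mean_cups_per_day[i] < 0)
      stop("parameter 'mean_cups_per_day' must be >= 0, got ",
           profiles$mean_cups_per_day[i], call. = FALSE)
  }
  if (abs(sum(q$population_share) - 1) > 1e-9)
    stop("quintile population shares must sum to 1, got ",
         sum(q$population_share), call. = FALSE)
  invisible(profiles)
}

# ---- epidemiological schedule ------------------------------------------

epi_schedule_columns <- function() {
  c("age", "sex", "caries_incidence", "caries_prevalence",
    "edentulism_incidence", "edentulism_prevalence", "mortality",
    "deciduous_fraction", "p_toothache", "p_attend", "p_denture_need")
}

#' Validate an epidemiological schedule
#'
#' The schedule carries, per single year of age 0-100 and sex, the annual
#' transition inputs of the Markov model: caries incidence, caries
#' prevalence at cohort entry, edentulism incidence and prevalence,
#' background mortality, the deciduous-dentition share, and the
#' care-seeking probabilities (toothache given caries, 12-month dental
#' attendance, perceived denture need). All entries must be probabilities;
#' mortality must be non-decreasing beyond age 60; the deciduous fraction
#' must be zero from age 15 upward.
#'
#' @param schedule a data frame with columns
#'   `age, sex, caries_incidence, caries_prevalence, edentulism_incidence,
#'   edentulism_prevalence, mortality, deciduous_fraction, p_toothache,
#'   p_attend, p_denture_need` covering every (age 0-100, sex) cell.
#' @return `schedule`, invisibly, if valid.
#' @export
validate_schedule <- function(schedule) {
  need <- epi_schedule_columns()
  miss <- setdiff(need, names(schedule))
  if (length(miss))
    stop("epi schedule missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cells <- expand.grid(age = 0:100, sex = c("female", "male"),
                       stringsAsFactors = FALSE)
  key_have <- paste(schedule$age, schedule$sex)
  key_need <- paste(cells$age, cells$sex)
  if (anyDuplicated(key_have))
    stop("epi schedule has duplicated (age, sex) rows", call. = FALSE)
  if (!all(key_need %in% key_have))
    stop("epi schedule missing (age, sex) cells, e.g. ",
         key_need[!key_need %in% key_have][1], call. = FALSE)
  probcols <- setdiff(need, c("age", "sex"))
  for (f in probcols) {
    v <- schedule[[f]]
    bad <- which(is.na(v) | v < 0 | v > 1)
    if (length(bad))
      stop("schedule column '", f, "' outside [0, 1] at row ", bad[1],
           " (value ", v[bad[1]], ")", call. = FALSE)
  }
  for (s in c("female", "male")) {
    m <- schedule$mortality[schedule$sex == s][order(schedule$age[schedule$sex == s])]
    if (any(diff(m[61:101]) < -1e-12))
      stop("mortality must be non-decreasing beyond age 60 (sex ", s, ")",
           call. = FALSE)
  }
  if (any(schedule$deciduous_fraction[schedule$age >= 15] != 0))
    stop("deciduous_fraction must be 0 from age 15 upward", call. = FALSE)
  invisible(schedule)
}

# ---- configuration I/O -------------------------------------------------

#' Write a full model input set to a directory
#'
#' Serializes a parameter set, an epidemiological schedule and the quintile
#' profiles as plain text: `config.yaml` (sections `exposure`,
#' `epidemiology`, `costs`, `settings`), `epi_schedule.tsv` and
#' `quintile_profiles.tsv`. [load_parameters()] reads the directory back
#' losslessly.
#'
#' @param params an `ssb_parameters` object.
#' @param schedule an epidemiological schedule (see [validate_schedule()]).
#' @param profiles a quintile profile table (see [validate_profiles()]).
#' @param dir output directory, created if needed.
#' @param population optional population table (columns `age`, `sex`,
#'   `count`), written as `population.tsv`.
#' @return `dir`, invisibly.
#' @export
write_parameters <- function(params, schedule, profiles, dir,
                             population = NULL) {
  validate_parameters(params)
  validate_schedule(schedule)
  validate_profiles(profiles)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sec <- config_sections()
  cfg <- list()
  for (s in names(sec)) {
    cfg[[s]] <- params[sec[[s]]]
  }
  # PSA spreads ride along in the section of their central value
  for (i in seq_len(nrow(params$psa))) {
    nm <- params$psa$name[i]
    s <- names(sec)[vapply(sec, function(x) nm %in% x, logical(1))]
    cfg[[s]][[paste0(nm, "_sd")]] <- params$psa$sd[i]
  }
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"), precision = 15)
  write_tsv_exact(schedule, file.path(dir, "epi_schedule.tsv"))
  write_tsv_exact(profiles, file.path(dir, "quintile_profiles.tsv"))
  if (!is.null(population))
    write_tsv_exact(population, file.path(dir, "population.tsv"))
  invisible(dir)
}

# doubles serialized with 17 significant digits parse back bit-identically
write_tsv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

config_sections <- function() {
  list(
    exposure = c("net_consumption_reduction", "dmft_slope_per_10g",
                 "grams_sugar_per_cup", "min_ssb_age", "effectiveness_decay"),
    epidemiology = c("teeth_per_case", "dw_caries", "dw_edentulism",
                     "caries_duration_child_days", "caries_duration_adult_days",
                     "adult_age_cutoff"),
    costs = c("cost_checkup", "cost_restoration", "cost_denture_pair",
              "denture_survival_10y", "cost_travel_per_visit",
              "time_value_per_hour", "minutes_travel_per_visit",
              "minutes_treatment_caries", "minutes_treatment_denture",
              "denture_visits", "denture_minutes_mode",
              "restoration_cost_mode", "private_care_share",
              "intervention_cost_year1", "intervention_cost_subsequent"),
    settings = c("discount_rate", "wtp_per_daly")
  )
}

#' Load a full model input set from a directory
#'
#' Reads `config.yaml`, `epi_schedule.tsv` and `quintile_profiles.tsv` as
#' written by [write_parameters()], fills missing optional keys with the
#' defaults of [default_parameters()], warns on unknown keys, and
#' range-checks every value. The packaged default inputs live at
#' `system.file("extdata", "default", package = "cariestax")`.
#'
#' @param dir directory containing the three input files.
#' @return a list with components `params`, `schedule`, `profiles`.
#' @examples
#' inp <- load_parameters(system.file("extdata", "default",
#'                                    package = "cariestax"))
#' inp$params$net_consumption_reduction
#' @export
load_parameters <- function(dir) {
  cfgfile <- file.path(dir, "config.yaml")
  if (!file.exists(cfgfile))
    stop("configuration file not found: ", cfgfile, call. = FALSE)
  cfg <- yaml::read_yaml(cfgfile)
  sec <- config_sections()
  miss_sec <- setdiff(names(sec), names(cfg))
  if (length(miss_sec))
    stop("configuration missing section(s): ",
         paste(miss_sec, collapse = ", "), call. = FALSE)
  p <- default_parameters()
  mandatory <- c("net_consumption_reduction", "dmft_slope_per_10g",
                 "teeth_per_case", "discount_rate", "wtp_per_daly")
  flat <- unlist(cfg, recursive = FALSE)
  names(flat) <- sub("^[^.]+\\.", "", names(flat))
  miss <- setdiff(mandatory, names(flat))
  if (length(miss))
    stop("configuration missing mandatory key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  known <- c(unlist(sec, use.names = FALSE), paste0(p$psa$name, "_sd"))
  unknown <- setdiff(names(flat), known)
  if (length(unknown))
    warning("unknown configuration key(s) ignored: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  p <- modify_parameters(p, flat[intersect(names(flat), known)])
  validate_parameters(p)
  schedule <- utils::read.delim(file.path(dir, "epi_schedule.tsv"),
                                stringsAsFactors = FALSE)
  validate_schedule(schedule)
  profiles <- utils::read.delim(file.path(dir, "quintile_profiles.tsv"),
                                colClasses = c(quintile = "character"),
                                stringsAsFactors = FALSE)
  validate_profiles(profiles)
  popfile <- file.path(dir, "population.tsv")
  population <- if (file.exists(popfile))
    utils::read.delim(popfile, stringsAsFactors = FALSE) else NULL
  list(params = p, schedule = schedule, profiles = profiles,
       population = population)
}
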