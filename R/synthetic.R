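#' Specification for the synthetic input generator
#'
#' Describes the shape constraints of the generated model inputs: a
#' population of the 2020 Australian scale, a unimodal caries-incidence age
#' profile peaking in childhood/young adulthood, edentulism starting in
#' mid-life and rising with age, Gompertz-like background mortality with an
#' infant component, and an SSB consumption gradient across IRSD quintiles
#' (most disadvantaged consuming most).
#'
#' @param seed integer seed for the synthetic (perturbed) mode.
#' @param population_total total population count across ages 0-100 and
#'   both sexes.
#' @param caries_incidence_peak_age age (years) of peak caries incidence.
#' @param caries_incidence_peak annual caries incidence probability at the
#'   peak age.
#' @param caries_age_spread log-age spread of the incidence profile.
#' @param edentulism_onset_age first age with nonzero edentulism incidence.
#' @param edentulism_rate0,edentulism_slope level and exponential slope of
#'   edentulism incidence beyond the onset age.
#' @param mortality_infant,mortality_gompertz_a,mortality_gompertz_b infant
#'   mortality hazard and Gompertz level/slope of the adult hazard.
#' @param quintile_gradient length-5 multipliers (quintile 1 first) applied
#'   to mean consumption in synthetic mode; must be strictly decreasing.
#' @param p_toothache probability of toothache given an incident caries
#'   case.
#' @param p_attend_child,p_attend_adult 12-month dental attendance
#'   probabilities for children and adults.
#' @param p_denture_need probability that an edentulous person perceives a
#'   need for dentures.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       population_total = 25.7e6,
                       caries_incidence_peak_age = 12,
                       caries_incidence_peak = 0.32,
                       caries_age_spread = 1.0,
                       edentulism_onset_age = 40,
                       edentulism_rate0 = 5e-4,
                       edentulism_slope = 0.055,
                       mortality_infant = 0.003,
                       mortality_gompertz_a = 2.5e-5,
                       mortality_gompertz_b = 0.095,
                       quintile_gradient = c(1.30, 1.12, 0.95, 0.90, 0.72),
                       p_toothache = 0.25,
                       p_attend_child = 0.65,
                       p_attend_adult = 0.55,
                       p_denture_need = 0.50) {
  spec <- list(seed = as.integer(seed),
               population_total = population_total,
               caries_incidence_peak_age = caries_incidence_peak_age,
               caries_incidence_peak = caries_incidence_peak,
               caries_age_spread = caries_age_spread,
               edentulism_onset_age = edentulism_onset_age,
               edentulism_rate0 = edentulism_rate0,
               edentulism_slope = edentulism_slope,
               mortality_infant = mortality_infant,
               mortality_gompertz_a = mortality_gompertz_a,
               mortality_gompertz_b = mortality_gompertz_b,
               quintile_gradient = quintile_gradient,
               p_toothache = p_toothache,
               p_attend_child = p_attend_child,
               p_attend_adult = p_attend_adult,
               p_denture_need = p_denture_need)
  class(spec) <- "synth_spec"
  validate_synth_spec(spec)
}

validate_synth_spec <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  for (f in c("caries_incidence_peak", "mortality_infant", "p_toothache",
              "p_attend_child", "p_attend_adult", "p_denture_need"))
    check_prob(spec[[f]], f)
  if (spec$population_total <= 0)
    stop("population_total must be positive", call. = FALSE)
  if (length(spec$quintile_gradient) != 5L ||
      any(diff(spec$quintile_gradient) >= 0))
    stop("quintile_gradient must be 5 strictly decreasing multipliers",
         call. = FALSE)
  invisible(spec)
}

# deciduous share of the dentition: fully deciduous to age 5, mixed
# dentition 6-14 (linear hand-over to the permanent dentition), 0 from 15
deciduous_fraction_age <- function(age) {
  ifelse(age <= 5, 1, ifelse(age >= 15, 0, (15 - age) / 10))
}

synth_curves <- function(spec, wiggle) {
  # wiggle: named multiplicative perturbations of the shape parameters
  ages <- 0:100
  peak_age <- spec$caries_incidence_peak_age * wiggle["peak_age"]
  peak <- min(1, spec$caries_incidence_peak * wiggle["peak"])
  spread <- spec$caries_age_spread * wiggle["spread"]
  caries <- peak * exp(-0.5 * (log((ages + 1) / (peak_age + 1)) / spread)^2)
  onset <- spec$edentulism_onset_age * wiggle["onset"]
  edent <- ifelse(ages < onset, 0,
                  pmin(1, spec$edentulism_rate0 * wiggle["edent0"] *
                         exp(spec$edentulism_slope * (ages - onset))))
  mort_haz <- spec$mortality_infant * wiggle["inf"] * exp(-ages) +
    spec$mortality_gompertz_a * wiggle["gomp"] *
      exp(spec$mortality_gompertz_b * ages)
  mort <- pmin(1, 1 - exp(-mort_haz))
  list(ages = ages, caries = pmin(1, caries), edent = edent, mort = mort)
}

#' Generate a synthetic epidemiological schedule
#'
#' Builds the full (age 0-100, sex) table of annual model inputs with the
#' shape the analysis assumes: a smooth unimodal caries-incidence profile
#' peaking in childhood/young adulthood, edentulism incidence zero before
#' the onset age and rising afterwards, Gompertz-like mortality (slightly
#' higher for males), a deciduous-dentition share declining linearly to
#' zero across the mixed-dentition ages 6-14, and flat care-seeking
#' probabilities. Edentulism prevalence at cohort entry is accumulated
#' from the incidence curve; caries prevalence at entry is the steady
#' state implied by incidence and the care-seeking recovery fraction.
#'
#' `mode = "fixture"` is fully deterministic (no random number generation);
#' `mode = "synthetic"` perturbs the curve-shape parameters with seeded
#' lognormal noise, so profiles stay smooth but vary across seeds.
#'
#' @param spec a [synth_spec()].
#' @param mode `"fixture"` or `"synthetic"`.
#' @return an epi schedule data frame (see [validate_schedule()]).
#' @examples
#' sched <- generate_epi_schedule(synth_spec())
#' subset(sched, age == 12 & sex == "female")
#' @export
generate_epi_schedule <- function(spec = synth_spec(),
                                  mode = c("fixture", "synthetic")) {
  mode <- match.arg(mode)
  validate_synth_spec(spec)
  wnames <- c("peak_age", "peak", "spread", "onset", "edent0", "inf", "gomp",
              "tooth", "attend", "need")
  if (mode == "fixture") {
    wiggle <- stats::setNames(rep(1, length(wnames)), wnames)
  } else {
    rs <- local({
      set.seed(spec$seed)
      stats::rlnorm(length(wnames), 0, 0.08)
    })
    wiggle <- stats::setNames(rs, wnames)
  }
  cur <- synth_curves(spec, wiggle)
  ages <- cur$ages
  out <- list()
  for (sex in c("female", "male")) {
    sex_mort <- if (sex == "male") 1.25 else 0.85
    mort <- pmin(1, cur$mort * sex_mort)
    caries <- cur$caries
    edent <- cur$edent * if (sex == "male") 0.95 else 1.05
    edent <- pmin(1, edent)
    p_tooth <- min(1, spec$p_toothache * wiggle["tooth"])
    p_att <- pmin(1, ifelse(ages < 18, spec$p_attend_child,
                            spec$p_attend_adult) * wiggle["attend"])
    p_need <- min(1, spec$p_denture_need * wiggle["need"])
    # prevalence at entry: edentulism accumulated from incidence;
    # caries steady state of incidence vs care-seeking recovery
    edent_prev <- 1 - cumprod(c(1, 1 - edent))[seq_along(ages)]
    recov <- p_tooth + (1 - p_tooth) * p_att
    caries_prev <- caries / pmax(caries + recov, 1e-12)
    out[[sex]] <- data.frame(
      age = ages, sex = sex,
      caries_incidence = caries,
      caries_prevalence = caries_prev,
      edentulism_incidence = edent,
      edentulism_prevalence = edent_prev,
      mortality = mort,
      deciduous_fraction = deciduous_fraction_age(ages),
      p_toothache = p_tooth,
      p_attend = p_att,
      p_denture_need = p_need,
      stringsAsFactors = FALSE)
  }
  sched <- rbind(out$female, out$male)
  rownames(sched) <- NULL
  validate_schedule(sched)
  sched
}

#' Generate SSB consumption profiles by IRSD quintile
#'
#' In `"fixture"` mode returns the published survey values exactly: mean
#' daily consumption of 1.41, 1.18, 0.94, 1.02 and 0.72 cups for quintiles
#' 1-5 (1.07 for the total population) and consumer shares of 44.7, 41.2,
#' 38.3, 34.2 and 29.0% (37.2% total), with equal population shares of 0.2
#' per quintile. In `"synthetic"` mode, consumption follows the spec's
#' strictly decreasing quintile gradient with seeded perturbations that
#' preserve the ordering.
#'
#' @param spec a [synth_spec()].
#' @param mode `"fixture"` or `"synthetic"`.
#' @param include_total include a `"total"` row (population-share-weighted
#'   mean in synthetic mode).
#' @return a data frame of quintile profiles (see [validate_profiles()]).
#' @examples
#' generate_quintile_profiles(synth_spec())
#' @export
generate_quintile_profiles <- function(spec = synth_spec(),
                                       mode = c("fixture", "synthetic"),
                                       include_total = TRUE) {
  mode <- match.arg(mode)
  validate_synth_spec(spec)
  if (mode == "fixture") {
    cups <- c(1.41, 1.18, 0.94, 1.02, 0.72)
    prop <- c(0.447, 0.412, 0.383, 0.342, 0.290)
    cups_tot <- 1.07
    prop_tot <- 0.372
    share <- rep(0.2, 5)
  } else {
    base <- local({
      set.seed(spec$seed + 11L)
      stats::rlnorm(5, 0, 0.05)
    })
    cups <- 0.9 * spec$quintile_gradient * base
    # enforce the strict gradient contract even after perturbation
    cups <- sort(cups, decreasing = TRUE) - (0:4) * 1e-9
    prop <- pmin(1, 0.30 * spec$quintile_gradient^0.6)
    share <- rep(0.2, 5)
    cups_tot <- sum(cups * share)
    prop_tot <- sum(prop * share)
  }
  prof <- data.frame(quintile = as.character(1:5),
                     prop_consumers = prop,
                     mean_cups_per_day = cups,
                     population_share = share,
                     stringsAsFactors = FALSE)
  if (include_total)
    prof <- rbind(prof, data.frame(quintile = "total",
                                   prop_consumers = prop_tot,
                                   mean_cups_per_day = cups_tot,
                                   population_share = 1,
                                   stringsAsFactors = FALSE))
  validate_profiles(prof)
  prof
}

#' Generate a population table by single year of age and sex
#'
#' A stationary-population age pyramid: counts proportional to survival to
#' each age under the spec's mortality curve, split 50/50 by sex, scaled
#' and rounded (largest-remainder) so the grand total equals
#' `spec$population_total` exactly. Fixture mode is deterministic;
#' synthetic mode adds seeded age-level jitter before rescaling.
#'
#' @param spec a [synth_spec()].
#' @param mode `"fixture"` or `"synthetic"`.
#' @return a data frame with columns `age`, `sex`, `count`.
#' @examples
#' pop <- generate_population(synth_spec())
#' sum(pop$count)
#' @export
generate_population <- function(spec = synth_spec(),
                                mode = c("fixture", "synthetic")) {
  mode <- match.arg(mode)
  validate_synth_spec(spec)
  cur <- synth_curves(spec, stats::setNames(rep(1, 10),
    c("peak_age", "peak", "spread", "onset", "edent0", "inf", "gomp",
      "tooth", "attend", "need")))
  surv <- cumprod(c(1, 1 - cur$mort))[1:101]
  if (mode == "synthetic") {
    jit <- local({
      set.seed(spec$seed + 23L)
      stats::rlnorm(101, 0, 0.03)
    })
    surv <- surv * jit
  }
  w <- rep(surv / sum(surv) / 2, 2)
  target <- round(spec$population_total)
  raw <- w * target
  counts <- floor(raw)
  rem <- target - sum(counts)
  if (rem > 0) {
    idx <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[idx] <- counts[idx] + 1
  }
  data.frame(age = rep(0:100, 2),
             sex = rep(c("female", "male"), each = 101),
             count = counts,
             stringsAsFactors = FALSE)
}

#' Generate a complete, internally consistent model input set
#'
#' Convenience wrapper bundling [generate_epi_schedule()],
#' [generate_quintile_profiles()], [generate_population()] and
#' [default_parameters()].
#'
#' @param spec a [synth_spec()].
#' @param mode `"fixture"` or `"synthetic"`.
#' @param ... parameter overrides passed to [default_parameters()].
#' @return a list with `params`, `schedule`, `profiles`, `population`.
#' @export
generate_inputs <- function(spec = synth_spec(),
                            mode = c("fixture", "synthetic"), ...) {
  mode <- match.arg(mode)
  list(params = default_parameters(...),
       schedule = generate_epi_schedule(spec, mode),
       profiles = generate_quintile_profiles(spec, mode),
       population = generate_population(spec, mode))
}
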