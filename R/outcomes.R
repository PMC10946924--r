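#' Decayed teeth from incident caries cases
#'
#' Each new caries case carries a mean caries severity of
#' `teeth_per_case` decayed teeth (1.64 centrally).
#'
#' @param new_cases expected incident cases.
#' @param teeth_per_case mean decayed teeth per case.
#' @return expected decayed-teeth count.
#' @export
decayed_teeth <- function(new_cases, teeth_per_case) {
  if (any(new_cases < 0) || any(teeth_per_case < 0))
    stop("decayed_teeth inputs must be non-negative", call. = FALSE)
  new_cases * teeth_per_case
}

#' Years lived with disability for one symptomatic caries episode
#'
#' Disability weight for symptomatic dental caries times the symptom
#' duration in years: 28 days for children (ages below the adult cutoff,
#' 17) and 55 days for adults. Only toothache (symptomatic) episodes
#' accrue this YLD.
#'
#' @param age age in years at the episode.
#' @param params an `ssb_parameters` object.
#' @return DALYs (YLD) per symptomatic episode.
#' @export
yld_caries_episode <- function(age, params = default_parameters()) {
  dur <- ifelse(age < params$adult_age_cutoff,
                params$caries_duration_child_days,
                params$caries_duration_adult_days)
  params$dw_caries * dur / 365
}

#' Years lived with disability from edentulism
#'
#' The edentulism disability weight is applied constantly over the time
#' spent edentulous.
#'
#' @param person_years (half-cycle-corrected) person-years in the
#'   edentulous state.
#' @param dw disability weight for edentulism.
#' @return DALYs (YLD).
#' @export
yld_edentulism <- function(person_years, dw) {
  if (any(person_years < 0)) stop("person_years must be >= 0", call. = FALSE)
  check_prob(dw, "dw_edentulism")
  dw * person_years
}

#' Cost of one treated dental episode
#'
#' For a caries episode, the healthcare perspective charges a dental
#' check-up plus restorations (scaling with the number of decayed teeth
#' under the default `per_tooth` mode); the societal perspective adds the
#' return-trip travel cost and the opportunity value of travel and
#' treatment time. Children accrue the same time and travel costs as
#' adults (an accompanying parent/guardian). For a denture episode, the
#' healthcare perspective charges a pair of full upper and lower dentures;
#' the societal perspective adds travel and time over the denture visit
#' schedule.
#'
#' @param n_teeth decayed teeth restored in the episode (caries episodes).
#' @param age age in years (carried for interface symmetry; time and
#'   travel costs do not vary with age).
#' @param params an `ssb_parameters` object.
#' @param perspective `"healthcare"` or `"societal"`.
#' @param type `"caries"` or `"denture"`.
#' @return AUD cost per treated episode.
#' @examples
#' episode_costs(1.64, 30, perspective = "societal")
#' @export
episode_costs <- function(n_teeth, age = 30, params = default_parameters(),
                          perspective = c("healthcare", "societal"),
                          type = c("caries", "denture")) {
  if (!is.character(perspective) ||
      !all(perspective %in% c("healthcare", "societal")))
    stop("unknown perspective: ", paste(perspective, collapse = ", "),
         call. = FALSE)
  perspective <- match.arg(perspective)
  type <- match.arg(type)
  if (any(n_teeth < 0)) stop("n_teeth must be >= 0", call. = FALSE)
  if (type == "caries") {
    teeth_factor <- if (params$restoration_cost_mode == "per_tooth")
      n_teeth else as.numeric(n_teeth > 0)
    hc <- params$cost_checkup + teeth_factor * params$cost_restoration
    extra <- params$cost_travel_per_visit + params$time_value_per_hour *
      (params$minutes_travel_per_visit + params$minutes_treatment_caries) / 60
  } else {
    hc <- params$cost_denture_pair + 0 * n_teeth
    v <- params$denture_visits
    treat_min <- if (params$denture_minutes_mode == "total")
      params$minutes_treatment_denture
    else params$minutes_treatment_denture * v
    extra <- v * params$cost_travel_per_visit + params$time_value_per_hour *
      (v * params$minutes_travel_per_visit + treat_min) / 60
  }
  if (perspective == "healthcare") hc else hc + extra
}

#' Care-seeking fractions for incident caries and edentulism
#'
#' Everyone experiencing toothache has the caries restored; of the
#' remainder, those who attended a dental practitioner within 12 months
#' also have it restored. Treated cases return to caries free. Edentulous
#' persons who perceive a need for dentures receive them.
#'
#' @param flows data frame with columns `new_caries` and (optionally)
#'   `new_edentulous` and/or `edentulous` occupancy, plus `age` and `sex`
#'   for the schedule lookup.
#' @param schedule epi schedule supplying `p_toothache`, `p_attend` and
#'   `p_denture_need` by age and sex.
#' @return `flows` with added columns `toothache_cases`, `treated_caries`
#'   and, where edentulism columns are present, `denture_treated`.
#' @export
apply_care_seeking <- function(flows, schedule) {
  key <- paste(schedule$age, schedule$sex)
  i <- match(paste(flows$age, flows$sex), key)
  if (anyNA(i))
    stop("schedule missing (age, sex) cells required by flows",
         call. = FALSE)
  pt <- schedule$p_toothache[i]
  pa <- schedule$p_attend[i]
  pn <- schedule$p_denture_need[i]
  flows$toothache_cases <- flows$new_caries * pt
  flows$treated_caries <- flows$new_caries * (pt + (1 - pt) * pa)
  if (!is.null(flows$new_edentulous))
    flows$denture_treated <- flows$new_edentulous * pn
  else if (!is.null(flows$edentulous))
    flows$denture_treated <- flows$edentulous * pn
  flows
}

#' Discount an annual series
#'
#' Costs and outcomes incurred from year 2 onward are discounted at the
#' annual rate; year 1 is expressed in present (2020) value already, so
#' the year-`t` factor is `(1 + rate)^-(t - 1)`.
#'
#' @param values numeric vector of annual amounts, element `t` being
#'   year `t`.
#' @param rate annual discount rate (0.03 default in the analysis).
#' @return the discounted total.
#' @examples
#' discount(c(0, 100), 0.03)  # 100 in year 2 -> 97.09
#' @export
discount <- function(values, rate) {
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  sum(values * discount_factors(length(values), rate))
}

discount_factors <- function(horizon, rate) {
  (1 + rate)^-(seq_len(horizon) - 1)
}

#' Intervention (tax administration) cost stream
#'
#' Passing legislation and implementing the tax costs AUD 5.8M in the
#' first year and AUD 4.47M in each subsequent year, whole-population
#' scale; quintile-level runs carry their population share of it. The
#' control arm carries no intervention cost.
#'
#' @param horizon number of annual cycles.
#' @param params an `ssb_parameters` object.
#' @param share population share of the modelled group (1 for the total
#'   population).
#' @param arm `"intervention"` or `"no_intervention"`.
#' @return undiscounted AUD per year, length `horizon`.
#' @export
intervention_cost_stream <- function(horizon, params = default_parameters(),
                                     share = 1,
                                     arm = c("intervention",
                                             "no_intervention")) {
  arm <- match.arg(arm)
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  if (arm == "no_intervention") return(numeric(horizon))
  c(params$intervention_cost_year1,
    rep(params$intervention_cost_subsequent, horizon - 1)) * share
}

#' Accrue outcomes and costs for one simulated arm
#'
#' Converts the population event streams of [run_population()] into
#' decayed teeth, DALYs (caries toothache YLD plus edentulism YLD) and
#' discounted and undiscounted societal and healthcare costs, per profile
#' group and per cycle. Treated caries episodes accrue check-up,
#' restoration, travel and time costs; treated edentulous persons accrue
#' denture provision at onset and annual denture replacement with the
#' annualized denture-failure probability; the intervention arm
#' additionally accrues the tax administration cost stream.
#'
#' @param streams a `population_streams` object.
#' @param params an `ssb_parameters` object.
#' @param profiles the quintile profile table used for the run (supplies
#'   population shares for the intervention cost split).
#' @return an object of class `arm_result`: `totals` (one row per group,
#'   discounted and undiscounted societal cost, healthcare cost, decayed
#'   teeth and DALYs) and `cycle` (per-group-by-cycle matrices).
#' @export
arm_result <- function(streams, params, profiles) {
  stopifnot(inherits(streams, "population_streams"))
  validate_parameters(params)
  Tn <- streams$horizon
  groups <- streams$groups
  shares <- profiles$population_share[match(groups, profiles$quintile)]
  teeth <- decayed_teeth(streams$new_cases, params$teeth_per_case)
  # caries treatment costs per treated episode
  hc_caries_unit <- episode_costs(params$teeth_per_case, params = params,
                                  perspective = "healthcare")
  soc_extra_caries <- episode_costs(params$teeth_per_case, params = params,
                                    perspective = "societal") - hc_caries_unit
  hc_caries <- streams$treated * hc_caries_unit
  tt_caries <- streams$treated * soc_extra_caries
  # denture episodes: provision at treated onset + annual replacement
  p_replace <- annualize_probability(1 - params$denture_survival_10y, 10)
  denture_eps <- streams$new_edentulous_treated +
    streams$edent_py_treated * p_replace
  hc_dent_unit <- episode_costs(0, params = params,
                                perspective = "healthcare",
                                type = "denture")
  soc_extra_dent <- episode_costs(0, params = params,
                                  perspective = "societal",
                                  type = "denture") - hc_dent_unit
  hc_denture <- denture_eps * hc_dent_unit
  tt_denture <- denture_eps * soc_extra_dent
  # intervention costs per group
  int_cost <- matrix(0, length(groups), Tn,
                     dimnames = list(groups, NULL))
  for (g in seq_along(groups))
    int_cost[g, ] <- intervention_cost_stream(Tn, params, shares[g],
                                              streams$arm)
  healthcare <- hc_caries + hc_denture + int_cost
  time_travel <- tt_caries + tt_denture
  societal <- healthcare + time_travel
  # DALYs: symptomatic caries episodes by age group + edentulism occupancy
  yld_child <- params$dw_caries * params$caries_duration_child_days / 365
  yld_adult <- params$dw_caries * params$caries_duration_adult_days / 365
  dalys <- streams$toothache_child * yld_child +
    streams$toothache_adult * yld_adult +
    yld_edentulism(streams$edent_py, params$dw_edentulism)
  disc <- discount_factors(Tn, params$discount_rate)
  tot <- function(m, discounted) {
    if (discounted) as.vector(m %*% disc) else rowSums(m)
  }
  totals <- data.frame(
    group = groups,
    societal = tot(societal, TRUE),
    healthcare = tot(healthcare, TRUE),
    teeth = tot(teeth, TRUE),
    dalys = tot(dalys, TRUE),
    societal_undisc = tot(societal, FALSE),
    healthcare_undisc = tot(healthcare, FALSE),
    teeth_undisc = tot(teeth, FALSE),
    dalys_undisc = tot(dalys, FALSE),
    stringsAsFactors = FALSE)
  structure(list(arm = streams$arm, horizon = Tn, groups = groups,
                 totals = totals,
                 cycle = list(societal = societal, healthcare = healthcare,
                              time_travel = time_travel, teeth = teeth,
                              dalys = dalys, intervention_cost = int_cost,
                              treated = streams$treated,
                              denture_episodes = denture_eps)),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm result (%s, %d-year horizon)\n", x$arm, x$horizon))
  tt <- x$totals
  tt$societal <- round(tt$societal)
  tt$healthcare <- round(tt$healthcare)
  tt$teeth <- round(tt$teeth)
  tt$dalys <- round(tt$dalys, 1)
  print(tt[, c("group", "societal", "healthcare", "teeth", "dalys")],
        row.names = FALSE)
  invisible(x)
}
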