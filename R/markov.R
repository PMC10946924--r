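#' Model run settings
#'
#' @param horizon_years simulation horizon in annual cycles (10 for the
#'   10-year scenario, 100 for the lifetime scenario).
#' @param n_draws number of Monte Carlo parameter draws for the
#'   probabilistic sensitivity analysis.
#' @param seed integer seed; every random stream in a run derives from it.
#' @param half_cycle_correction if `TRUE` (default), state-occupancy
#'   rewards are accrued with trapezoidal (within-cycle) weighting.
#' @return a `model_settings` list.
#' @export
model_settings <- function(horizon_years = 10, n_draws = 2000, seed = 1L,
                           half_cycle_correction = TRUE) {
  if (horizon_years < 1) stop("horizon_years must be >= 1", call. = FALSE)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  structure(list(horizon_years = as.integer(horizon_years),
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "model_settings")
}

state_names <- function() c("caries_free", "caries", "edentulous", "dead")

#' One annual cycle of the four-state caries model
#'
#' Advances a state-occupancy vector over the states caries free, dental
#' caries, edentulism and dead, applying competing events in a fixed
#' within-cycle order: background death first (from all living states),
#' then edentulism onset (from caries free and caries; edentulous persons
#' are no longer susceptible to caries), then caries incidence (from
#' caries free, scaled by the intervention multiplier), then recovery of
#' treated caries back to caries free. Dead is absorbing.
#'
#' @param state numeric occupancy over
#'   `c("caries_free", "caries", "edentulous", "dead")`, summing to 1.
#' @param mortality,edentulism,caries annual event probabilities.
#' @param recovery fraction of the caries state treated and returned to
#'   caries free within the cycle (care-seeking fraction).
#' @param multiplier intervention multiplier on caries incidence.
#' @return a list with `state` (end-of-cycle occupancy) and `flows`
#'   (`deaths`, `new_edentulous`, `new_caries`, `recovered` — expected
#'   events per person this cycle).
#' @export
transition <- function(state, mortality, edentulism, caries, recovery,
                       multiplier = 1) {
  if (length(state) != 4L || any(state < 0))
    stop("state must be 4 non-negative occupancies", call. = FALSE)
  if (abs(sum(state) - 1) > 1e-8)
    stop("state occupancy must sum to 1, got ", sum(state), call. = FALSE)
  for (v in c(mortality, edentulism, caries, recovery, multiplier))
    if (v < 0 || v > 1) stop("hazards must lie in [0, 1]", call. = FALSE)
  f <- state[1]; c_ <- state[2]; e <- state[3]; d <- state[4]
  deaths <- (f + c_ + e) * mortality
  f <- f * (1 - mortality); c_ <- c_ * (1 - mortality)
  e <- e * (1 - mortality); d <- d + deaths
  new_edent <- (f + c_) * edentulism
  f <- f * (1 - edentulism); c_ <- c_ * (1 - edentulism)
  e <- e + new_edent
  new_caries <- f * caries * multiplier
  f <- f - new_caries; c_ <- c_ + new_caries
  recovered <- c_ * recovery
  c_ <- c_ - recovered; f <- f + recovered
  out <- c(f, c_, e, d)
  if (abs(sum(out) - sum(state)) > 1e-8)
    stop("internal consistency error: occupancy drift ",
         sum(out) - sum(state), call. = FALSE)
  list(state = stats::setNames(out, state_names()),
       flows = list(deaths = deaths, new_edentulous = new_edent,
                    new_caries = new_caries, recovered = recovered))
}

schedule_lookup <- function(schedule) {
  # dense (age, sex) -> row arrays for O(1) hazard lookup
  idx <- schedule$age * 2L + ifelse(schedule$sex == "male", 2L, 1L)
  ord <- order(idx)
  s <- schedule[ord, ]
  list(idx = function(age, sex) age * 2L + ifelse(sex == "male", 2L, 1L),
       tab = s)
}

initial_state <- function(schedule_row) {
  e0 <- schedule_row$edentulism_prevalence
  c0 <- (1 - e0) * schedule_row$caries_prevalence
  stats::setNames(c(1 - e0 - c0, c0, e0, 0), state_names())
}

#' Simulate one age-sex-quintile cohort
#'
#' Runs a single cohort from its starting age through annual cycles.
#' Cycle-0 occupancy is initialized from prevalence at entry (edentulism
#' prevalence; the remainder split between caries and caries free by
#' caries prevalence). The cohort ages one year per cycle with hazards
#' looked up at its current age, and is simulated for
#' `min(horizon, 101 - start_age)` cycles, so no one ages past 100;
#' survivors at the cap stop accruing.
#'
#' @param start_age integer age 0-100 at entry.
#' @param sex `"female"` or `"male"`.
#' @param quintile quintile label matching a column of `effect`.
#' @param arm `"intervention"` or `"no_intervention"`; under the control
#'   arm the incidence multiplier is 1 regardless of `effect`.
#' @param params an `ssb_parameters` object.
#' @param schedule epi schedule (see [validate_schedule()]).
#' @param effect an `incidence_effect` matrix from
#'   [build_incidence_effect()], or `NULL` for multiplier 1.
#' @param horizon number of annual cycles requested.
#' @return a `cohort_trace` data frame: one row per cycle 0..T with the
#'   four occupancies and the per-person event flows.
#' @export
run_cohort <- function(start_age, sex, quintile, arm = "intervention",
                       params = default_parameters(), schedule,
                       effect = NULL, horizon = 10) {
  if (start_age < 0 || start_age > 100)
    stop("start_age must be in 0-100", call. = FALSE)
  n_cyc <- min(horizon, 101 - start_age)
  rows <- schedule[schedule$sex == sex, ]
  rows <- rows[order(rows$age), ]
  if (nrow(rows) != 101L)
    stop("schedule does not cover ages 0-100 for sex ", sex, call. = FALSE)
  st <- initial_state(rows[rows$age == start_age, ])
  trace <- data.frame(cycle = 0:n_cyc, age = start_age + 0:n_cyc,
                      caries_free = NA_real_, caries = NA_real_,
                      edentulous = NA_real_, dead = NA_real_,
                      new_caries = 0, new_edentulous = 0, recovered = 0,
                      deaths = 0)
  trace[1, state_names()] <- st
  for (t in seq_len(n_cyc)) {
    age <- start_age + t - 1
    r <- rows[age + 1L, ]
    mult <- if (arm == "no_intervention" || is.null(effect)) 1
            else effect[age + 1L, as.character(quintile)]
    recov <- r$p_toothache + (1 - r$p_toothache) * r$p_attend
    step <- transition(st, r$mortality, r$edentulism_incidence,
                       r$caries_incidence, recov, mult)
    st <- step$state
    trace[t + 1L, state_names()] <- st
    trace$new_caries[t + 1L] <- step$flows$new_caries
    trace$new_edentulous[t + 1L] <- step$flows$new_edentulous
    trace$recovered[t + 1L] <- step$flows$recovered
    trace$deaths[t + 1L] <- step$flows$deaths
  }
  attr(trace, "start_age") <- start_age
  attr(trace, "sex") <- sex
  attr(trace, "quintile") <- quintile
  attr(trace, "arm") <- arm
  class(trace) <- c("cohort_trace", "data.frame")
  trace
}

# ---- vectorized population engine --------------------------------------

# Precompute everything invariant across arms and PSA draws: cohort rows
# (age0 x sex x group), initial occupancies, per-cycle active indices,
# hazard lookups, effect-matrix indices and weighted group aggregation
# matrices. `run_engine()` then only performs arithmetic.
markov_context <- function(schedule, profiles, population, params,
                           horizon, half_cycle = TRUE) {
  validate_schedule(schedule)
  validate_profiles(profiles)
  groups <- profiles$quintile
  cohorts <- expand.grid(age0 = 0:100, sex = c("female", "male"),
                         group = groups, stringsAsFactors = FALSE)
  popkey <- paste(population$age, population$sex)
  cnt <- population$count[match(paste(cohorts$age0, cohorts$sex), popkey)]
  if (anyNA(cnt))
    stop("population table missing (age, sex) cells", call. = FALSE)
  share <- profiles$population_share[match(cohorts$group, profiles$quintile)]
  cohorts$weight <- cnt * share
  sched <- schedule[order(schedule$age * 2 +
                            ifelse(schedule$sex == "male", 1, 0)), ]
  sidx_of <- function(age, sex) 2L * age + ifelse(sex == "male", 2L, 1L)
  # dense arrays indexed by sidx
  arr <- function(col) {
    a <- numeric(202)
    a[sidx_of(sched$age, sched$sex)] <- sched[[col]]
    a
  }
  A <- list(mort = arr("mortality"), edent = arr("edentulism_incidence"),
            caries = arr("caries_incidence"), ptooth = arr("p_toothache"),
            pattend = arr("p_attend"), pneed = arr("p_denture_need"),
            cprev = arr("caries_prevalence"),
            eprev = arr("edentulism_prevalence"))
  s0 <- sidx_of(cohorts$age0, cohorts$sex)
  E0 <- A$eprev[s0]
  C0 <- (1 - E0) * A$cprev[s0]
  F0 <- 1 - E0 - C0
  n <- nrow(cohorts)
  gidx <- match(cohorts$group, groups)
  cutoff <- params$adult_age_cutoff
  cycles <- vector("list", horizon)
  for (t in seq_len(horizon)) {
    act <- which(t <= 101 - cohorts$age0)
    if (!length(act)) { cycles[t] <- list(NULL); next }
    age <- cohorts$age0[act] + t - 1L
    si <- sidx_of(age, cohorts$sex[act])
    W <- matrix(0, length(groups), length(act))
    W[cbind(gidx[act], seq_along(act))] <- cohorts$weight[act]
    recov <- A$ptooth[si] + (1 - A$ptooth[si]) * A$pattend[si]
    cycles[[t]] <- list(
      act = act, si = si,
      effli = (gidx[act] - 1L) * 101L + age + 1L,  # linear index into effect
      q = A$mort[si], e = A$edent[si], h = A$caries[si],
      ptooth = A$ptooth[si], pneed = A$pneed[si], recov = recov,
      child = age < cutoff, W = W)
  }
  list(n = n, groups = groups, horizon = horizon, half_cycle = half_cycle,
       F0 = F0, C0 = C0, E0 = E0, cohorts = cohorts, cycles = cycles,
       pop_by_group = as.vector(rowsum(cohorts$weight,
                                       match(cohorts$group, groups))))
}

# Run all cohorts through the horizon for one arm; `eff` is the 101 x
# n_group incidence-effect matrix. Returns per-(group, cycle) aggregate
# event streams (population-weighted expected counts).
run_engine <- function(ctx, eff) {
  n <- ctx$n; Tn <- ctx$horizon
  Fv <- ctx$F0; Cv <- ctx$C0; Ev <- ctx$E0; Dv <- numeric(n)
  ng <- length(ctx$groups)
  z <- matrix(0, ng, Tn, dimnames = list(ctx$groups, NULL))
  out <- list(new_cases = z, toothache_child = z, toothache_adult = z,
              treated = z, new_edentulous = z, new_edentulous_treated = z,
              edent_py = z, edent_py_treated = z, deaths = z, alive_py = z)
  for (t in seq_len(Tn)) {
    cyc <- ctx$cycles[[t]]
    if (is.null(cyc)) break
    i <- cyc$act
    f <- Fv[i]; c_ <- Cv[i]; e <- Ev[i]
    e_start <- e
    alive_start <- f + c_ + e
    deaths <- alive_start * cyc$q
    f <- f * (1 - cyc$q); c_ <- c_ * (1 - cyc$q); e <- e * (1 - cyc$q)
    new_edent <- (f + c_) * cyc$e
    f <- f * (1 - cyc$e); c_ <- c_ * (1 - cyc$e); e <- e + new_edent
    m <- eff[cyc$effli]
    new_cases <- f * cyc$h * m
    f <- f - new_cases; c_ <- c_ + new_cases
    recovered <- c_ * cyc$recov
    c_ <- c_ - recovered; f <- f + recovered
    Fv[i] <- f; Cv[i] <- c_; Ev[i] <- e; Dv[i] <- Dv[i] + deaths
    e_py <- if (ctx$half_cycle) (e_start + e) / 2 else e
    alive_py <- if (ctx$half_cycle) (alive_start + f + c_ + e) / 2
                else f + c_ + e
    tooth <- new_cases * cyc$ptooth
    W <- cyc$W
    out$new_cases[, t] <- W %*% new_cases
    out$toothache_child[, t] <- W %*% (tooth * cyc$child)
    out$toothache_adult[, t] <- W %*% (tooth * !cyc$child)
    out$treated[, t] <- W %*% recovered
    out$new_edentulous[, t] <- W %*% new_edent
    out$new_edentulous_treated[, t] <- W %*% (new_edent * cyc$pneed)
    out$edent_py[, t] <- W %*% e_py
    out$edent_py_treated[, t] <- W %*% (e_py * cyc$pneed)
    out$deaths[, t] <- W %*% deaths
    out$alive_py[, t] <- W %*% alive_py
  }
  out$final <- list(caries_free = Fv, caries = Cv, edentulous = Ev,
                    dead = Dv)
  out
}

#' Simulate the whole population for one arm
#'
#' Runs every (age 0-100, sex) cohort of every profile group (IRSD
#' quintiles and/or the total population) through the four-state model,
#' weighting cohorts by their population counts (quintile runs are scaled
#' by the quintile's population share). The cohort is closed: no entrants
#' after cycle 0.
#'
#' @inheritParams run_cohort
#' @param profiles quintile profile table.
#' @param population population table (`age`, `sex`, `count`).
#' @param decay retained effectiveness fraction for the intervention arm.
#' @param half_cycle_correction trapezoidal occupancy weighting for
#'   person-year rewards.
#' @return an object of class `population_streams`: per-(group, cycle)
#'   matrices of expected event counts (`new_cases`, `toothache_child`,
#'   `toothache_adult`, `treated`, `new_edentulous`,
#'   `new_edentulous_treated`, `edent_py`, `edent_py_treated`, `deaths`,
#'   `alive_py`).
#' @export
run_population <- function(arm = c("intervention", "no_intervention"),
                           params = default_parameters(), schedule, profiles,
                           population, horizon = 10,
                           decay = params$effectiveness_decay,
                           half_cycle_correction = TRUE) {
  arm <- match.arg(arm)
  ctx <- markov_context(schedule, profiles, population, params, horizon,
                        half_cycle_correction)
  eff <- build_incidence_effect(profiles, params, arm, decay)
  streams <- run_engine(ctx, unclass(eff))
  structure(c(streams, list(arm = arm, horizon = horizon,
                            groups = ctx$groups,
                            pop_by_group = ctx$pop_by_group)),
            class = "population_streams")
}
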