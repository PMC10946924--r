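#' Daily free-sugar intake from SSB consumption
#'
#' Population-mean grams of free sugar per day implied by a quintile's
#' mean daily SSB consumption. The cups value is the mean over the whole
#' quintile population (consumers and non-consumers), so the product is
#' directly the per-capita exposure.
#'
#' @param mean_cups_per_day population-mean daily SSB consumption, cups.
#'   A `quintile_profile` row may be passed instead.
#' @param grams_per_cup grams of free sugar per cup of SSB.
#' @return grams of sugar per person per day.
#' @examples
#' sugar_intake(1.07, 26)   # total-population exposure
#' @export
sugar_intake <- function(mean_cups_per_day, grams_per_cup) {
  if (is.data.frame(mean_cups_per_day))
    mean_cups_per_day <- mean_cups_per_day$mean_cups_per_day
  if (any(mean_cups_per_day < 0) || any(grams_per_cup < 0))
    stop("sugar_intake inputs must be non-negative", call. = FALSE)
  mean_cups_per_day * grams_per_cup
}

#' Tax-attributable reduction in daily sugar intake
#'
#' The 20% valoric tax reduces SSB volume by a net fraction (own- and
#' cross-price elasticity effect); an optional effectiveness-decay factor
#' retains only part of that effect in each cycle.
#'
#' @param intake grams of sugar per day before the tax.
#' @param net_reduction net fractional reduction in SSB consumption under
#'   the tax, in \[0, 1\].
#' @param decay retained effectiveness fraction, in \[0, 1\] (1 = full
#'   effect every cycle).
#' @return grams of sugar per day removed by the tax.
#' @examples
#' consumption_reduction(27.82, 0.1152, 1)
#' @export
consumption_reduction <- function(intake, net_reduction, decay = 1) {
  if (any(intake < 0)) stop("intake must be non-negative", call. = FALSE)
  check_prob(net_reduction, "net_reduction")
  check_prob(decay, "decay")
  intake * net_reduction * decay
}

#' Caries-incidence multiplier from a sugar-intake reduction
#'
#' The linear sugar-dose relationship gives the annual DMFT change per
#' 10 g of sugar per day; its fractional value is taken as an equal
#' fractional reduction in annual caries incidence (a DMFT change of 0.10
#' corresponds to a 10% incidence reduction). The same multiplier applies
#' to deciduous and permanent dentition. The result is clamped at 0, but
#' for published central inputs it stays above 0.9.
#'
#' @param sugar_reduction grams of sugar per day removed.
#' @param slope_per_10g annual DMFT change per 10 g sugar/day.
#' @return multiplicative factor in \[0, 1\] applied to caries incidence in
#'   the intervention arm.
#' @examples
#' incidence_multiplier(3.205, 0.010)
#' @export
incidence_multiplier <- function(sugar_reduction, slope_per_10g) {
  if (any(sugar_reduction < 0))
    stop("sugar_reduction must be non-negative", call. = FALSE)
  frac <- slope_per_10g * sugar_reduction / 10
  pmax(0, 1 - frac)
}

#' Build the age-, sex- and quintile-specific incidence effect
#'
#' Composes [sugar_intake()], [consumption_reduction()] and
#' [incidence_multiplier()] per quintile, expanded over ages and sexes.
#' Consumption is carried at the quintile level (the survey source has no
#' sex split), constant across ages from `min_ssb_age` up; below
#' `min_ssb_age` (ages 0-1 by default, for which no consumption data
#' exist) the multiplier is 1. Under the control arm all multipliers are 1.
#'
#' @param profiles quintile profile table (see [validate_profiles()]).
#' @param params an `ssb_parameters` object.
#' @param arm `"intervention"` or `"no_intervention"`.
#' @param decay retained effectiveness fraction; defaults to
#'   `params$effectiveness_decay`.
#' @return an object of class `incidence_effect`: a matrix with 101 age
#'   rows and one column per profile row (quintiles and/or `"total"`),
#'   identical for both sexes.
#' @export
build_incidence_effect <- function(profiles, params,
                                   arm = c("intervention", "no_intervention"),
                                   decay = params$effectiveness_decay) {
  arm <- match.arg(arm)
  validate_profiles(profiles)
  validate_parameters(params)
  check_prob(decay, "effectiveness_decay")
  ages <- 0:100
  eff <- matrix(1, nrow = 101, ncol = nrow(profiles),
                dimnames = list(age = ages, quintile = profiles$quintile))
  if (arm == "intervention") {
    for (j in seq_len(nrow(profiles))) {
      intake <- sugar_intake(profiles$mean_cups_per_day[j],
                             params$grams_sugar_per_cup)
      red <- consumption_reduction(intake, params$net_consumption_reduction,
                                   decay)
      m <- incidence_multiplier(red, params$dmft_slope_per_10g)
      eff[ages >= params$min_ssb_age, j] <- m
    }
  }
  class(eff) <- c("incidence_effect", class(eff))
  eff
}
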