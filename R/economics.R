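## Direct out-of-pocket costs by payer, discounted productivity losses, and
## the universal-health-coverage decomposition.

COST_COLS <- c("oop_public", "oop_private")

#' Cost tier of a classified PPH case
#'
#' Deterministic tier assignment: mild cases map to the mild tier; severe
#' cases to the with-/without-surgery severe tiers. Referred cases are costed
#' at the public-hospital vaginal tiers (referral is to a higher-level public
#' facility). PHC severe cases that are not referred take the PHC
#' severe-without-surgery tier (PHC has no surgery tier).
#'
#' @param severity `"none"`, `"mild"` or `"severe"`.
#' @param surgery Logical; only meaningful for severe cases.
#' @param location `"public_hospital"`, `"phc"`, `"private_hospital"`;
#'   referred cases should be passed as `location = "public_hospital"`,
#'   `mode = "vaginal"`.
#' @param mode `"vaginal"` or `"cesarean"`.
#' @param costs Cost table from a `pph_params` object.
#' @return The USD cost of that case's delivery tier.
#' @export
tier_of <- function(severity, surgery, location, mode, costs) {
  tab <- costs[[location]][[mode]]
  if (is.null(tab)) {
    stop("no cost block for location `", location, "` and mode `", mode, "`",
         call. = FALSE)
  }
  tier <- switch(severity,
    none = "no_pph",
    mild = "mild",
    severe = if (isTRUE(surgery)) "severe_surgery" else "severe",
    stop("unknown severity: ", severity, call. = FALSE))
  if (is.null(tab[[tier]])) {
    stop("no `", tier, "` tier for ", location, " ", mode, call. = FALSE)
  }
  tab[[tier]]
}

# expected cost of one severe case: surgery-share blend of the two severe tiers
severe_case_cost <- function(costs, location, mode, surgery_share) {
  if (location == "phc") {
    return(tier_of("severe", FALSE, "phc", "vaginal", costs))
  }
  surgery_share * tier_of("severe", TRUE, location, mode, costs) +
    (1 - surgery_share) * tier_of("severe", FALSE, location, mode, costs)
}

# arm-level expected out-of-pocket PPH costs by payer. The burden is the full
# tier cost of every PPH case in facility arms plus referred severe cases from
# home and PHC (costed at public-hospital vaginal tiers); unreferred home PPH
# carries no cost, and no-PPH delivery costs are excluded.
arm_costs <- function(arms, params) {
  costs <- params$costs
  surg <- params$care$surgery_severe_vaginal
  referred_cost <- severe_case_cost(costs, "public_hospital", "vaginal", surg)
  n <- nrow(arms)
  pub <- numeric(n); priv <- numeric(n)
  for (i in seq_len(n)) {
    loc <- arms$location[i]; mode <- arms$mode[i]
    if (loc == "home") {
      pub[i] <- arms$referred_severe[i] * referred_cost
    } else if (loc == "phc") {
      pub[i] <- arms$mild[i] * tier_of("mild", FALSE, "phc", "vaginal", costs) +
        (arms$severe[i] - arms$referred_severe[i]) *
          tier_of("severe", FALSE, "phc", "vaginal", costs) +
        arms$referred_severe[i] * referred_cost
    } else {
      val <- arms$mild[i] * tier_of("mild", FALSE, loc, mode, costs) +
        arms$severe[i] * severe_case_cost(costs, loc, mode, surg)
      if (loc == "public_hospital") pub[i] <- val else priv[i] <- val
    }
  }
  arms$oop_public <- pub
  arms$oop_private <- priv
  arms
}

#' Direct out-of-pocket PPH costs by payer
#'
#' @param result A `pph_cohort` from [run_cohort()].
#' @return A list with `oop_public` (public hospitals + PHC + referred cases),
#'   `oop_private` (private hospitals), `productivity_loss`, `total_burden`
#'   and `substandard_attributable_oop` (OOP incurred in substandard arms),
#'   all in USD per year.
#' @export
direct_costs <- function(result) {
  t <- result$totals
  sub <- result$arms$quality == "substandard"
  list(oop_public = t[["oop_public"]],
       oop_private = t[["oop_private"]],
       productivity_loss = t[["productivity_loss"]],
       total_burden = t[["total_burden"]],
       substandard_attributable_oop =
         sum(result$arms$oop_public[sub] + result$arms$oop_private[sub]))
}

#' Discounted productivity loss per maternal death
#'
#' Years of life lost (female life expectancy minus mean age at maternal
#' death) valued at GDP per capita and discounted, annuity-due style: the
#' first year undiscounted, whole years thereafter at `1/(1+r)^t`, and the
#' terminal fractional year weighted by its fraction.
#'
#' @param demography Demography block of a `pph_params` object.
#' @return USD per death.
#' @export
productivity_loss_per_death <- function(demography) {
  L <- demography$life_expectancy_female - demography$mean_age_maternal_death
  if (L <= 0) {
    if (L == 0) return(0)
    stop("life expectancy must exceed mean age at maternal death",
         call. = FALSE)
  }
  d <- 1 / (1 + demography$discount_rate)
  whole <- floor(L)
  frac <- L - whole
  demography$gdp_per_capita * (sum(d^(seq_len(whole) - 1)) + frac * d^whole)
}

#' Universal-health-coverage decomposition of the substandard burden
#'
#' Contrasts the baseline run with the no-substandard counterfactual
#' (scenario 1) from the perspectives of families, healthcare providers and
#' government: exposure counts read off the baseline substandard arms, and
#' excess quantities as baseline minus counterfactual.
#'
#' @param baseline Baseline `pph_cohort`.
#' @param counterfactual Scenario-1 `pph_cohort` run on the same calibrated
#'   parameters.
#' @return A list of exposure counts, excess OOP costs, deaths and
#'   transfusions, and substandard shares of PPH/severe cases and deaths.
#' @export
uhc_decomposition <- function(baseline, counterfactual) {
  b <- baseline$totals; s <- counterfactual$totals
  if (abs(b[["births"]] - s[["births"]]) > 1e-6 * b[["births"]]) {
    stop("baseline and counterfactual must share the same birth cohort",
         call. = FALSE)
  }
  excess_deaths <- b[["deaths"]] - s[["deaths"]]
  list(
    mothers_receiving_substandard = b[["substandard_mothers"]],
    pph_on_substandard = b[["substandard_pph"]],
    severe_on_substandard = b[["substandard_severe"]],
    excess_oop = (b[["oop_public"]] + b[["oop_private"]]) -
      (s[["oop_public"]] + s[["oop_private"]]),
    excess_deaths = excess_deaths,
    excess_transfusions = b[["transfusions"]] - s[["transfusions"]],
    pct_substandard_among_pph = b[["substandard_pph"]] / b[["pph"]],
    pct_substandard_among_severe = b[["substandard_severe"]] / b[["severe"]],
    pct_excess_deaths = excess_deaths / b[["deaths"]]
  )
}
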