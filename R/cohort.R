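## Expected-value evaluation of the decision tree:
## births -> stratum -> regimen -> quality -> PPH severity -> downstream care.

#' Probability that at least one regimen component is substandard
#'
#' For a multi-drug regimen whose components fail quality testing
#' independently, the chance the administered regimen contains any
#' substandard component is `1 - prod(1 - p)`.
#'
#' @param drug_probs Numeric vector of per-drug substandard proportions.
#' @return A single probability.
#' @export
combined_substandard_prob <- function(drug_probs) {
  stopifnot(all(drug_probs >= 0), all(drug_probs <= 1))
  1 - prod(1 - drug_probs)
}

# payer sector of a delivery location
location_sector <- function(location) {
  switch(location,
         public_hospital = "public", phc = "public",
         private_hospital = "private", home = "home",
         stop("unknown location: ", location, call. = FALSE))
}

# substandard proportion faced by one regimen through one supply channel
regimen_substandard_prob <- function(regimen, channel, quality) {
  q_ox <- quality$oxytocin
  q_mi <- quality$misoprostol
  switch(regimen,
    oxytocin = q_ox[[channel]],
    oxytocin_misoprostol =
      combined_substandard_prob(c(q_ox[[channel]], q_mi[[channel]])),
    misoprostol = q_mi[[channel]],
    carbetocin = 0,                # no substandard datum; modeled quality-assured
    none = NA_real_,
    stop("unknown regimen: ", regimen, call. = FALSE))
}

#' PPH probabilities for one tree branch
#'
#' Looks up the (regimen, mode) risk cell and applies the substandard risk
#' ratios when the product is substandard: `p500 * rr_pph` capped at 1, and
#' `p1000 * rr_severe` capped so that severe never exceeds total PPH.
#'
#' @param regimen One of `"oxytocin"`, `"oxytocin_misoprostol"`,
#'   `"misoprostol"`, `"carbetocin"`, `"none"`.
#' @param mode `"vaginal"` or `"cesarean"`.
#' @param quality `"quality"`, `"substandard"` or `"none"` (no prophylaxis).
#' @param risks Risk table from a `pph_params` object.
#' @param risk_ratios List with `pph` and `severe` multipliers.
#' @return Named numeric vector `c(p500 = , p1000 = )` with `p1000 <= p500`.
#' @export
pph_probs <- function(regimen, mode, quality, risks,
                      risk_ratios = list(pph = 1, severe = 1)) {
  cell <- risks[[regimen]][[mode]]
  if (is.null(cell)) {
    stop("no risk cell for regimen `", regimen, "` with mode `", mode, "`",
         call. = FALSE)
  }
  p500 <- cell$p500
  p1000 <- cell$p1000
  if (identical(quality, "substandard")) {
    p500 <- min(1, p500 * risk_ratios$pph)
    p1000 <- min(p1000 * risk_ratios$severe, p500)
  }
  c(p500 = p500, p1000 = min(p1000, p500))
}

# stratum table: one row per (rurality x location x mode), weight = share of
# all births. Scenario home-redistribution is handled by delivery weights.
stratum_table <- function(params) {
  del <- params$delivery
  rur_share <- c(urban = del$urban_fraction, rural = 1 - del$urban_fraction)
  out <- lapply(names(del$weights), function(r) {
    w <- unlist(del$weights[[r]])[STRATUM_KEYS]
    data.frame(rurality = r,
               location = unname(STRATUM_LOCATION[STRATUM_KEYS]),
               mode = unname(STRATUM_MODE[STRATUM_KEYS]),
               weight = as.numeric(w) * rur_share[[r]],
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Expand strata into regimen-by-quality tree arms
#'
#' Facility strata are split over the utilization regimens and, within each
#' regimen, into a quality-assured and a (pooled) substandard branch at the
#' channel's combined substandard probability. The home stratum follows the
#' home utilization block (no prophylaxis at baseline). Zero-weight arms are
#' kept out of the table.
#'
#' @param params A validated `pph_params` object.
#' @param scenario Optional [make_scenario()] spec applied before expansion.
#' @return A data frame with one row per arm: `rurality`, `location`, `mode`,
#'   `regimen`, `quality`, `weight` (share of all births; sums to 1).
#' @export
build_arms <- function(params, scenario = NULL) {
  if (!is.null(scenario)) params <- apply_scenario(params, scenario)
  strata <- stratum_table(params)
  rows <- vector("list", nrow(strata) * 4L)
  k <- 0L
  add <- function(s, regimen, quality, share) {
    if (share <= 0) return(invisible())
    k <<- k + 1L
    rows[[k]] <<- data.frame(
      rurality = s$rurality, location = s$location, mode = s$mode,
      regimen = regimen, quality = quality, weight = s$weight * share)
  }
  for (i in seq_len(nrow(strata))) {
    s <- strata[i, ]
    if (s$weight <= 0) next
    block <- if (s$location == "home") params$utilization$home
             else params$utilization$facility
    channel <- if (s$location == "home") "home"
               else location_sector(s$location)
    for (regimen in names(block)) {
      share <- block[[regimen]]
      if (share <= 0) next
      if (regimen == "none") {
        add(s, "none", "none", share)
      } else {
        q_sub <- regimen_substandard_prob(regimen, channel, params$quality)
        add(s, regimen, "substandard", share * q_sub)
        add(s, regimen, "quality", share * (1 - q_sub))
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Expected downstream outcomes for a table of arms
#'
#' Applies the severity split and downstream-care rules to each arm:
#' mild/severe nesting (`mild = pph - severe`), 18% referral of severe cases
#' from home and PHC, additional uterotonic treatment and blood transfusion at
#' quality-dependent rates among facility PPH cases plus referred severe cases
#' (unreferred home PPH receives neither), surgery among 20% of severe cases
#' in hospital vaginal arms and among referred severe cases, 40% diagnosis of
#' facility PPH with referred home cases counted as diagnosed, and death
#' applied to severe cases at the calibrated probability.
#'
#' @param arms Arm table from [build_arms()].
#' @param params A `pph_params` object.
#' @param births Total annual births distributed over the arms.
#' @return `arms` with expected-count columns appended.
#' @export
downstream_outcomes <- function(arms, params, births) {
  care <- params$care
  p_death <- if (is.null(care$p_death_severe)) 0 else care$p_death_severe
  n <- nrow(arms)
  p500 <- numeric(n); p1000 <- numeric(n)
  for (i in seq_len(n)) {
    p <- pph_probs(arms$regimen[i], arms$mode[i], arms$quality[i],
                   params$risks, params$risk_ratios)
    p500[i] <- p[["p500"]]; p1000[i] <- p[["p1000"]]
  }
  facility <- arms$location != "home"
  hospital_vaginal <- arms$location %in% c("public_hospital",
                                           "private_hospital") &
    arms$mode == "vaginal"
  referable <- arms$location %in% c("home", "phc")
  substandard <- arms$quality == "substandard"
  treat_rate <- ifelse(substandard, care$additional_treatment$substandard,
                       care$additional_treatment$quality)
  transfusion_rate <- ifelse(substandard, care$transfusion$substandard,
                             care$transfusion$quality)

  arms$births <- births * arms$weight
  arms$pph <- arms$births * p500
  arms$severe <- arms$births * p1000
  arms$mild <- arms$pph - arms$severe
  arms$referred_severe <- ifelse(referable, care$referral_severe * arms$severe, 0)
  eligible <- ifelse(facility, arms$pph, arms$referred_severe)
  arms$additional_treatments <- treat_rate * eligible
  arms$transfusions <- transfusion_rate * eligible
  arms$surgeries <- care$surgery_severe_vaginal *
    (ifelse(hospital_vaginal, arms$severe, 0) + arms$referred_severe)
  arms$diagnosed_pph <- ifelse(facility, care$diagnosed * arms$pph,
                               arms$referred_severe)
  arms$diagnosed_severe <- ifelse(facility, care$diagnosed * arms$severe,
                                  arms$referred_severe)
  arms$deaths <- p_death * arms$severe
  arms
}

OUTCOME_COLS <- c("births", "pph", "severe", "mild", "referred_severe",
                  "additional_treatments", "transfusions", "surgeries",
                  "diagnosed_pph", "diagnosed_severe", "deaths")

#' Run the expected-value cohort model
#'
#' Evaluates the full decision tree for one parameter set (optionally under a
#' scenario transform) and attaches direct costs and productivity losses.
#' Deterministic: identical inputs give identical outputs.
#'
#' @param params A validated `pph_params` object, normally with the severe-case
#'   death probability already calibrated (see [calibrate()]).
#' @param scenario Optional scenario spec from [make_scenario()].
#' @return An object of class `pph_cohort` with elements `arms` (arm-level
#'   expected counts and costs), `totals` (named numeric vector over all arms,
#'   including cost outcomes), and `scenario`.
#' @export
run_cohort <- function(params, scenario = NULL) {
  if (!is.null(scenario)) {
    params <- apply_scenario(params, scenario)
  }
  births <- annual_births(params$demography)
  arms <- build_arms(params)
  arms <- downstream_outcomes(arms, params, births)
  arms <- arm_costs(arms, params)
  totals <- colSums(arms[, c(OUTCOME_COLS, COST_COLS)])
  totals[["productivity_loss"]] <-
    totals[["deaths"]] * productivity_loss_per_death(params$demography)
  totals[["total_burden"]] <- totals[["oop_public"]] +
    totals[["oop_private"]] + totals[["productivity_loss"]]
  sub <- arms$quality == "substandard"
  totals[["substandard_mothers"]] <- sum(arms$births[sub])
  totals[["substandard_pph"]] <- sum(arms$pph[sub])
  totals[["substandard_severe"]] <- sum(arms$severe[sub])
  structure(list(arms = arms, totals = totals,
                 scenario = if (is.null(scenario)) make_scenario(0) else scenario),
            class = "pph_cohort")
}

#' @export
print.pph_cohort <- function(x, ...) {
  cat("<pph_cohort>", x$scenario$name, "\n")
  t <- x$totals
  cat(sprintf("  births %s | PPH %s (severe %s) | deaths %s\n",
              format(round(t[["births"]]), big.mark = ","),
              format(round(t[["pph"]]), big.mark = ","),
              format(round(t[["severe"]]), big.mark = ","),
              format(round(t[["deaths"]]), big.mark = ",")))
  cat(sprintf("  OOP public $%s | OOP private $%s | total burden $%s\n",
              format(round(t[["oop_public"]]), big.mark = ","),
              format(round(t[["oop_private"]]), big.mark = ","),
              format(round(t[["total_burden"]]), big.mark = ",")))
  invisible(x)
}
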