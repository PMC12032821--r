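## Calibration of the per-severe-case death probability to the national
## maternal mortality ratio.

#' Target annual PPH deaths implied by the maternal mortality ratio
#'
#' `annual_births x MMR/100,000 x PPH share of maternal deaths`.
#'
#' @param demography Demography block of a `pph_params` object.
#' @return Expected PPH deaths per year.
#' @export
target_pph_deaths <- function(demography) {
  annual_births(demography) * demography$mmr / 1e5 *
    demography$pph_share_of_maternal_deaths
}

#' Calibrate the death probability per severe PPH case
#'
#' Deaths are applied only to the severe (>= 1,000 ml) branch and are linear
#' in the per-case probability, so the calibrated value is the closed-form
#' ratio of target deaths to baseline severe cases. The same calibrated
#' probability is reused by every scenario, so scenario deaths move with
#' severe cases.
#'
#' @param params A validated `pph_params` object.
#' @return A list with `p_death_severe`, `target_deaths` and
#'   `achieved_deaths` (equal to the target by construction).
#' @seealso [calibrate()] to get a parameter object with the probability set.
#' @export
calibrate_death_prob <- function(params) {
  target <- target_pph_deaths(params$demography)
  params$care$p_death_severe <- 0
  base <- run_cohort(params)
  severe <- base$totals[["severe"]]
  if (severe <= 0 && target > 0) {
    stop("cannot calibrate: baseline has no severe PPH cases", call. = FALSE)
  }
  p <- if (target == 0) 0 else target / severe
  if (p > 1) {
    stop("cannot calibrate: target deaths (", format(target),
         ") exceed baseline severe cases (", format(severe), ")",
         call. = FALSE)
  }
  list(p_death_severe = p, target_deaths = target,
       achieved_deaths = p * severe)
}

#' Return a parameter object with the calibrated death probability applied
#'
#' @param params A validated `pph_params` object.
#' @return `params` with `care$p_death_severe` set and the calibration report
#'   stored as `params$calibration`.
#' @export
calibrate <- function(params) {
  cal <- calibrate_death_prob(params)
  params$care$p_death_severe <- cal$p_death_severe
  params$calibration <- cal
  params
}
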