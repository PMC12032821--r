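## Synthetic inputs for validation: random structurally-valid parameter sets,
## and an individual-level microsimulation that brute-forces the same tree the
## expected-value engine evaluates.

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

# Dirichlet-like positive weights via independent gammas
rdirichlet_like <- function(n) {
  g <- stats::rgamma(n, shape = 2) + 1e-6
  g / sum(g)
}

#' Generate a random, structurally valid parameter set
#'
#' Every invariant of the loader holds by construction: delivery mixes are
#' Dirichlet-like, risks ordered `p1000 <= p500` and inside their stated
#' ranges, substandard care proportions at least the quality-assured ones,
#' and cost tiers nondecreasing. Useful as fuzz input for the engine/oracle
#' equivalence checks.
#'
#' @param seed Integer seed.
#' @return A validated `pph_params` object.
#' @export
random_params <- function(seed) {
  set.seed(as.integer(seed))
  p <- senegal_params()
  p$country <- paste0("synthetic-", seed)

  p$demography$total_population <- runif1(1e6, 5e7)
  p$demography$crude_birth_rate <- runif1(15, 45)
  p$demography$mmr <- runif1(50, 800)
  p$demography$life_expectancy_female <- runif1(55, 80)
  p$demography$mean_age_maternal_death <-
    runif1(18, p$demography$life_expectancy_female - 10)
  p$demography$gdp_per_capita <- runif1(400, 8000)
  p$demography$discount_rate <- runif1(0, 0.08)
  p$demography$pph_share_of_maternal_deaths <- runif1(0.2, 0.5)

  p$delivery$urban_fraction <- runif1(0.1, 0.9)
  for (r in names(p$delivery$weights)) {
    p$delivery$weights[[r]] <-
      stats::setNames(as.list(rdirichlet_like(length(STRATUM_KEYS))),
                      STRATUM_KEYS)
  }

  fac <- rdirichlet_like(2)
  p$utilization$facility <- list(oxytocin = fac[1],
                                 oxytocin_misoprostol = fac[2])
  p$utilization$home <- list(none = 1)

  p$quality$oxytocin <- list(public = runif1(0, 0.6), private = runif1(0, 0.6))
  p$quality$misoprostol <- list(public = runif1(0, 0.6),
                                private = runif1(0, 0.6),
                                home = runif1(0, 0.6))

  p$risk_ratios <- list(pph = 1 + runif1(0, 0.6), severe = 1 + runif1(0, 0.6))

  for (reg in names(p$risks)) {
    for (mode in names(p$risks[[reg]])) {
      p500 <- runif1(0.02, 0.6)
      p1000 <- runif1(0.001, p500)
      p$risks[[reg]][[mode]] <- list(
        p500 = p500,
        p500_range = c(p500 * 0.8, min(1, p500 * 1.25)),
        p1000 = p1000,
        p1000_range = c(p1000 * 0.8, min(p500, p1000 * 1.25)))
    }
  }

  tq <- runif1(0.3, 0.7)
  bq <- runif1(0.1, 0.4)
  p$care$additional_treatment <- list(quality = tq,
                                      substandard = min(1, tq + runif1(0, 0.25)))
  p$care$transfusion <- list(quality = bq,
                             substandard = min(1, bq + runif1(0, 0.25)))
  p$care$surgery_severe_vaginal <- runif1(0.05, 0.4)
  p$care$referral_severe <- runif1(0.05, 0.4)
  p$care$diagnosed <- runif1(0.2, 0.7)
  p$care$p_death_severe <- NULL
  p$calibration <- NULL

  for (loc in names(p$costs)) {
    for (mode in names(p$costs[[loc]])) {
      k <- length(p$costs[[loc]][[mode]])
      tiers <- cumsum(c(runif1(5, 500), stats::runif(k - 1, 1, 300)))
      p$costs[[loc]][[mode]] <-
        stats::setNames(as.list(tiers), names(p$costs[[loc]][[mode]]))
    }
  }
  validate_params(p)
  p
}

MICROSIM_OUTCOMES <- c("pph", "severe", "mild", "referred_severe",
                       "additional_treatments", "transfusions", "surgeries",
                       "diagnosed_pph", "diagnosed_severe", "deaths")

#' Individual-level microsimulation of the decision tree
#'
#' Samples each woman's path (stratum, tree arm, PPH severity, referral,
#' treatment, transfusion, surgery, diagnosis, death) with exactly the
#' probabilities the expected-value engine applies, as a brute-force oracle.
#' Severity is sampled nested: PPH with probability `p500`, then severe given
#' PPH with probability `p1000 / p500`, so per-woman nesting
#' (death => severe => PPH) holds by construction.
#'
#' @param params A calibrated `pph_params` object.
#' @param scenario Optional scenario spec from [make_scenario()].
#' @param n_women Number of simulated women.
#' @param seed Integer seed.
#' @return A list of class `pph_microsim`: `n_women`, `counts` (named sampled
#'   counts), `proportions` (counts / n_women) and `se` (binomial standard
#'   errors of the counts).
#' @export
microsimulate <- function(params, scenario = NULL, n_women, seed) {
  stopifnot(n_women >= 1)
  if (!is.null(scenario)) params <- apply_scenario(params, scenario)
  set.seed(as.integer(seed))
  care <- params$care
  p_death <- if (is.null(care$p_death_severe)) 0 else care$p_death_severe
  arms <- build_arms(params)
  n_arm <- as.vector(stats::rmultinom(1, n_women, arms$weight))
  acc <- stats::setNames(numeric(length(MICROSIM_OUTCOMES)),
                         MICROSIM_OUTCOMES)
  for (i in seq_len(nrow(arms))) {
    n <- n_arm[i]
    if (n == 0) next
    pr <- pph_probs(arms$regimen[i], arms$mode[i], arms$quality[i],
                    params$risks, params$risk_ratios)
    facility <- arms$location[i] != "home"
    hospital_vaginal <- arms$location[i] %in%
      c("public_hospital", "private_hospital") && arms$mode[i] == "vaginal"
    substandard <- arms$quality[i] == "substandard"

    pph <- stats::rbinom(1, n, pr[["p500"]])
    p_sev_given <- if (pr[["p500"]] > 0) pr[["p1000"]] / pr[["p500"]] else 0
    severe <- stats::rbinom(1, pph, p_sev_given)
    referred <- if (arms$location[i] %in% c("home", "phc")) {
      stats::rbinom(1, severe, care$referral_severe)
    } else 0L
    eligible <- if (facility) pph else referred
    treat_rate <- if (substandard) care$additional_treatment$substandard
                  else care$additional_treatment$quality
    transfusion_rate <- if (substandard) care$transfusion$substandard
                        else care$transfusion$quality
    acc[["pph"]] <- acc[["pph"]] + pph
    acc[["severe"]] <- acc[["severe"]] + severe
    acc[["mild"]] <- acc[["mild"]] + pph - severe
    acc[["referred_severe"]] <- acc[["referred_severe"]] + referred
    acc[["additional_treatments"]] <- acc[["additional_treatments"]] +
      stats::rbinom(1, eligible, treat_rate)
    acc[["transfusions"]] <- acc[["transfusions"]] +
      stats::rbinom(1, eligible, transfusion_rate)
    acc[["surgeries"]] <- acc[["surgeries"]] +
      (if (hospital_vaginal)
         stats::rbinom(1, severe, care$surgery_severe_vaginal) else 0L) +
      stats::rbinom(1, referred, care$surgery_severe_vaginal)
    acc[["diagnosed_pph"]] <- acc[["diagnosed_pph"]] +
      (if (facility) stats::rbinom(1, pph, care$diagnosed) else referred)
    acc[["diagnosed_severe"]] <- acc[["diagnosed_severe"]] +
      (if (facility) stats::rbinom(1, severe, care$diagnosed) else referred)
    acc[["deaths"]] <- acc[["deaths"]] + stats::rbinom(1, severe, p_death)
  }
  phat <- acc / n_women
  structure(list(n_women = n_women, counts = acc, proportions = phat,
                 se = sqrt(pmax(phat * (1 - phat), 0) / n_women) * n_women),
            class = "pph_microsim")
}

#' @export
print.pph_microsim <- function(x, ...) {
  cat("<pph_microsim>", format(x$n_women, big.mark = ","), "women\n")
  print(round(x$counts))
  invisible(x)
}
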