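## Policy scenarios as declarative parameter/structure transforms.

SCENARIO_NAMES <- c(
  "0" = "Baseline",
  "1" = "No substandard uterotonics",
  "2" = "Quality misoprostol + oxytocin for facility births",
  "3" = "Quality heat-stable carbetocin for facility births",
  "4" = "Misoprostol at reported level of quality for home births",
  "5" = "Quality misoprostol for home births",
  "6" = "All deliveries happen in facilities",
  "7" = "All deliveries happen in facilities with quality-assured uterotonics"
)

#' Canonical scenario specifications
#'
#' Returns the declarative transform list for one of the eight modeled
#' situations: 0 baseline; 1 substandard proportions zeroed at facilities;
#' 2 all facility births on quality-assured oxytocin + misoprostol; 3 all
#' facility births on quality-assured heat-stable carbetocin; 4 home births
#' on misoprostol at the reported (38% substandard) quality; 5 home births on
#' quality-assured misoprostol; 6 home births redistributed proportionally to
#' the facility strata of the same rurality at baseline quality; 7 scenario 6
#' with all substandard proportions zeroed.
#'
#' @param id Integer 0 to 7.
#' @return An object of class `pph_scenario` with `id`, `name` and an ordered
#'   `transforms` list.
#' @export
make_scenario <- function(id) {
  if (length(id) != 1 || !id %in% 0:7) {
    stop("unknown scenario id: ", paste(id, collapse = ","),
         " (must be 0..7)", call. = FALSE)
  }
  id <- as.integer(id)
  transforms <- switch(as.character(id),
    "0" = list(),
    "1" = list(list(op = "zero_substandard", channels = "facility")),
    "2" = list(list(op = "set_facility_regimen",
                    regimen = "oxytocin_misoprostol"),
               list(op = "zero_substandard", channels = "facility")),
    "3" = list(list(op = "set_facility_regimen", regimen = "carbetocin"),
               list(op = "zero_substandard", channels = "facility")),
    "4" = list(list(op = "set_home_regimen", regimen = "misoprostol",
                    quality_source = "reported")),
    "5" = list(list(op = "set_home_regimen", regimen = "misoprostol",
                    quality_source = "assured")),
    "6" = list(list(op = "move_home_births")),
    "7" = list(list(op = "move_home_births"),
               list(op = "zero_substandard", channels = "all")))
  structure(list(id = id, name = SCENARIO_NAMES[[as.character(id)]],
                 transforms = transforms),
            class = "pph_scenario")
}

#' @export
print.pph_scenario <- function(x, ...) {
  cat("<pph_scenario>", x$id, "-", x$name, "\n")
  for (tr in x$transforms) {
    cat("  *", tr$op,
        paste(unlist(tr[setdiff(names(tr), "op")]), collapse = " "), "\n")
  }
  invisible(x)
}

#' Apply a scenario's transforms to a parameter object
#'
#' @param params A validated `pph_params` object.
#' @param scenario A `pph_scenario` from [make_scenario()].
#' @return The transformed `pph_params`.
#' @export
apply_scenario <- function(params, scenario) {
  if (!inherits(scenario, "pph_scenario")) scenario <- make_scenario(scenario)
  for (tr in scenario$transforms) {
    params <- switch(tr$op,
      zero_substandard = transform_zero_substandard(params, tr$channels),
      set_facility_regimen = transform_facility_regimen(params, tr$regimen),
      set_home_regimen = transform_home_regimen(params, tr$regimen,
                                                tr$quality_source),
      move_home_births = transform_move_home_births(params),
      stop("unknown scenario transform: ", tr$op, call. = FALSE))
  }
  validate_params(params)
  params
}

transform_zero_substandard <- function(params, channels) {
  chans <- switch(channels,
    facility = c("public", "private"),
    home = "home",
    all = c("public", "private", "home"),
    stop("unknown channel group: ", channels, call. = FALSE))
  for (drug in names(params$quality)) {
    for (ch in intersect(chans, names(params$quality[[drug]]))) {
      params$quality[[drug]][[ch]] <- 0
    }
  }
  params
}

transform_facility_regimen <- function(params, regimen) {
  if (!regimen %in% setdiff(REGIMENS, "none")) {
    stop("unknown facility regimen: ", regimen, call. = FALSE)
  }
  params$utilization$facility <- stats::setNames(list(1), regimen)
  params
}

transform_home_regimen <- function(params, regimen, quality_source) {
  if (!regimen %in% REGIMENS) {
    stop("unknown home regimen: ", regimen, call. = FALSE)
  }
  params$utilization$home <- stats::setNames(list(1), regimen)
  if (identical(quality_source, "assured") && regimen != "none") {
    params$quality[[regimen]][["home"]] <- 0
  }
  params
}

# home weight reallocated proportionally to the facility strata of the same
# rurality, preserving total births and the urban/rural case mix
transform_move_home_births <- function(params) {
  for (r in names(params$delivery$weights)) {
    w <- unlist(params$delivery$weights[[r]])[STRATUM_KEYS]
    fac <- setdiff(STRATUM_KEYS, "home")
    w[fac] <- w[fac] * (1 + w[["home"]] / sum(w[fac]))
    w[["home"]] <- 0
    params$delivery$weights[[r]] <- as.list(w)
  }
  params
}

#' Compare a scenario run against baseline
#'
#' @param scenario_result,baseline_result `pph_cohort` objects run on the same
#'   calibrated parameter set.
#' @return A data frame with one row per outcome: baseline and scenario
#'   values, `difference` (scenario minus baseline) and `pct_difference`
#'   (difference over baseline).
#' @export
compare_to_baseline <- function(scenario_result, baseline_result) {
  outcomes <- c("pph", "severe", "diagnosed_pph", "diagnosed_severe",
                "additional_treatments", "transfusions", "deaths",
                "total_burden", "oop_public", "oop_private",
                "productivity_loss")
  b <- baseline_result$totals[outcomes]
  s <- scenario_result$totals[outcomes]
  data.frame(scenario_id = scenario_result$scenario$id,
             scenario = scenario_result$scenario$name,
             outcome = outcomes,
             baseline = unname(b),
             value = unname(s),
             difference = unname(s - b),
             pct_difference = unname(ifelse(b == 0, 0, (s - b) / b)),
             row.names = NULL)
}

#' Run baseline and all seven scenarios
#'
#' @param params A calibrated `pph_params` object (see [calibrate()]).
#' @param ids Scenario ids to run (default 0:7; baseline is always included
#'   as the comparator).
#' @return A list with `results` (named list of `pph_cohort`s) and
#'   `comparison` (long data frame from [compare_to_baseline()] over all
#'   requested scenarios).
#' @export
run_all_scenarios <- function(params, ids = 0:7) {
  ids <- sort(unique(c(0L, as.integer(ids))))
  results <- lapply(ids, function(i) run_cohort(params, make_scenario(i)))
  names(results) <- as.character(ids)
  comparison <- do.call(rbind, lapply(results, compare_to_baseline,
                                      baseline_result = results[["0"]]))
  rownames(comparison) <- NULL
  list(results = results, comparison = comparison)
}
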