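## Report writers: tables of the baseline-vs-no-substandard comparison, the
## scenario panel, and the UHC decomposition, plus run manifests.
## Counts are rounded (half-to-even) at render time only; internal values
## stay fractional.

TABLE2_ROWS <- data.frame(
  outcome = c("pph", "severe", "diagnosed_pph", "diagnosed_severe",
              "additional_treatments", "transfusions", "deaths",
              "total_burden", "oop_public", "oop_private",
              "productivity_loss"),
  label = c("PPH >= 500 ml", "PPH >= 1,000 ml", "PPH >= 500 ml diagnosed",
            "PPH >= 1,000 ml diagnosed", "Additional uterotonic treatment",
            "Blood transfusions", "Deaths due to PPH",
            "Total economic burden of PPH", "Total OOP costs public",
            "Total OOP costs private", "Long term productivity loss"),
  kind = c(rep("health", 7), rep("economic", 4)))

#' Render the baseline vs no-substandard comparison table
#'
#' Seven health outcomes and four economic outcomes, with baseline value,
#' counterfactual value, difference and integer percent difference (computed
#' on unrounded values, then rounded).
#'
#' @param baseline Baseline `pph_cohort`.
#' @param counterfactual Scenario-1 `pph_cohort` on the same calibrated
#'   parameters.
#' @return A data frame with columns `outcome`, `kind`, `baseline`, `value`,
#'   `difference`, `pct_difference`.
#' @export
render_table2 <- function(baseline, counterfactual) {
  cmp <- compare_to_baseline(counterfactual, baseline)
  cmp <- cmp[match(TABLE2_ROWS$outcome, cmp$outcome), ]
  data.frame(outcome = TABLE2_ROWS$label, kind = TABLE2_ROWS$kind,
             baseline = round(cmp$baseline),
             value = round(cmp$value),
             difference = round(cmp$difference),
             pct_difference = round(100 * cmp$pct_difference),
             row.names = NULL)
}

#' Render the full scenario panel
#'
#' @param all_out Result of [run_all_scenarios()].
#' @return A data frame, one row per scenario x outcome, with rounded values,
#'   differences and integer percent differences.
#' @export
render_table3 <- function(all_out) {
  cmp <- all_out$comparison
  cmp <- cmp[cmp$outcome %in% TABLE2_ROWS$outcome, ]
  cmp$outcome <- TABLE2_ROWS$label[match(cmp$outcome, TABLE2_ROWS$outcome)]
  cmp$baseline <- round(cmp$baseline)
  cmp$value <- round(cmp$value)
  cmp$pct_difference <- round(100 * cmp$pct_difference)
  cmp$difference <- round(cmp$difference)
  cmp
}

#' Render the UHC-perspective table
#'
#' @param uhc Result of [uhc_decomposition()].
#' @return A data frame with `perspective`, `description`, `estimate`.
#' @export
render_table4 <- function(uhc) {
  data.frame(
    perspective = c(rep("Families", 5), "Healthcare providers",
                    rep("Governments", 3)),
    description = c(
      "Number of mothers receiving substandard uterotonics",
      "Number of PPH cases receiving substandard uterotonics",
      "Number of severe PPH cases receiving substandard uterotonics",
      "Out-of-pocket costs due to substandard uterotonics (US$)",
      "Number of additional maternal deaths from substandard uterotonics",
      "Number of additional blood transfusions from substandard uterotonics",
      "% receiving substandard uterotonics among PPH cases",
      "% receiving substandard uterotonics among severe PPH cases",
      "% of additional maternal deaths from substandard uterotonics"),
    estimate = c(
      round(uhc$mothers_receiving_substandard),
      round(uhc$pph_on_substandard),
      round(uhc$severe_on_substandard),
      round(uhc$excess_oop),
      round(uhc$excess_deaths),
      round(uhc$excess_transfusions),
      round(100 * uhc$pct_substandard_among_pph),
      round(100 * uhc$pct_substandard_among_severe),
      round(100 * uhc$pct_excess_deaths)))
}

#' Write a run manifest
#'
#' Records the config path and its MD5 hash, the scenario ids, seeds, the
#' package version and a timestamp, so a run can be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param config_path Config file the run loaded.
#' @param scenario_ids Integer vector of scenario ids.
#' @param seed Seed(s) used, if any.
#' @return Invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, config_path, scenario_ids = integer(),
                               seed = NULL) {
  manifest <- list(
    config = config_path,
    config_md5 = unname(tools::md5sum(config_path)),
    scenario_ids = as.integer(scenario_ids),
    seed = seed,
    package_version = as.character(utils::packageVersion("pphburden")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
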