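## Parameter bundle: loading, validation, normalization.
##
## All proportions are stored as fractions in [0, 1]. Config files may instead
## carry percents by setting `percent: true`; the loader rescales on read.

# canonical stratum keys, in the order used throughout
STRATUM_KEYS <- c(
  "public_hospital_vaginal", "public_hospital_cesarean", "phc_vaginal",
  "private_hospital_vaginal", "private_hospital_cesarean", "home"
)
STRATUM_LOCATION <- c(
  public_hospital_vaginal  = "public_hospital",
  public_hospital_cesarean = "public_hospital",
  phc_vaginal              = "phc",
  private_hospital_vaginal = "private_hospital",
  private_hospital_cesarean = "private_hospital",
  home                     = "home"
)
STRATUM_MODE <- c(
  public_hospital_vaginal  = "vaginal",
  public_hospital_cesarean = "cesarean",
  phc_vaginal              = "vaginal",
  private_hospital_vaginal = "vaginal",
  private_hospital_cesarean = "cesarean",
  home                     = "vaginal"
)
REGIMENS <- c("oxytocin", "oxytocin_misoprostol", "misoprostol",
              "carbetocin", "none")
COST_TIERS <- c("no_pph", "mild", "severe", "severe_surgery")

#' Load a model parameter set from a config file
#'
#' Reads a YAML or JSON configuration holding the full parameter bundle
#' (demography, delivery mix, uterotonic utilization, substandard proportions,
#' PPH risks, downstream-care proportions, cost tiers and sensitivity-analysis
#' settings), validates every invariant, and renormalizes the per-rurality
#' delivery mixes so each sums to one.
#'
#' @param config_path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated object of class `pph_params`.
#' @seealso [senegal_params()], [write_params()]
#' @export
load_params <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("config file not found: ", config_path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", config_path, ignore.case = TRUE)) {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(config_path)
  }
  as_pph_params(raw)
}

#' Build a validated parameter object from a plain list
#'
#' @param raw A list with the same structure as the packaged config files.
#' @return A `pph_params` object.
#' @export
as_pph_params <- function(raw) {
  required <- c("demography", "delivery", "utilization", "quality",
                "risk_ratios", "risks", "care", "costs")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("config is missing required key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (isTRUE(raw$percent)) raw <- rescale_percents(raw)
  raw$percent <- NULL
  if (is.null(raw$psa)) raw$psa <- list()
  raw$psa <- utils::modifyList(
    list(n_draws = 1000L, default_rel_halfwidth = 0.25), raw$psa)
  raw$delivery <- normalize_delivery_mix(raw$delivery)
  params <- structure(raw, class = "pph_params")
  validate_params(params)
  params
}

# divide every proportion-valued field by 100 (percent dialect)
rescale_percents <- function(raw) {
  pct <- function(x) x / 100
  raw$delivery$urban_fraction <- pct(raw$delivery$urban_fraction)
  raw$delivery$weights <- lapply(raw$delivery$weights, function(w) lapply(w, pct))
  raw$utilization <- lapply(raw$utilization, function(u) lapply(u, pct))
  raw$quality <- lapply(raw$quality, function(q) lapply(q, pct))
  raw$care$additional_treatment <- lapply(raw$care$additional_treatment, pct)
  raw$care$transfusion <- lapply(raw$care$transfusion, pct)
  raw$care$surgery_severe_vaginal <- pct(raw$care$surgery_severe_vaginal)
  raw$care$referral_severe <- pct(raw$care$referral_severe)
  raw$care$diagnosed <- pct(raw$care$diagnosed)
  ## risks, risk ratios, costs and demography are never expressed as percents
  raw
}

#' Renormalize the per-rurality delivery mix
#'
#' Each rurality's six stratum weights are divided by their sum so that the
#' mix is a proper distribution (published survey columns can sum to 99% or
#' 101% from rounding).
#'
#' @param delivery A delivery-mix list with `urban_fraction` and `weights`
#'   (one named six-vector per rurality).
#' @return The same list with every rurality's weights summing to one.
#' @export
normalize_delivery_mix <- function(delivery) {
  for (r in names(delivery$weights)) {
    w <- unlist(delivery$weights[[r]])[STRATUM_KEYS]
    if (anyNA(w)) {
      stop("delivery mix for ", r, " must name all strata: ",
           paste(STRATUM_KEYS, collapse = ", "), call. = FALSE)
    }
    if (any(w < 0)) {
      stop("delivery mix for ", r, " has negative weights", call. = FALSE)
    }
    s <- sum(w)
    if (s <= 0) {
      stop("delivery mix for ", r, " has all-zero weights", call. = FALSE)
    }
    delivery$weights[[r]] <- as.list(w / s)
  }
  delivery
}

#' Expected annual live births
#'
#' @param demography Demography block of a `pph_params` object.
#' @return Expected live births per year (kept fractional; no rounding).
#' @export
annual_births <- function(demography) {
  stopifnot(demography$total_population >= 0, demography$crude_birth_rate >= 0)
  demography$total_population * demography$crude_birth_rate / 1000
}

chk <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop("invalid parameter `", field, "`: ", msg, call. = FALSE)
  }
}

prop_in_01 <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)

#' Validate a parameter object
#'
#' Checks every structural invariant: proportions in \[0, 1\], risk ordering
#' p1000 <= p500 per populated cell, risk ratios >= 1, cost tiers nonnegative
#' and nondecreasing, delivery mixes normalized, and demographic sanity
#' (mean age at maternal death below female life expectancy).
#'
#' @param params A `pph_params` object.
#' @return Invisibly, `params`; errors name the offending field.
#' @export
validate_params <- function(params) {
  d <- params$demography
  for (f in c("total_population", "crude_birth_rate", "mmr",
              "life_expectancy_female", "mean_age_maternal_death",
              "gdp_per_capita", "discount_rate",
              "pph_share_of_maternal_deaths")) {
    chk(is.numeric(d[[f]]) && length(d[[f]]) == 1 && d[[f]] >= 0,
        paste0("demography$", f), "must be a single nonnegative number")
  }
  chk(d$discount_rate <= 0.2, "demography$discount_rate", "must be in [0, 0.2]")
  chk(d$mean_age_maternal_death < d$life_expectancy_female,
      "demography$mean_age_maternal_death",
      "must be below female life expectancy")
  chk(d$pph_share_of_maternal_deaths <= 1,
      "demography$pph_share_of_maternal_deaths", "must be in [0, 1]")

  del <- params$delivery
  chk(prop_in_01(del$urban_fraction), "delivery$urban_fraction",
      "must be in [0, 1]")
  for (r in names(del$weights)) {
    w <- unlist(del$weights[[r]])
    chk(abs(sum(w) - 1) < 1e-12, paste0("delivery$weights$", r),
        "must sum to 1 after normalization")
  }

  fac <- unlist(params$utilization$facility)
  chk(prop_in_01(fac) && abs(sum(fac) - 1) < 1e-9, "utilization$facility",
      "regimen shares must be proportions summing to 1")
  chk(all(names(fac) %in% REGIMENS), "utilization$facility",
      "unknown regimen name")
  hom <- unlist(params$utilization$home)
  chk(prop_in_01(hom) && abs(sum(hom) - 1) < 1e-9, "utilization$home",
      "regimen shares must be proportions summing to 1")
  chk(all(names(hom) %in% REGIMENS), "utilization$home",
      "unknown regimen name")

  for (drug in names(params$quality)) {
    chk(prop_in_01(unlist(params$quality[[drug]])),
        paste0("quality$", drug), "substandard proportions must be in [0, 1]")
  }

  rr <- params$risk_ratios
  chk(is.numeric(rr$pph) && rr$pph >= 1, "risk_ratios$pph", "must be >= 1")
  chk(is.numeric(rr$severe) && rr$severe >= 1, "risk_ratios$severe",
      "must be >= 1")

  for (reg in names(params$risks)) {
    chk(reg %in% REGIMENS, paste0("risks$", reg), "unknown regimen")
    for (mode in names(params$risks[[reg]])) {
      cell <- params$risks[[reg]][[mode]]
      lbl <- paste0("risks$", reg, "$", mode)
      chk(prop_in_01(c(cell$p500, cell$p1000, unlist(cell$p500_range),
                       unlist(cell$p1000_range))),
          lbl, "probabilities must be in [0, 1]")
      chk(cell$p1000 <= cell$p500, lbl, "requires p1000 <= p500")
      chk(cell$p500_range[1] <= cell$p500 && cell$p500 <= cell$p500_range[2],
          lbl, "p500 must lie inside its uncertainty range")
      chk(cell$p1000_range[1] <= cell$p1000 &&
            cell$p1000 <= cell$p1000_range[2],
          lbl, "p1000 must lie inside its uncertainty range")
    }
  }
  for (reg in c("misoprostol", "none")) {
    chk(is.null(params$risks[[reg]]$cesarean), paste0("risks$", reg),
        "must not define a cesarean cell")
  }

  care <- params$care
  chk(prop_in_01(unlist(care$additional_treatment)),
      "care$additional_treatment", "must be in [0, 1]")
  chk(prop_in_01(unlist(care$transfusion)), "care$transfusion",
      "must be in [0, 1]")
  chk(prop_in_01(care$surgery_severe_vaginal), "care$surgery_severe_vaginal",
      "must be in [0, 1]")
  chk(prop_in_01(care$referral_severe), "care$referral_severe",
      "must be in [0, 1]")
  chk(prop_in_01(care$diagnosed), "care$diagnosed", "must be in [0, 1]")
  if (!is.null(care$p_death_severe)) {
    chk(prop_in_01(care$p_death_severe), "care$p_death_severe",
        "must be in [0, 1]")
  }

  for (loc in names(params$costs)) {
    for (mode in names(params$costs[[loc]])) {
      tiers <- unlist(params$costs[[loc]][[mode]])
      lbl <- paste0("costs$", loc, "$", mode)
      want <- if (loc == "phc") COST_TIERS[1:3] else COST_TIERS
      chk(identical(names(tiers), want), lbl,
          paste("must define tiers", paste(want, collapse = ", ")))
      chk(all(tiers >= 0), lbl, "costs must be nonnegative")
      chk(all(diff(tiers) >= 0), lbl,
          "costs must be nondecreasing across tiers")
    }
  }

  psa <- params$psa
  chk(psa$n_draws >= 2, "psa$n_draws", "must be >= 2")
  chk(psa$default_rel_halfwidth > 0 && psa$default_rel_halfwidth < 1,
      "psa$default_rel_halfwidth", "must be in (0, 1)")
  invisible(params)
}

#' Packaged Senegal parameter set
#'
#' The default national parameter bundle: 2022 demography, the 2019 DHS
#' delivery mix, facility uterotonic utilization, WHO post-market-surveillance
#' substandard proportions, network-meta-analysis PPH risks, downstream-care
#' proportions and per-delivery cost tiers.
#'
#' @return A validated `pph_params` object.
#' @export
senegal_params <- function() {
  load_params(system.file("extdata", "senegal_2022.yaml",
                          package = "pphburden", mustWork = TRUE))
}

#' Senegal parameter set with Cote d'Ivoire medicine quality
#'
#' Identical to [senegal_params()] except that the substandard proportions of
#' oxytocin and misoprostol are replaced by the values surveyed in Cote
#' d'Ivoire (oxytocin 54% in both sectors, misoprostol 4% in both sectors),
#' for the alternative medicine-quality analysis.
#'
#' @return A validated `pph_params` object.
#' @export
cote_divoire_params <- function() {
  load_params(system.file("extdata", "cote_divoire_quality.yaml",
                          package = "pphburden", mustWork = TRUE))
}

#' Write a parameter object back to a config file
#'
#' @param params A `pph_params` object.
#' @param path Output path; `.json` writes JSON, anything else YAML.
#' @return Invisibly, `path`.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 12)
  }
  invisible(path)
}

#' @export
print.pph_params <- function(x, ...) {
  cat("<pph_params>", if (!is.null(x$country)) x$country else "", "\n")
  cat("  annual births:",
      format(annual_births(x$demography), big.mark = ","), "\n")
  cat("  strata:", length(STRATUM_KEYS), "per rurality;",
      "facility regimens:",
      paste(names(x$utilization$facility), collapse = ", "), "\n")
  cal <- x$care$p_death_severe
  cat("  death probability per severe case:",
      if (is.null(cal)) "uncalibrated" else format(cal, digits = 4), "\n")
  invisible(x)
}
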