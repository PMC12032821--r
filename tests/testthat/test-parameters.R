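test_that("packaged Senegal default reproduces the published inputs", {
  p <- senegal_params()
  expect_s3_class(p, "pph_params")
  expect_equal(p$demography$total_population, 17316449)
  expect_equal(p$demography$crude_birth_rate, 33)
  expect_equal(p$demography$mmr, 261)
  expect_equal(p$utilization$facility$oxytocin, 0.34)
  expect_equal(p$utilization$facility$oxytocin_misoprostol, 0.66)
  expect_equal(p$quality$oxytocin$public, 0.053)
  expect_equal(p$quality$misoprostol$public, 0.455)
  expect_equal(p$quality$misoprostol$home, 0.38)
  expect_equal(p$risk_ratios$pph, 1.29)
  expect_equal(p$risk_ratios$severe, 1.26)
  expect_equal(p$risks$oxytocin$vaginal$p500, 0.12)
  expect_equal(p$risks$none$vaginal$p500, 0.24)
  expect_equal(p$care$additional_treatment$substandard, 0.73)
  expect_equal(p$costs$public_hospital$vaginal$severe_surgery, 66.76)
  expect_equal(p$costs$phc$vaginal$mild, 24.97)
  expect_equal(p$costs$private_hospital$cesarean$no_pph, 788.36)
  # survey columns sum to 101/99 and are renormalized on load
  expect_equal(p$delivery$weights$urban$public_hospital_vaginal, 0.10 / 1.01)
  expect_equal(p$delivery$weights$rural$home, 0.31 / 0.99)
})

test_that("Cote d'Ivoire variant swaps only the substandard proportions", {
  p <- senegal_params()
  ci <- cote_divoire_params()
  expect_equal(ci$quality$oxytocin, list(public = 0.54, private = 0.54))
  expect_equal(ci$quality$misoprostol,
               list(public = 0.04, private = 0.04, home = 0.38))
  ci$quality <- p$quality
  ci$country <- p$country
  expect_equal(unclass(ci), unclass(p))
})

test_that("annual births follow population x birth rate / 1000", {
  d <- senegal_params()$demography
  expect_equal(annual_births(d), 17316449 * 33 / 1000)
  d$crude_birth_rate <- 0
  expect_equal(annual_births(d), 0)
  d$total_population <- 1e5
  d$crude_birth_rate <- 10
  expect_equal(annual_births(d), 1000)
})

test_that("delivery mix normalization divides by the column sum and is idempotent", {
  del <- list(urban_fraction = 0.3, weights = list(
    urban = as.list(setNames(c(10, 4, 75, 6, 1, 5) / 100,
                             pphburden:::STRATUM_KEYS)),
    rural = as.list(setNames(c(3, 2, 62, 1, 0, 31) / 100,
                             pphburden:::STRATUM_KEYS))))
  out <- normalize_delivery_mix(del)
  expect_equal(unlist(out$weights$urban), setNames(c(10, 4, 75, 6, 1, 5) / 101,
                                                   pphburden:::STRATUM_KEYS))
  expect_equal(unlist(out$weights$rural), setNames(c(3, 2, 62, 1, 0, 31) / 99,
                                                   pphburden:::STRATUM_KEYS))
  expect_equal(normalize_delivery_mix(out), out)

  already <- del
  already$weights$urban <- as.list(setNames(c(0.5, 0.5, 0, 0, 0, 0),
                                            pphburden:::STRATUM_KEYS))
  expect_equal(unlist(normalize_delivery_mix(already)$weights$urban),
               unlist(already$weights$urban))

  zero <- del
  zero$weights$urban <- as.list(setNames(rep(0, 6), pphburden:::STRATUM_KEYS))
  expect_error(normalize_delivery_mix(zero), "all-zero")
})

test_that("config round-trips through YAML and JSON", {
  p <- senegal_params()
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_params(p, path)
    p2 <- load_params(path)
    expect_equal(unclass(p2), unclass(p), tolerance = 1e-9)
    unlink(path)
  }
})

test_that("percent dialect rescales proportions on load", {
  raw <- yaml::read_yaml(system.file("extdata", "senegal_2022.yaml",
                                     package = "pphburden"))
  raw$percent <- TRUE
  x100 <- function(x) x * 100
  raw$delivery$urban_fraction <- x100(raw$delivery$urban_fraction)
  raw$delivery$weights <- lapply(raw$delivery$weights,
                                 function(w) lapply(w, x100))
  raw$utilization <- lapply(raw$utilization, function(u) lapply(u, x100))
  raw$quality <- lapply(raw$quality, function(q) lapply(q, x100))
  raw$care$additional_treatment <- lapply(raw$care$additional_treatment, x100)
  raw$care$transfusion <- lapply(raw$care$transfusion, x100)
  raw$care$surgery_severe_vaginal <- x100(raw$care$surgery_severe_vaginal)
  raw$care$referral_severe <- x100(raw$care$referral_severe)
  raw$care$diagnosed <- x100(raw$care$diagnosed)
  expect_equal(unclass(as_pph_params(raw)), unclass(senegal_params()),
               tolerance = 1e-12)
})

test_that("validation rejects malformed configs with named errors", {
  p <- senegal_params()

  broken <- unclass(p)
  broken$quality <- NULL
  expect_error(as_pph_params(broken), "quality")

  bad <- p
  bad$risks$oxytocin$vaginal$p1000 <- 0.5   # above p500 = 0.12
  bad$risks$oxytocin$vaginal$p1000_range <- c(0.4, 0.6)
  expect_error(validate_params(bad), "p1000 <= p500")

  bad <- p
  bad$risk_ratios$pph <- 0.8
  expect_error(validate_params(bad), "risk_ratios")

  bad <- p
  bad$costs$phc$vaginal$mild <- 5           # below the no-PPH tier
  expect_error(validate_params(bad), "nondecreasing")

  bad <- p
  bad$demography$mean_age_maternal_death <- 75
  expect_error(validate_params(bad), "life expectancy")
})
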