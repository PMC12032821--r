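test_that("tier lookup returns the published per-delivery costs", {
  costs <- senegal_params()$costs
  expect_equal(tier_of("mild", FALSE, "phc", "vaginal", costs), 24.97)
  expect_equal(tier_of("none", FALSE, "private_hospital", "cesarean", costs),
               788.36)
  expect_equal(tier_of("severe", TRUE, "public_hospital", "vaginal", costs),
               66.76)
  expect_error(tier_of("severe", TRUE, "phc", "vaginal", costs), "tier")
  expect_error(tier_of("mild", FALSE, "phc", "cesarean", costs), "cost block")
})

test_that("a thousand PHC mild cases cost a thousand times the mild tier", {
  p <- senegal_params()
  arms <- single_arm(location = "phc")
  arms$mild <- 1000
  arms$severe <- 0
  arms$referred_severe <- 0
  out <- pphburden:::arm_costs(arms, p)
  expect_equal(out$oop_public, 1000 * 24.97)
  expect_equal(out$oop_private, 0)
})

test_that("referred severe cases are costed at blended public-hospital tiers", {
  p <- senegal_params()
  arms <- single_arm(location = "home", regimen = "none", quality = "none")
  arms$mild <- 0
  arms$severe <- 100
  arms$referred_severe <- 18
  out <- pphburden:::arm_costs(arms, p)
  expect_equal(out$oop_public, 18 * (0.2 * 66.76 + 0.8 * 43.16))
})

test_that("productivity loss per death discounts the lost years annuity-due", {
  d <- senegal_params()$demography

  d0 <- d
  d0$discount_rate <- 0
  expect_equal(productivity_loss_per_death(d0), 39.5 * 1598.70)

  # independent oracle: explicit year-by-year sum at 3%
  oracle <- 1598.70 * (sum(1.03^-(0:38)) + 0.5 * 1.03^-39)
  expect_equal(productivity_loss_per_death(d), oracle)
  # and it sits near the value implied by published loss / published deaths
  expect_within_pct(productivity_loss_per_death(d), 16890566 / 447, 1)

  dz <- d
  dz$mean_age_maternal_death <- dz$life_expectancy_female
  expect_equal(productivity_loss_per_death(dz), 0)
})

test_that("burden totals are additive and productivity is linear in deaths", {
  p <- calibrated_senegal()
  res <- run_cohort(p)
  t <- res$totals
  expect_equal(t[["total_burden"]],
               t[["oop_public"]] + t[["oop_private"]] +
                 t[["productivity_loss"]], tolerance = 1e-12)
  expect_equal(t[["productivity_loss"]],
               t[["deaths"]] * productivity_loss_per_death(p$demography),
               tolerance = 1e-12)
  cb <- direct_costs(res)
  expect_equal(cb$total_burden, t[["total_burden"]])
  expect_gte(cb$substandard_attributable_oop, 0)
})

test_that("raising any single cost tier never lowers an OOP total", {
  p <- calibrated_senegal()
  base <- run_cohort(p)$totals
  for (cell in list(c("public_hospital", "vaginal", "severe_surgery"),
                    c("phc", "vaginal", "mild"),
                    c("private_hospital", "cesarean", "severe"))) {
    p2 <- p
    p2$costs[[cell[1]]][[cell[2]]][[cell[3]]] <-
      p2$costs[[cell[1]]][[cell[2]]][[cell[3]]] + 50
    up <- run_cohort(p2)$totals
    expect_gte(up[["oop_public"]], base[["oop_public"]] - 1e-9)
    expect_gte(up[["oop_private"]], base[["oop_private"]] - 1e-9)
  }
})

test_that("UHC decomposition zeroes out without substandard products", {
  p <- calibrated_senegal()
  clean <- p
  for (drug in names(clean$quality)) {
    clean$quality[[drug]] <- lapply(clean$quality[[drug]], function(x) 0)
  }
  b <- run_cohort(clean)
  s <- run_cohort(clean, make_scenario(1))
  u <- uhc_decomposition(b, s)
  expect_equal(u$mothers_receiving_substandard, 0)
  expect_equal(u$pph_on_substandard, 0)
  expect_equal(u$excess_oop, 0, tolerance = 1e-9)
  expect_equal(u$excess_deaths, 0, tolerance = 1e-9)
})

test_that("UHC decomposition rejects mismatched cohorts", {
  p <- calibrated_senegal()
  b <- run_cohort(p)
  p2 <- p
  p2$demography$total_population <- 2 * p$demography$total_population
  expect_error(uhc_decomposition(b, run_cohort(p2, make_scenario(1))),
               "same birth cohort")
})
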