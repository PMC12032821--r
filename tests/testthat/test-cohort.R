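test_that("combined substandard probability is one minus the all-good product", {
  expect_equal(combined_substandard_prob(c(0.053, 0.455)), 1 - 0.947 * 0.545)
  expect_equal(combined_substandard_prob(c(0, 0)), 0)
  expect_equal(combined_substandard_prob(c(1, 0.3)), 1)
  expect_error(combined_substandard_prob(c(-0.1, 0.5)))
})

test_that("pph_probs applies risk ratios to substandard branches and caps ordering", {
  p <- senegal_params()
  expect_equal(pph_probs("oxytocin", "vaginal", "quality", p$risks,
                         p$risk_ratios),
               c(p500 = 0.12, p1000 = 0.03))
  expect_equal(pph_probs("oxytocin", "vaginal", "substandard", p$risks,
                         p$risk_ratios),
               c(p500 = 0.12 * 1.29, p1000 = 0.03 * 1.26))
  expect_equal(pph_probs("none", "vaginal", "none", p$risks, p$risk_ratios),
               c(p500 = 0.24, p1000 = 0.05))
  expect_error(pph_probs("none", "cesarean", "none", p$risks, p$risk_ratios),
               "no risk cell")
  expect_error(pph_probs("misoprostol", "cesarean", "quality", p$risks,
                         p$risk_ratios), "no risk cell")
  # capping: large ratios can never push severe above total PPH or above 1
  rr <- list(pph = 2, severe = 30)
  out <- pph_probs("none", "vaginal", "substandard", p$risks, rr)
  expect_lte(out[["p1000"]], out[["p500"]])
  expect_lte(out[["p500"]], 1)
})

test_that("build_arms splits facility strata into regimen x quality branches", {
  p <- senegal_params()
  arms <- build_arms(p)
  expect_equal(sum(arms$weight), 1, tolerance = 1e-12)

  pub <- arms[arms$rurality == "urban" & arms$location == "public_hospital" &
                arms$mode == "vaginal", ]
  expect_equal(nrow(pub), 4)
  w <- 0.3 * 0.10 / 1.01
  q_om <- combined_substandard_prob(c(0.053, 0.455))
  expect_equal(sort(pub$weight),
               sort(w * c(0.34 * 0.947, 0.34 * 0.053,
                          0.66 * (1 - q_om), 0.66 * q_om)))

  home <- arms[arms$location == "home", ]
  expect_equal(nrow(home), 2)  # one arm per rurality
  expect_true(all(home$regimen == "none" & home$quality == "none"))

  # scenario 1 removes the substandard branches entirely
  arms1 <- build_arms(p, make_scenario(1))
  expect_false(any(arms1$quality == "substandard"))
  pub1 <- arms1[arms1$rurality == "urban" &
                  arms1$location == "public_hospital" &
                  arms1$mode == "vaginal", ]
  expect_equal(nrow(pub1), 2)
  expect_equal(sum(pub1$weight), w)
})

test_that("downstream outcomes follow the referral/treatment/diagnosis rules", {
  p <- calibrated_senegal()

  zero <- downstream_outcomes(single_arm(), p, births = 0)
  expect_true(all(zero[, c("pph", "severe", "transfusions", "deaths")] == 0))

  # home arm with 100,000 births: 24,000 PPH, 5,000 severe, 900 referred
  home <- downstream_outcomes(
    single_arm(location = "home", regimen = "none", quality = "none"),
    p, births = 1e5)
  expect_equal(home$pph, 24000)
  expect_equal(home$severe, 5000)
  expect_equal(home$referred_severe, 900)
  # unreferred home PPH receives neither treatment nor transfusion
  expect_equal(home$additional_treatments, 0.58 * 900)
  expect_equal(home$transfusions, 0.19 * 900)
  expect_equal(home$diagnosed_pph, 900)

  # quality facility arm holding 1,000 PPH cases: 580 treatments, 190 transfusions
  fac <- downstream_outcomes(single_arm(), p, births = 1000 / 0.12)
  expect_equal(fac$pph, 1000)
  expect_equal(fac$additional_treatments, 580)
  expect_equal(fac$transfusions, 190)
  expect_equal(fac$diagnosed_pph, 400)
  expect_equal(fac$surgeries, 0.20 * fac$severe)
})

test_that("cohort run conserves births and nests severities", {
  p <- calibrated_senegal()
  res <- run_cohort(p)
  expect_equal(res$totals[["births"]], annual_births(p$demography),
               tolerance = 1e-12)
  expect_equal(res$arms$mild + res$arms$severe, res$arms$pph)
  expect_true(all(res$arms$severe <= res$arms$pph + 1e-12))
  expect_true(all(res$arms$deaths <= res$arms$severe))
  expect_true(all(res$arms$diagnosed_pph <= res$arms$pph + 1e-12))
  expect_true(all(unlist(res$arms[pphburden:::OUTCOME_COLS]) >= 0))
  # totals equal the sum of parts
  expect_equal(res$totals[["pph"]], sum(res$arms$pph), tolerance = 1e-9)
})

test_that("expected counts scale exactly linearly with the birth cohort", {
  p <- calibrated_senegal()
  res <- run_cohort(p)
  p2 <- p
  p2$demography$total_population <- 2 * p$demography$total_population
  res2 <- run_cohort(p2)
  expect_equal(res2$totals, 2 * res$totals, tolerance = 1e-12)
})

test_that("removing substandard products never increases adverse outcomes", {
  p0 <- calibrated_senegal()
  for (seed in c(11, 22, 33)) {
    p <- random_params(seed)
    p$care$p_death_severe <- 0.03
    clean <- p
    for (drug in names(clean$quality)) {
      clean$quality[[drug]] <- lapply(clean$quality[[drug]], function(x) 0)
    }
    a <- run_cohort(p)$totals
    b <- run_cohort(clean)$totals
    for (o in c("pph", "severe", "transfusions", "deaths",
                "additional_treatments")) {
      expect_lte(b[[o]], a[[o]] + 1e-9)
    }
  }
  # and for the packaged set via scenario 1
  s1 <- run_cohort(p0, make_scenario(1))$totals
  b0 <- run_cohort(p0)$totals
  for (o in c("pph", "severe", "transfusions", "deaths")) {
    expect_lte(s1[[o]], b0[[o]])
  }
})

test_that("a no-risk world yields no PPH and no PPH costs", {
  p <- calibrated_senegal()
  for (reg in names(p$risks)) {
    for (mode in names(p$risks[[reg]])) {
      p$risks[[reg]][[mode]][c("p500", "p1000")] <- list(0, 0)
      p$risks[[reg]][[mode]]$p500_range <- c(0, 0)
      p$risks[[reg]][[mode]]$p1000_range <- c(0, 0)
    }
  }
  res <- run_cohort(p)
  expect_equal(res$totals[["pph"]], 0)
  expect_equal(res$totals[["deaths"]], 0)
  expect_equal(res$totals[["oop_public"]] + res$totals[["oop_private"]], 0)
})
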