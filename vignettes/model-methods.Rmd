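---
title: "Model and methods: the burden of substandard uterotonics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: the burden of substandard uterotonics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pphburden)
```

## The decision tree

`pphburden` evaluates a single-year expected-value cohort model. The cohort
size is `population × crude birth rate / 1000` — 571,443 births for the
packaged Senegal set — and every downstream quantity is an expected count,
kept fractional internally and rounded only when tables are rendered.

Births flow through four layers:

1. **Stratum.** Rurality (30% urban) × delivery location (public hospital,
   primary health center (PHC), private hospital, home) × mode (vaginal,
   cesarean). The published survey columns sum to 101%/99% because of
   rounding, so each rurality's six weights are renormalized to a proper
   distribution on load; `normalize_delivery_mix()` is idempotent.
2. **Regimen.** Facility births all receive prophylaxis: 34% oxytocin alone,
   66% oxytocin + misoprostol. Home births receive none at baseline.
3. **Quality.** Within a regimen the substandard branch has the channel's
   combined probability `1 − Π(1 − q_drug)` — for the dual regimen a single
   pooled branch, so the risk multiplier is applied once even when both
   components are substandard, keeping the tree at four facility options per
   stratum. PHC shares the public-sector proportions. Heat-stable carbetocin
   appears only in a quality-assured scenario and has no substandard share.
4. **Severity.** PPH is blood loss ≥ 500 ml with probability `p500`;
   severe PPH (≥ 1,000 ml) is a nested sub-branch with probability `p1000`,
   and `mild = p500 − p1000`. A substandard product multiplies `p500` by
   1.29 and `p1000` by 1.26; after multiplication probabilities are clipped
   to [0, 1] and a final `min` enforces `p1000 ≤ p500`, so extreme ratios
   can never break the nesting.

Downstream of severity: 18% of severe cases from home and PHC are referred
to a public hospital; additional uterotonic treatment (58% quality / 73%
substandard) and transfusion (19% / 38%) apply to PPH cases in facility arms
plus referred severe cases — unreferred home PPH receives neither, which is
what makes these facility interventions; surgery applies to 20% of severe
cases in hospital vaginal arms and of referred cases; 40% of facility PPH is
diagnosed, and referred home cases count as diagnosed. Deaths apply only to
the severe branch, at a single calibrated probability (next section).

## Calibration

The per-severe-case death probability is not an input. The target is
`births × MMR/100,000 × share`, where `share` is the proportion of maternal
deaths attributable to PPH, defaulting to 0.30 — the low end of the 30–50%
range reported for sub-Saharan Africa, and the value that anchors baseline
deaths at 447 per year for Senegal. Because deaths are linear in the
probability and severe cases do not depend on it, calibration is the closed
form `p = target / severe(baseline)` rather than root-finding;
`calibrate_death_prob()` errors if the target exceeds the severe count
(probability above 1). Scenarios reuse the baseline-calibrated probability,
so scenario deaths scale exactly with severe cases — a testable invariant.

## Costs and productivity losses

Every PPH case in a facility arm, plus every referred severe case (costed at
public-hospital vaginal tiers — referral is to a higher-level public
facility), incurs the full cost of its tier: mild; severe without surgery;
severe with surgery. Severe hospital cases are costed as a 20%/80% blend of
the with-/without-surgery tiers; this share is published for vaginal births
and is extended to cesarean severe cases, whose with-surgery cost tiers
exist, while the surgery *count* tracks vaginal and referred cases only.
PHC severe cases that are not referred take the PHC severe tier (PHC has no
surgery tier). Unreferred home PPH carries no cost, no-PPH delivery costs
are excluded from the burden, and the 40% diagnosis share drives the
diagnosed-count rows only — costing all facility PPH cases rather than only
diagnosed ones is the attribution rule that best matches the out-of-pocket
totals this parameterization is anchored to, and it is a deliberate,
documented inference; the public total lands within ~6% and the private
total runs higher, which we report rather than re-tune.

A death loses `life expectancy − mean age at maternal death = 39.5` years,
valued at GDP per capita and discounted at 3% annuity-due: the first year
undiscounted, the terminal fractional year weighted by 0.5. That yields
$37,810 per death, within 0.1% of the per-death loss implied by the
anchored burden figures (an ordinary annuity would undershoot by ~2.5%).

## Scenarios

Scenarios are ordered transform lists (`make_scenario()`), applied to the
parameter object before the tree is built:

| id | transform |
|----|-----------|
| 1 | substandard proportions → 0 at facilities |
| 2 | all facility births: quality-assured oxytocin + misoprostol |
| 3 | all facility births: quality-assured heat-stable carbetocin |
| 4 | home births: misoprostol at the reported 38% substandard share |
| 5 | home births: quality-assured misoprostol |
| 6 | home births moved to facilities, baseline quality |
| 7 | scenario 6 + all quality-assured |

Scenario 6/7 reallocate each rurality's home weight **proportionally** to
that rurality's existing facility strata. This is the minimal assumption —
it preserves the urban/rural facility case mix — where any other reallocation
rule would import structure the inputs do not support. Scenario 4/5 use the
vaginal misoprostol risk row (0.13/0.04) with the usual substandard
multipliers; referral, diagnosis and treatment rules are unchanged.

A note on regimen contrasts: the packaged risk inputs carry two decimals,
and at that precision oxytocin alone and oxytocin + misoprostol share the
same severe-PPH risk for vaginal births (0.03). Scenario 2's severe-case
reduction therefore comes almost entirely from removing the substandard
branches, not from the regimen switch; contrasts between near-equivalent
regimens are sensitive to digits beyond the stored precision, which is a
limitation of any two-decimal parameterization of this tree.

## Uncertainty analysis

`run_psa()` redraws the parameter set `n_draws = 1000` times:

* **Rates with published ranges** (the risk cells): beta by method of
  moments, mean at the point estimate, sd `(high − low)/3.92` (the range
  read as an approximate 95% interval). Boundary points or degenerate
  ranges collapse to point masses; the sd is capped just below the
  admissible beta variance.
* **Risk ratios**: symmetric triangular around the point estimate with
  ±25% relative half-width; where the floor of 1 binds, the support shrinks
  symmetrically so the draw mean stays at the point estimate.
* **Costs**: gamma on the nonnegative tier *increments* (cv =
  half-width/1.96), then cumulative sums — tier monotonicity holds by
  construction and each tier keeps its point-estimate mean. (Drawing tiers
  marginally and sorting or cummax-ing inflates mean costs by several
  percent; the increment scheme removes that estimator bias.)
* **Proportions without published ranges** (delivery mix, utilization,
  substandard shares, care proportions): beta with a ±25% relative 95%
  interval — a configurable default (`psa$default_rel_halfwidth`), exposed
  rather than hidden, since these inputs ship without uncertainty ranges.
  Mixes are renormalized per draw; the substandard care proportions are
  floored at the quality-assured draws so the quality ordering holds in
  every draw.

The death probability is recalibrated inside each draw — the mortality
anchor is external to the drawn parameters — so baseline deaths are pinned
at the target in every draw, while scenario deaths vary with severe-case
reductions. All scenarios within a draw share the same parameter set
(common random numbers), which is what makes the difference IQRs meaningful.
Draws are reproducible from `(seed, draw_index)` via a dedicated seed mix,
and every drawn set passes the same validator as a loaded config.

## Synthetic data and the oracle

`random_params()` generates structurally valid but otherwise random
parameter sets (Dirichlet-like mixes, ordered risks, quality-ordered care
proportions, monotone cost tiers) for fuzzing. `microsimulate()` samples
individual women down the identical tree — multinomial strata, binomial
chains for severity (severe drawn conditionally on PPH, so per-woman nesting
death ⇒ severe ⇒ PPH holds by construction), referral, treatment,
transfusion, surgery, diagnosis and death — and is the package's brute-force
oracle: the test suite requires agreement with the expected-value engine
within 3 binomial standard errors on the Senegal baseline with 2×10⁶
sampled women, and within 4 standard errors on 20 random parameter sets of
150,000 women each. The microsimulation validates counts, not costs; cost
identities (additivity, linearity in deaths) are checked analytically.

What the generator does not emulate: correlation between a woman's risk
factors and her care-seeking (anemia, parity), within-facility clustering of
medicine quality, seasonality, or any time dynamics. Passing the oracle
shows the expected-value engine integrates the stated tree correctly; it
says nothing about whether the tree captures real-world confounding.

## Degenerate inputs and tie-breaks

All-zero rurality mixes are rejected at load; zero-weight strata and arms
are dropped from the arm table; `p500 = 0` makes the conditional severe
probability 0 in the microsimulation; a zero calibration target gives a
zero death probability; counts are rounded half-to-even at render time
only, and percent differences are computed on unrounded values and then
rounded to integer percent.

## Known limitations

* Attribution rules for diagnosis, treatment eligibility and cost
  eligibility are inferences (documented above), not measured quantities;
  the private out-of-pocket total is the output most sensitive to them.
* The model is static (one annual cohort, no dynamics) and excludes
  intervention implementation costs (cold chain, distribution), anemia risk
  stratification, and ergometrine.
* Two-decimal risk inputs limit the resolution of regimen-switch contrasts
  (see Scenarios above).
* The ±25% default half-width for unranged inputs is an assumption; the
  uncertainty intervals for cost outcomes inherit it directly.
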