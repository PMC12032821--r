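# pphburden

Postpartum hemorrhage (PPH) is the leading cause of maternal death in
sub-Saharan Africa, and it is largely preventable with prophylactic
uterotonics (oxytocin, misoprostol, heat-stable carbetocin) given in the
third stage of labor. When those medicines are substandard — authorized
products that fail their quality specifications — they prevent fewer
hemorrhages, and the failures propagate into additional treatments, blood
transfusions, surgery, deaths and costs. `pphburden` is an expected-value
decision-tree cohort model of that burden for Senegal, for health economists
and maternal-health policy analysts who want a transparent, tested,
re-runnable implementation.

## The model

An annual cohort of `N = population × crude birth rate / 1000` births is
distributed over strata `s` (rurality × delivery location × mode). Facility
births receive a prophylactic regimen `r` (34% oxytocin alone, 66%
oxytocin + misoprostol) which is substandard with the channel's combined
probability `q = 1 − Π(1 − q_drug)`; home births receive no prophylaxis.
Each tree arm has PPH risk

```
p500(r, m)                       quality-assured
min(1, p500 · RR500)             substandard        RR500 = 1.29
```

and analogously `p1000` for severe PPH (≥ 1,000 ml; `RR1000 = 1.26`, capped
so severe never exceeds total PPH). Downstream, severe cases from home and
primary health centers are referred (18%), facility PPH cases receive
additional uterotonic treatment and transfusion at quality-dependent rates
(58%/73% and 19%/38%), 20% of severe vaginal hospital and referred cases
undergo surgery, 40% of facility cases are diagnosed, and the per-severe-case
death probability is calibrated in closed form so that baseline deaths equal
`N × MMR/100,000 × (PPH share of maternal deaths)`. Costs attach per case by
(facility, mode, severity tier) in USD; deaths additionally incur a
discounted productivity loss, `GDP per capita` per year of life lost
(life expectancy − mean age at maternal death = 39.5 years, discounted at
3%, annuity-due). Seven policy scenarios (quality assurance, regimen
switches, misoprostol at home births, universal facility delivery) are
declarative transforms of the parameter set, and a 1,000-draw probabilistic
sensitivity analysis ranges rates (beta), costs (gamma) and risk ratios
(triangular) with common random numbers across scenarios.

## Worked example

```r
library(pphburden)

params <- calibrate(senegal_params())    # packaged national parameter set
baseline <- run_cohort(params)
baseline
#> <pph_cohort> Baseline
#>   births 571,443 | PPH 86,659 (severe 22,626) | deaths 447
#>   OOP public $1,885,504 | OOP private $1,174,222 | total burden $19,977,331

quality <- run_cohort(params, make_scenario(1))   # no substandard uterotonics
head(render_table2(baseline, quality), 4)
#>                   outcome   kind baseline value difference pct_difference
#> 1           PPH >= 500 ml health    86659 82268      -4391             -5
#> 2         PPH >= 1,000 ml health    22626 21366      -1261             -6
#> 3 PPH >= 500 ml diagnosed health    23028 21272      -1756             -8
#> 4 PPH >= 1,000 ml diagnosed health    7579  7075       -504             -7
```

Read: of the 571,443 expected annual births, 86,659 lead to PPH and 447 to
death (the calibrated anchor); making every facility uterotonic
quality-assured would avert about 4,400 PPH cases and 4,500 transfusions a
year and release roughly $1.2M of economic burden. `run_all_scenarios()`
produces the full scenario panel, `uhc_decomposition()` the
families/providers/government view (145,487 mothers per year receive a
substandard uterotonic), `run_psa()` the uncertainty intervals, and
`microsimulate()` an individual-level sampling oracle for the engine.
`cote_divoire_params()` swaps in the Côte d'Ivoire medicine-quality survey
values. A thin command-line wrapper with `run`, `psa`, `microsim` and
`validate` subcommands is installed at `inst/cli/pphburden.R`.

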