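Package: pphburden
Title: Decision-Tree Model of the Burden of Substandard Uterotonics in Senegal
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An expected-value decision-tree cohort model of the annual health
    and economic burden of substandard uterotonic quality in postpartum
    hemorrhage (PPH) prevention. Women giving birth are distributed over
    rurality, delivery location and mode, receive prophylactic uterotonics of
    quality-assured or substandard quality, and face PPH (blood loss >= 500 ml)
    and severe PPH (>= 1,000 ml) risks with downstream referral, diagnosis,
    additional uterotonic treatment, blood transfusion, surgery and death.
    Deaths are calibrated to the national maternal mortality ratio; direct
    out-of-pocket costs by payer and discounted productivity losses are
    attached; seven policy scenarios, a universal-health-coverage
    decomposition, a probabilistic sensitivity analysis and an
    individual-level microsimulation oracle are included, together with a
    packaged Senegal parameter set and a Cote d'Ivoire medicine-quality
    variant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
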