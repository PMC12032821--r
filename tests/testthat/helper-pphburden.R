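# calibrated Senegal defaults, computed once per test session
calibrated_senegal <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate(senegal_params())
    cache
  }
})

# a one-arm table suitable for downstream_outcomes()/arm_costs()
single_arm <- function(location = "public_hospital", mode = "vaginal",
                       regimen = "oxytocin", quality = "quality",
                       weight = 1) {
  data.frame(rurality = "urban", location = location, mode = mode,
             regimen = regimen, quality = quality, weight = weight)
}

expect_within_pct <- function(value, target, pct) {
  expect_lt(abs(value - target), abs(target) * pct / 100,
            label = sprintf("|%.4g - %.4g| / target", value, target))
}
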