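# shared fixtures: lines, crosses, and the published seven-cross estimates

sr_line <- line_spec("SR", driver = TRUE)
even_line <- line_spec("EVEN")

srxsr <- cross_spec(line_genotype(sr_line, "male"),
                    line_genotype(sr_line, "female"), "SRxSR")
evenxeven <- cross_spec(line_genotype(even_line, "male"),
                        line_genotype(even_line, "female"), "EVENxEVEN")

# the seven-cross estimates of the original study, as literal inputs
published_inputs <- function() {
  screen_inputs(
    E  = sex_ratio_estimate(76.5, 74.0, 78.7, n = 1423),
    F_ = sex_ratio_estimate(83.9, 82.7, 84.6, n = 6588),
    control = sex_ratio_estimate(50.2, 48.5, 52.1, n = 2821),
    step2a = sex_ratio_estimate(52.7, 51.1, 54.4, n = 7013),
    step2b = sex_ratio_estimate(84.6, 82.9, 86.2, n = 5434),
    step3a = sex_ratio_estimate(87.3, 85.6, 88.3, n = 4307),
    step3b = sex_ratio_estimate(87.2, 85.6, 88.7, n = 4692),
    step3c = sex_ratio_estimate(53.2, 52.1, 54.3, n = 4692),
    total_survival = list(est = 0.840, lo = 0.803, hi = 0.875)
  )
}

pooled_pf <- function(broods, stage) {
  b <- broods[broods$stage == stage, ]
  100 * sum(b$n_female) / sum(b$n_female + b$n_male)
}
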