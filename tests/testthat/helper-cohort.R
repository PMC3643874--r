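# Shared fixtures, built in code.

# small hand-made analysis-ready table (balanced covariates, spread doses)
tiny_cohort <- function(n = 8) {
  pfos <- c(5, 8, 12, 15, 20, 26, 33, 40)[seq_len(n)]
  tibble::tibble(
    id = seq_len(n),
    sex = rep(c(0, 1), length.out = n),
    age_5y = 5.0 + c(-0.1, 0.06, -0.03, 0.09, -0.07, 0.1, -0.04, 0.02)[seq_len(n)],
    age_7y = 7.5 + c(-0.1, 0.05, -0.02, 0.08, -0.06, 0.1, -0.08, 0.03)[seq_len(n)],
    booster_type = rep(c("DT", "DT-IPV"), each = n / 2),
    pfos = pfos,
    pfoa = c(2, 2.5, 3.2, 4, 4.7, 5.6, 6.8, 8)[seq_len(n)],
    tetanus_ab = exp(1.5 - 0.03 * pfos +
                       c(0.1, -0.2, 0.15, -0.05, 0.2, -0.1, 0.05, -0.15)[seq_len(n)]),
    diphtheria_ab = exp(0.5 - 0.02 * pfos +
                          c(-0.1, 0.2, -0.15, 0.05, -0.2, 0.1, -0.05, 0.15)[seq_len(n)]))
}

# noise-free cohort with a known injected dose-response
noiseless_config <- function(spec = dose_response("linear", beta = -0.02),
                             n = 431, seed = 42) {
  cfg <- cohort_defaults(n = n, injected_effect = spec, seed = seed)
  cfg$outcome_params$tetanus$residual_sd <- 0
  cfg$outcome_params$diphtheria$residual_sd <- 0
  cfg
}

# a moderately sized cohort with a real linear effect, reused across files
effect_cohort <- function(beta = -0.02, n = 431, seed = 7) {
  generate_cohort(cohort_defaults(
    n = n, injected_effect = dose_response("linear", beta = beta),
    seed = seed))
}
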