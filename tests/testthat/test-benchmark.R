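test_that("BMD closed forms solve f(BMD) = log(1 - BMR) for each family", {
  # calibrate the linear curve so BMD at 5% is exactly 2.70 ng/mL
  lin <- dose_response("linear", beta = log(0.95) / 2.70)
  expect_equal(compute_bmd(lin, 0.05), 2.70, tolerance = 1e-12)
  expect_equal(round(compute_bmd(lin, 0.10), 2), 5.55)

  lg <- dose_response("log", beta = log(0.95) / log(1.13))
  expect_equal(compute_bmd(lg, 0.05), 0.13, tolerance = 1e-12)
  expect_equal(round(compute_bmd(lg, 0.10), 2), 0.29)

  kp <- dose_response("kpower", beta = log(0.95) / 2.70^2, K = 2)
  expect_equal(compute_bmd(kp, 0.05), 2.70, tolerance = 1e-12)

  # piecewise and threshold variants go through the bisection path;
  # verify against direct evaluation of the defining equation
  pw <- dose_response("piecewise", beta = log(0.95) / 1.45, beta2 = -0.001,
                      knot_m = 17.3)
  b5 <- compute_bmd(pw, 0.05)
  expect_equal(b5, 1.45, tolerance = 1e-8)
  expect_equal(dr_evaluate(pw, compute_bmd(pw, 0.10)), log(0.90),
               tolerance = 1e-8)
  thr <- dose_response("log", beta = -0.3, threshold = TRUE, d_min = 6)
  bthr <- compute_bmd(thr, 0.05)
  expect_gt(bthr, 6)
  expect_equal(dr_evaluate(thr, bthr), log(0.95), tolerance = 1e-8)
})

test_that("BMD ratio identities hold and BMD is monotone in BMR", {
  ratio <- log(0.90) / log(0.95)
  fit <- fit_dose_response(effect_cohort(seed = 7), "pfos", "tetanus", "linear")
  expect_equal(compute_bmd(fit, 0.10) / compute_bmd(fit, 0.05), ratio,
               tolerance = 1e-6)
  expect_equal(compute_bmdl_closed_form(fit, 0.10) /
                 compute_bmdl_closed_form(fit, 0.05), ratio, tolerance = 1e-6)

  lgfit <- fit_dose_response(effect_cohort(seed = 7), "pfos", "tetanus", "log")
  expect_equal(log(1 + compute_bmd(lgfit, 0.10)) /
                 log(1 + compute_bmd(lgfit, 0.05)), ratio, tolerance = 1e-6)

  bmrs <- c(0.01, 0.02, 0.05, 0.10, 0.20)
  bmds <- vapply(bmrs, function(b) compute_bmd(fit, b), numeric(1))
  expect_true(all(diff(bmds) > 0))
  # bmr -> 0 sends the BMD to 0
  expect_lt(compute_bmd(fit, 1e-8), 1e-5)
})

test_that("closed-form BMDL matches a dense grid-search oracle on random linear data", {
  withr::with_seed(123, {
    for (rep in 1:5) {
      n <- 60
      tb <- tibble::tibble(
        id = 1:n, sex = rbinom(n, 1, 0.5),
        age_5y = rnorm(n, 5, 0.1), age_7y = rnorm(n, 7.5, 0.1),
        booster_type = sample(c("DT", "DT-IPV"), n, replace = TRUE),
        pfos = exp(rnorm(n, log(17), 0.3)),
        pfoa = exp(rnorm(n, log(4), 0.3)),
        tetanus_ab = exp(1 - 0.05 * exp(rnorm(n, log(17), 0.3)) + rnorm(n, 0, 0.8)),
        diphtheria_ab = exp(rnorm(n, 0, 0.5)))
      tb$tetanus_ab <- exp(1 - 0.05 * tb$pfos + rnorm(n, 0, 0.8))
      fit <- fit_dose_response(tb, "pfos", "tetanus", "linear")
      bmdl <- compute_bmdl_closed_form(fit, 0.10)
      # oracle: scan a fine dose grid for the first crossing of the
      # lower confidence band below log(1 - BMR)
      tq <- qt(0.95, fit$df_resid)
      beta_hat <- unname(fit$slopes)
      se <- sqrt(fit$slope_covariance[1, 1])
      grid <- seq(1e-6, 2 * compute_bmd(fit, 0.10), length.out = 200001)
      band <- beta_hat * grid - tq * se * grid
      oracle <- grid[which(band <= log(0.90))[1]]
      expect_equal(bmdl, oracle, tolerance = diff(grid[1:2]) / oracle + 1e-6)
    }
  })
})

test_that("BMDL collapses onto the BMD when the slope has no uncertainty", {
  tb <- generate_cohort(noiseless_config(dose_response("linear", beta = -0.02)))
  fit <- fit_dose_response(tb, "pfos", "tetanus", "linear")
  bmd <- compute_bmd(fit, 0.05)
  expect_equal(compute_bmdl_closed_form(fit, 0.05), bmd, tolerance = 1e-6)
  expect_equal(compute_bmdl_profile(fit, 0.05), bmd, tolerance = 1e-6)
})

test_that("BMDL stays below BMD and the pure-linear reduction holds", {
  fit <- fit_dose_response(effect_cohort(seed = 29), "pfos", "tetanus", "linear")
  for (b in c(0.05, 0.10)) {
    bmd <- compute_bmd(fit, b)
    bmdl <- compute_bmdl_closed_form(fit, b)
    expect_lt(bmdl, bmd)
    # linear family: BMDL = log(1-BMR) / (beta_hat - t * se)
    tq <- qt(0.95, fit$df_resid)
    expect_equal(bmdl,
                 log(1 - b) / (unname(fit$slopes) -
                                 tq * sqrt(fit$slope_covariance[1, 1])),
                 tolerance = 1e-8)
    expect_lt(compute_bmdl_profile(fit, b), bmd)
  }
})

test_that("profile and closed-form BMDLs agree on large samples", {
  fit <- fit_dose_response(effect_cohort(n = 4000, seed = 19),
                           "pfos", "tetanus", "linear")
  cf <- compute_bmdl_closed_form(fit, 0.05)
  pr <- compute_bmdl_profile(fit, 0.05)
  expect_lt(abs(pr / cf - 1), 0.02)
})

test_that("non-adverse trends yield flagged NA, not numbers", {
  tb <- generate_cohort(cohort_defaults(
    injected_effect = dose_response("linear", beta = 0.03), seed = 8))
  fit <- fit_dose_response(tb, "pfos", "tetanus", "linear")
  bmd <- compute_bmd(fit, 0.05)
  expect_true(is.na(bmd))
  expect_match(attr(bmd, "bmd_undefined"), "adverse")
  expect_true(is.na(compute_bmdl_closed_form(fit, 0.05)))
  rows <- benchmark_doses(fit)
  expect_true(all(is.na(rows$bmd)))
  expect_match(rows$note[1], "adverse")
})

test_that("threshold-variant benchmark doses dominate the base model's", {
  tb <- effect_cohort(seed = 57)
  for (fam in c("linear", "log", "piecewise")) {
    base <- fit_dose_response(tb, "pfos", "tetanus", fam)
    thr <- fit_dose_response(tb, "pfos", "tetanus", fam, threshold = TRUE)
    b0 <- compute_bmd(base, 0.05)
    b1 <- compute_bmd(thr, 0.05)
    if (!is.na(b0) && !is.na(b1)) expect_gte(b1, b0)
  }
})

test_that("bmr outside (0, 1) and unsupported families are rejected", {
  fit <- fit_dose_response(tiny_cohort(), "pfos", "tetanus", "linear")
  expect_error(compute_bmd(fit, 0), class = "bmdserum_domain_error")
  expect_error(compute_bmd(fit, 1.2), class = "bmdserum_domain_error")
  kfit <- fit_dose_response(tiny_cohort(), "pfos", "tetanus", "kpower")
  expect_error(compute_bmdl_closed_form(kfit, 0.05),
               class = "bmdserum_unsupported_family")
})

test_that("regulatory conversions reproduce the published arithmetic", {
  expect_equal(derive_rfd(1, 10), 0.1)
  expect_equal(derive_rfd(5.2, 1), 5.2)
  expect_equal(round(derive_rfd(23, 30), 1), 0.8)
  expect_equal(serum_to_water(0.1, 100), 1)
  expect_equal(serum_to_water(0.1, 1), 100)
  expect_equal(serum_to_water(0.3, 100), 3)
  expect_error(derive_rfd(Inf, 10))
  expect_error(serum_to_water(-1))
})
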