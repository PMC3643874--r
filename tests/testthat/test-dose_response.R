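test_that("family formulas evaluate to their closed forms and satisfy f(0) = 0", {
  beta <- log(0.95) / 2.70
  lin <- dose_response("linear", beta = beta)
  expect_equal(dr_evaluate(lin, 2.70), log(0.95), tolerance = 1e-12)

  specs <- list(
    lin,
    dose_response("log", beta = -0.1),
    dose_response("kpower", beta = -0.01, K = 2.5),
    dose_response("piecewise", beta = -0.02, beta2 = -0.005, knot_m = 10),
    dose_response("linear", beta = -0.1, threshold = TRUE, d_min = 6),
    dose_response("log", beta = -0.1, threshold = TRUE, d_min = 6))
  for (s in specs) expect_identical(dr_evaluate(s, 0), 0)

  d <- c(0.3, 1, 7, 25)
  expect_equal(dr_evaluate(dose_response("log", beta = -0.1), d),
               -0.1 * log(d + 1))
  expect_equal(dr_evaluate(dose_response("kpower", beta = -0.01, K = 2.5), d),
               -0.01 * d^2.5)
})

test_that("piecewise evaluation matches independent segment-wise accumulation", {
  # oracle: integrate the slope function (beta below the knot, beta2 above),
  # splitting the integral at the knot so quadrature sees smooth pieces
  pw_oracle <- function(beta, beta2, m, d) {
    slope <- function(u) ifelse(u < m, beta, beta2)
    quad <- function(a, b) {
      if (a >= b) return(0)
      stats::integrate(slope, a, b, rel.tol = 1e-12)$value
    }
    vapply(d, function(x) quad(0, min(x, m)) + quad(m, x), numeric(1))
  }
  spec <- dose_response("piecewise", beta = -0.02, beta2 = -0.005, knot_m = 10)
  expect_equal(dr_evaluate(spec, 14), -0.02 * 10 - 0.005 * 4, tolerance = 1e-12)
  d <- c(0.5, 3, 9.99, 10, 10.01, 14, 60)
  expect_equal(dr_evaluate(spec, d), pw_oracle(-0.02, -0.005, 10, d),
               tolerance = 1e-8)
})

test_that("threshold variant is flat below d_min and matches the base curve shifted", {
  for (fam in c("linear", "log", "piecewise", "kpower")) {
    base <- switch(fam,
      piecewise = dose_response(fam, beta = -0.03, beta2 = -0.01, knot_m = 12),
      kpower = dose_response(fam, beta = -0.001, K = 2),
      dose_response(fam, beta = -0.03))
    thr <- base
    thr$threshold <- TRUE
    thr$d_min <- 6
    expect_identical(dr_evaluate(thr, c(0, 2, 6)), c(0, 0, 0))
    d <- c(7, 15, 30)
    expect_equal(dr_evaluate(thr, d),
                 dr_evaluate(base, d) - dr_evaluate(base, 6))
    # d_min = 0 collapses onto the base family exactly
    thr0 <- thr
    thr0$d_min <- 0
    expect_identical(dr_evaluate(thr0, d), dr_evaluate(base, d))
  }
})

test_that("kpower with K = 1 equals the linear family at every dose", {
  k1 <- dose_response("kpower", beta = -0.04, K = 1)
  lin <- dose_response("linear", beta = -0.04)
  d <- c(0, 0.1, 1, 17.3, 100)
  expect_identical(dr_evaluate(k1, d), dr_evaluate(lin, d))
})

test_that("curves with negative slopes are non-increasing in dose", {
  withr::with_seed(99, {
    specs <- list(
      dose_response("linear", beta = -runif(1)),
      dose_response("log", beta = -runif(1)),
      dose_response("kpower", beta = -runif(1), K = 1 + 3 * runif(1)),
      dose_response("piecewise", beta = -runif(1), beta2 = -runif(1),
                    knot_m = 5 + 10 * runif(1)),
      dose_response("log", beta = -runif(1), threshold = TRUE, d_min = 4))
    d <- sort(c(0, runif(50, 0, 60)))
    for (s in specs) {
      expect_true(all(diff(dr_evaluate(s, d)) <= 1e-14))
    }
  })
})

test_that("linear-in-parameter families satisfy f(d) = c(d)' slopes to machine precision", {
  withr::with_seed(4, {
    d <- runif(40, 0, 50)
    specs <- list(
      dose_response("linear", beta = -0.019),
      dose_response("log", beta = -0.11),
      dose_response("piecewise", beta = -0.02, beta2 = -0.004, knot_m = 17.3),
      dose_response("linear", beta = -0.019, threshold = TRUE, d_min = 6.2),
      dose_response("piecewise", beta = -0.02, beta2 = -0.004, knot_m = 17.3,
                    threshold = TRUE, d_min = 6.2))
    for (s in specs) {
      cd <- dr_design_vector(s, d)
      slopes <- if (s$family == "piecewise") c(s$beta, s$beta2) else s$beta
      expect_equal(drop(cd %*% slopes), dr_evaluate(s, d), tolerance = 1e-14)
    }
  })
})

test_that("design vectors encode the documented dose transforms", {
  expect_equal(drop(dr_design_vector(dose_response("linear", beta = -1), 3)), 3,
               ignore_attr = TRUE)
  pw <- dose_response("piecewise", beta = -1, beta2 = -1, knot_m = 10)
  expect_equal(drop(dr_design_vector(pw, 14)), c(10, 4),
               ignore_attr = TRUE)
  tl <- dose_response("log", beta = -1, threshold = TRUE, d_min = 6)
  expect_equal(drop(dr_design_vector(tl, 6)), 0, ignore_attr = TRUE)
  expect_equal(drop(dr_design_vector(tl, 20)), log(21) - log(7),
               ignore_attr = TRUE)
})

test_that("domain and family errors are raised", {
  lin <- dose_response("linear", beta = -0.02)
  expect_error(dr_evaluate(lin, -1), class = "bmdserum_domain_error")
  kp <- dose_response("kpower", beta = -0.02, K = 2)
  expect_error(dr_design_vector(kp, 5), class = "bmdserum_unsupported_family")
  expect_error(dose_response("kpower", beta = -1, K = 0.5),
               class = "bmdserum_config_error")
  expect_error(dose_response("piecewise", beta = -1),
               class = "bmdserum_config_error")
  expect_error(dose_response("linear", beta = -1, d_min = -2),
               class = "bmdserum_config_error")
})

test_that("dose-response specs survive a JSON round trip", {
  spec <- dose_response("piecewise", beta = -0.02, beta2 = -0.004,
                        knot_m = 17.3, threshold = TRUE, d_min = 6.2)
  back <- dr_from_json(dr_to_json(spec))
  expect_equal(back, spec)
  d <- c(0, 3, 20)
  expect_identical(dr_evaluate(back, d), dr_evaluate(spec, d))
})
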