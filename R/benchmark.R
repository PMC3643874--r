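#' Benchmark dose of a dose-response curve or fitted model
#'
#' The benchmark dose (BMD) for a benchmark response BMR on a log-transformed
#' outcome solves \eqn{f(BMD) = \log(1 - BMR)}: the dose at which the outcome
#' is reduced by the fraction BMR relative to an unexposed reference.
#' Because the outcome is log-transformed, the BMD does not depend on the
#' covariate coefficients.
#'
#' Closed forms are used where they exist (linear: \eqn{\log(1-BMR)/\beta};
#' log: \eqn{\exp(\log(1-BMR)/\beta) - 1}; kpower:
#' \eqn{(\log(1-BMR)/\beta)^{1/K}}); the piecewise family and all threshold
#' variants are solved by monotone bisection to relative tolerance 1e-9
#' (threshold variants solve \eqn{f_0(d) - f_0(d_{min}) = \log(1-BMR)}, so
#' the BMD exceeds \eqn{d_{min}}).
#'
#' When the fitted trend is not adverse (slope \eqn{\ge 0}) the BMD is
#' undefined and `NA` is returned, carrying a `"bmd_undefined"` attribute
#' explaining why.
#'
#' @param object a [dose_response()] specification or a `bmd_fit` from
#'   [fit_dose_response()].
#' @param bmr benchmark response, a fraction strictly inside (0, 1);
#'   conventionally 0.05 or 0.10.
#' @param ... passed to methods.
#' @return the BMD in ng/mL serum (a bare number), or flagged `NA` when
#'   undefined.
#' @examples
#' spec <- dose_response("linear", beta = log(0.95) / 2.70)
#' compute_bmd(spec, 0.05)  # 2.70 by construction
#' compute_bmd(spec, 0.10)  # 5.55: the ln(0.90)/ln(0.95) ratio
#' @export
compute_bmd <- function(object, bmr, ...) UseMethod("compute_bmd")

check_bmr <- function(bmr) {
  if (!is.numeric(bmr) || length(bmr) != 1L || bmr <= 0 || bmr >= 1) {
    rlang::abort("`bmr` must be a single fraction strictly inside (0, 1)",
                 class = "bmdserum_domain_error")
  }
}

bmd_undefined <- function(reason) {
  structure(NA_real_, bmd_undefined = reason)
}

#' @rdname compute_bmd
#' @param max_dose upper end of the bisection bracket; expanded automatically
#'   when `NULL`.
#' @export
compute_bmd.dose_response_spec <- function(object, bmr, max_dose = NULL, ...) {
  check_bmr(bmr)
  target <- log(1 - bmr)
  if (object$beta >= 0) {
    return(bmd_undefined("no adverse trend: fitted slope is non-negative"))
  }
  if (!object$threshold) {
    closed <- switch(object$family,
      linear = target / object$beta,
      log = exp(target / object$beta) - 1,
      kpower = (target / object$beta)^(1 / object$K),
      NULL)
    if (!is.null(closed)) return(closed)
  }
  solve_decreasing(function(d) dr_evaluate(object, d), target,
                   max_dose = max_dose)
}

#' @rdname compute_bmd
#' @export
compute_bmd.bmd_fit <- function(object, bmr, ...) {
  compute_bmd(fitted_spec(object), bmr, max_dose = object$max_dose * 1e3, ...)
}

# find d with g(d) = target for a continuous non-increasing g with g(0) >=
# target; bracket expands geometrically up to `max_dose` (or a hard cap)
solve_decreasing <- function(g, target, max_dose = NULL,
                             rel_tol = 1e-9) {
  lo <- 1e-12
  cap <- max_dose %||% 1e12
  hi <- min(1, cap)
  while (g(hi) > target && hi < cap) hi <- min(hi * 2, cap)
  if (g(hi) > target) {
    return(bmd_undefined(
      "dose-response never reaches the benchmark response within the bracket"))
  }
  if (g(lo) <= target) return(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > target) lo <- mid else hi <- mid
    if ((hi - lo) <= rel_tol * hi) break
  }
  (lo + hi) / 2
}

#' Closed-form BMDL for families linear in their parameters
#'
#' The benchmark dose lower limit (BMDL) is the lower one-sided
#' `alpha_level` (default 95%) confidence limit of the BMD. For the linear,
#' log and piecewise families (and their threshold variants) the dose
#' effect is \eqn{f(d) = c(d)^\top \gamma} with \eqn{c(d)} the
#' [dr_design_vector()]; the pointwise lower confidence band of \eqn{f} is
#' \deqn{\hat f(d) - t_{1-\alpha,\,n-p}\sqrt{c(d)^\top \Sigma\, c(d)},}
#' and the BMDL is the dose where this band equals \eqn{\log(1-BMR)},
#' found by bisection (relative tolerance 1e-9). For the pure linear family
#' this reduces to \eqn{\log(1-BMR)/(\hat\beta - t\,se(\hat\beta))}. The
#' BMDL never exceeds the BMD, with equality only when the slope is
#' estimated without uncertainty.
#'
#' @param fit a `bmd_fit` for a linear-in-parameters family (the kpower
#'   family requires [compute_bmdl_profile()]).
#' @param bmr benchmark response fraction in (0, 1).
#' @param alpha_level one-sided confidence level (default 0.95).
#' @return the BMDL in ng/mL serum, or flagged `NA` when the trend is not
#'   adverse.
#' @export
compute_bmdl_closed_form <- function(fit, bmr, alpha_level = 0.95) {
  stopifnot(inherits(fit, "bmd_fit"))
  check_bmr(bmr)
  if (fit$family == "kpower") {
    rlang::abort(
      "closed-form BMDL is unavailable for the kpower family; use compute_bmdl_profile()",
      class = "bmdserum_unsupported_family")
  }
  spec <- fitted_spec(fit)
  if (spec$beta >= 0) {
    return(bmd_undefined("no adverse trend: fitted slope is non-negative"))
  }
  target <- log(1 - bmr)
  tq <- qt(alpha_level, df = fit$df_resid)
  Sigma <- fit$slope_covariance
  lower_band <- function(d) {
    cd <- dr_design_vector(spec, d)
    drop(cd %*% dr_slopes(spec)) - tq * sqrt(rowSums((cd %*% Sigma) * cd))
  }
  solve_decreasing(function(d) lower_band(d), target,
                   max_dose = fit$max_dose * 1e3)
}

#' Profile-likelihood BMDL
#'
#' Reparameterises the model so that the BMD is an explicit parameter (for
#' one-slope families \eqn{\beta = \log(1-BMR)/c(BMD)}; for the K-power
#' family \eqn{\beta = \log(1-BMR)/BMD^K}; the piecewise family imposes the
#' linear constraint \eqn{c(BMD)^\top\gamma = \log(1-BMR)}), then profiles
#' \eqn{-2\log L} over all remaining parameters at each trial BMD. The BMDL
#' is the smallest BMD whose profile \eqn{-2\log L} lies within
#' \eqn{\chi^2_1(0.90) = 2.7055} of the full-model minimum — the standard
#' one-sided 95% profile construction (the cutoff is
#' \eqn{\chi^2_1(2\alpha - 1)} for general `alpha_level`). Required for the
#' K-power family, available for every family.
#'
#' @param fit a `bmd_fit`.
#' @param bmr benchmark response fraction in (0, 1).
#' @param alpha_level one-sided confidence level (default 0.95).
#' @param K_max upper bound of the inner K search (kpower only).
#' @return the BMDL in ng/mL serum, or flagged `NA` when the trend is not
#'   adverse.
#' @export
compute_bmdl_profile <- function(fit, bmr, alpha_level = 0.95, K_max = 15) {
  stopifnot(inherits(fit, "bmd_fit"))
  check_bmr(bmr)
  bmd_hat <- compute_bmd(fit, bmr)
  if (is.na(bmd_hat)) return(bmd_hat)
  # degenerate (noise-free) likelihood: any deviation from the MLE is
  # infinitely penalised, so the limit collapses onto the BMD
  if (fit$sigma_hat < 1e-10) return(bmd_hat)

  target <- log(1 - bmr)
  cutoff <- qchisq(2 * alpha_level - 1, df = 1)
  md <- fit$model_data
  n <- fit$n

  prof_rss <- function(b) {
    if (fit$family == "kpower") {
      rss_k <- function(K) {
        z <- dr_design_matrix("kpower", md$d, d_min = fit$d_min,
                              threshold = fit$threshold, K = K)[, 1]
        zb <- if (fit$threshold) {
          pmax(b, fit$d_min)^K - fit$d_min^K
        } else b^K
        if (zb <= 0) return(Inf)
        beta <- target / zb
        r <- qr.resid(qr(md$X), md$y - beta * z)
        sum(r^2)
      }
      grid <- seq(1, K_max, length.out = 15)
      vals <- vapply(grid, rss_k, numeric(1))
      i <- which.min(vals)
      opt <- optimize(rss_k, lower = grid[max(i - 1, 1)],
                      upper = grid[min(i + 1, length(grid))], tol = 1e-6)
      min(opt$objective, rss_k(1))
    } else {
      spec <- fitted_spec(fit)
      Dmat <- dr_design_vector(spec, md$d)
      cb <- drop(dr_design_vector(spec, b))
      if (all(cb == 0)) return(Inf)
      gamma0 <- cb * target / sum(cb^2)
      y_adj <- md$y - drop(Dmat %*% gamma0)
      if (length(cb) == 1L) {
        M <- md$X
      } else {
        null_vec <- c(-cb[2], cb[1])
        M <- cbind(md$X, drop(Dmat %*% null_vec))
      }
      sum(qr.resid(qr(M), y_adj)^2)
    }
  }
  prof_m2ll <- function(b) {
    rss <- prof_rss(b)
    n * log(2 * pi * rss / n) + n
  }
  h <- function(b) prof_m2ll(b) - fit$minus2loglik_full - cutoff

  lo <- bmd_hat / 2
  it <- 0
  while (h(lo) < 0 && it < 100) {
    lo <- lo / 2
    it <- it + 1
  }
  if (h(lo) < 0) {
    rlang::abort("profile likelihood failed to bracket the BMDL",
                 class = "bmdserum_convergence_error")
  }
  uniroot(h, lower = lo, upper = bmd_hat, tol = 1e-9 * bmd_hat)$root
}

#' Benchmark results for a fitted model
#'
#' Computes BMD and BMDL at each requested benchmark response, choosing the
#' closed-form BMDL for families linear in their parameters and the
#' profile-likelihood BMDL for the K-power family. Undefined results
#' (non-adverse trend) are kept as explicit `NA` rows with a note, never
#' dropped.
#'
#' @param fit a `bmd_fit` from [fit_dose_response()].
#' @param bmr vector of benchmark-response fractions (default 5% and 10%).
#' @param alpha_level one-sided confidence level for the BMDL.
#' @param method `"auto"` (closed form where available, otherwise profile),
#'   `"closed_form"` or `"profile_likelihood"`.
#' @return a tibble with one row per BMR: outcome, exposure, family,
#'   threshold flag, bmr, bmd, bmdl, method, alpha_level, note.
#' @export
benchmark_doses <- function(fit, bmr = c(0.05, 0.10), alpha_level = 0.95,
                            method = c("auto", "closed_form",
                                       "profile_likelihood")) {
  stopifnot(inherits(fit, "bmd_fit"))
  method <- match.arg(method)
  use_profile <- switch(method,
    auto = fit$family == "kpower",
    closed_form = FALSE,
    profile_likelihood = TRUE)
  purrr::map_dfr(bmr, function(b) {
    bmd <- compute_bmd(fit, b)
    bmdl <- if (is.na(bmd)) {
      bmd
    } else if (use_profile) {
      compute_bmdl_profile(fit, b, alpha_level)
    } else {
      compute_bmdl_closed_form(fit, b, alpha_level)
    }
    note <- attr(bmd, "bmd_undefined") %||% attr(bmdl, "bmd_undefined") %||% NA_character_
    tibble::tibble(
      outcome = fit$outcome, exposure = fit$exposure,
      family = fit$family, threshold = fit$threshold,
      bmr = b, bmd = as.numeric(bmd), bmdl = as.numeric(bmdl),
      method = if (use_profile) "profile_likelihood" else "closed_form",
      alpha_level = alpha_level, note = note)
  })
}

#' Reference dose from a BMDL
#'
#' Regulatory practice divides the BMDL by an uncertainty factor (commonly
#' 10 for within-population variability in vulnerability) to obtain a
#' reference dose (RfD) presumed safe for sensitive individuals.
#'
#' @param bmdl serum-based BMDL in ng/mL.
#' @param uncertainty_factor positive factor, at least 1 (default 10).
#' @return RfD in ng/mL serum.
#' @examples
#' derive_rfd(1, 10)    # 0.1 ng/mL serum
#' derive_rfd(23, 30)   # ~0.77, i.e. about 0.8 ng/mL serum
#' @export
derive_rfd <- function(bmdl, uncertainty_factor = 10) {
  stopifnot(is.finite(bmdl), uncertainty_factor >= 1)
  bmdl / uncertainty_factor
}

#' Convert a serum concentration to a drinking-water concentration
#'
#' Long-term residents' serum concentrations track the drinking-water
#' concentration at an approximately fixed serum:water ratio (about 100 for
#' PFOA). Converting ng/mL serum to ng/L water at ratio `r` gives
#' `serum_conc * 1000 / r` (the factor 1000 converts mL to L).
#'
#' @param serum_conc serum concentration in ng/mL.
#' @param serum_water_ratio dimensionless serum:water ratio (default 100).
#' @return water concentration in ng/L.
#' @examples
#' serum_to_water(0.1)  # 1 ng/L
#' @export
serum_to_water <- function(serum_conc, serum_water_ratio = 100) {
  stopifnot(all(serum_conc > 0), serum_water_ratio > 0)
  serum_conc * 1000 / serum_water_ratio
}
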