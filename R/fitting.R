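#' Fit the covariate-adjusted dose-response model
#'
#' Maximum-likelihood fit of
#' \deqn{\log(\mathrm{antibody}) = \alpha_0 + \alpha_1 \mathrm{sex} +
#'   \alpha_2 \mathrm{age} + \alpha_3 \mathrm{booster} + f(d) + \varepsilon}
#' where \eqn{d} is the chosen serum exposure and \eqn{f} one of the
#' [dose_response()] families. For families linear in their parameters
#' (linear, log, piecewise, and all threshold variants) the ML estimate is
#' the exact least-squares solution; the K-power family profiles the
#' likelihood over \eqn{K \in [1, K_{max}]}, with an exact inner linear fit
#' at each K.
#'
#' Fit quality is summarised by \eqn{-2\log L} with the ML variance
#' convention \eqn{\hat\sigma^2 = RSS/n} (so
#' \eqn{-2\log L = n\log(2\pi\hat\sigma^2) + n}), both over the full sample
#' and accumulated over the children in the lowest exposure quartile
#' (evaluated at the full-sample estimates by default). Coefficient
#' covariance uses the unbiased \eqn{RSS/(n-p)} convention, matching
#' standard regression software.
#'
#' @param data an analysis-ready cohort table (see [generate_cohort()],
#'   [read_cohort()]); complete cases with positive exposures and outcomes.
#' @param exposure `"pfos"` or `"pfoa"`.
#' @param outcome `"tetanus"` or `"diphtheria"`.
#' @param family dose-response family: `"linear"`, `"log"`, `"kpower"` or
#'   `"piecewise"`.
#' @param threshold logical; fit the low-dose-threshold variant (flat below
#'   `d_min`).
#' @param knot_m piecewise knot; defaults to the in-sample median exposure.
#' @param d_min threshold dose; defaults to the minimum observed exposure.
#' @param K_max upper bound of the K-power profile search (default 15).
#' @param lowdose_refit if `TRUE`, the low-dose \eqn{-2\log L} comes from
#'   re-fitting the model within the lowest-quartile subset instead of
#'   evaluating the full-sample fit there.
#' @return an object of class `bmd_fit`; see [tidy.bmd_fit()] and
#'   [glance.bmd_fit()].
#' @examples
#' cohort <- generate_cohort(cohort_defaults(
#'   injected_effect = dose_response("linear", beta = -0.02), seed = 11))
#' fit <- fit_dose_response(cohort, "pfos", "tetanus", "linear")
#' glance(fit)
#' @export
fit_dose_response <- function(data,
                              exposure = c("pfos", "pfoa"),
                              outcome = c("tetanus", "diphtheria"),
                              family = c("linear", "log", "kpower", "piecewise"),
                              threshold = FALSE,
                              knot_m = NULL,
                              d_min = NULL,
                              K_max = 15,
                              lowdose_refit = FALSE) {
  exposure <- match.arg(exposure)
  outcome <- match.arg(outcome)
  family <- match.arg(family)
  tbl <- validate_cohort(data)

  d <- tbl[[exposure]]
  y <- log(tbl[[paste0(outcome, "_ab")]])
  n <- length(y)
  knot_m <- knot_m %||% if (family == "piecewise") median(d) else NULL
  d_min <- if (threshold) d_min %||% min(d) else 0

  X <- covariate_design(tbl)
  # slopes: one for every family except piecewise (two); K adds a parameter
  p_total <- ncol(X) + (if (family == "piecewise") 2L else 1L) +
    (family == "kpower")
  if (n <= p_total) {
    rlang::abort(sprintf("insufficient data: n = %d observations for %d parameters",
                         n, p_total),
                 class = "bmdserum_insufficient_data")
  }

  if (family == "kpower") {
    prof <- profile_kpower(y, X, d, d_min = d_min, threshold = threshold,
                           K_max = K_max)
    K_hat <- prof$K
    D <- dr_design_matrix("kpower", d, d_min = d_min, threshold = threshold,
                          K = K_hat)
  } else {
    K_hat <- NULL
    D <- dr_design_matrix(family, d, knot_m = knot_m, d_min = d_min,
                          threshold = threshold)
  }
  ls <- ols_fit(y, cbind(X, D))
  p <- ls$p + (family == "kpower")  # K counts as an estimated parameter
  sigma2_ml <- ls$rss / n
  m2ll <- n * log(2 * pi * sigma2_ml) + n

  q1 <- quantile(d, 0.25, type = 7, names = FALSE)
  low_idx <- d <= q1  # ties at the cut included
  if (lowdose_refit) {
    sub <- ols_fit(y[low_idx], cbind(X, D)[low_idx, , drop = FALSE])
    n_low <- sum(low_idx)
    s2_low <- sub$rss / n_low
    m2ll_low <- n_low * log(2 * pi * s2_low) + n_low
  } else {
    r <- ls$residuals[low_idx]
    m2ll_low <- sum(log(2 * pi * sigma2_ml) + r^2 / sigma2_ml)
  }

  k_slopes <- ncol(D)
  slope_idx <- ls$p - k_slopes + seq_len(k_slopes)
  coefs <- ls$coefficients
  structure(
    list(
      family = family, threshold = threshold,
      exposure = exposure, outcome = outcome,
      coefficients = coefs,
      alpha = coefs[seq_len(ls$p - k_slopes)],
      slopes = coefs[slope_idx],
      K_hat = K_hat,
      sigma_hat = sqrt(sigma2_ml),
      covariance = ls$covariance,
      slope_covariance = ls$covariance[slope_idx, slope_idx, drop = FALSE],
      n = n, p = p, df_resid = n - ls$p,
      minus2loglik_full = m2ll,
      minus2loglik_lowdose = m2ll_low,
      lowdose_n = sum(low_idx), lowdose_refit = lowdose_refit,
      knot_m = knot_m, d_min = d_min,
      model_data = list(y = y, X = X, d = d),
      max_dose = max(d)),
    class = "bmd_fit")
}

# covariate design matrix: intercept, sex (girl = 1), age at the 7-year
# examination, booster dummies with lexicographically first level as reference
covariate_design <- function(tbl) {
  booster <- factor(tbl$booster_type)
  if (nlevels(booster) > 1) {
    mm <- model.matrix(~booster)
    bcols <- mm[, -1, drop = FALSE]
    colnames(bcols) <- paste0("booster_type", levels(booster)[-1])
  } else {
    bcols <- NULL
  }
  X <- cbind("(Intercept)" = 1, sex = tbl$sex, age_7y = tbl$age_7y)
  if (!is.null(bcols)) X <- cbind(X, bcols)
  X
}

# exact least-squares fit with rank check; names of collinear columns are
# reported on failure
ols_fit <- function(y, M) {
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M)) {
    dropped <- colnames(M)[qr_m$pivot[(qr_m$rank + 1):ncol(M)]]
    rlang::abort(paste0("rank-deficient design; collinear column(s): ",
                        paste(dropped, collapse = ", ")),
                 class = "bmdserum_singular_design")
  }
  beta <- qr.coef(qr_m, y)
  res <- y - drop(M %*% beta)
  rss <- sum(res^2)
  n <- length(y)
  p <- ncol(M)
  xtx_inv <- chol2inv(qr.R(qr_m))
  covb <- xtx_inv * rss / (n - p)
  dimnames(covb) <- list(colnames(M), colnames(M))
  list(coefficients = setNames(drop(beta), colnames(M)),
       residuals = res, rss = rss, p = p, covariance = covb)
}

# profile -2logL over K for the kpower family: grid warm start then a
# bounded scalar search; K = 1 boundary handled explicitly
profile_kpower <- function(y, X, d, d_min = 0, threshold = FALSE,
                           K_max = 15, n_grid = 29, tol = 1e-6) {
  rss_at <- function(K) {
    D <- dr_design_matrix("kpower", d, d_min = d_min, threshold = threshold,
                          K = K)
    M <- cbind(X, D)
    qr_m <- qr(M)
    sum(qr.resid(qr_m, y)^2)
  }
  grid <- seq(1, K_max, length.out = n_grid)
  rss_grid <- vapply(grid, rss_at, numeric(1))
  i <- which.min(rss_grid)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, n_grid)]
  opt <- optimize(rss_at, lower = lo, upper = hi, tol = tol)
  # the boundary K = 1 is a legitimate profile minimum
  K <- if (rss_at(1) <= opt$objective + 1e-12) 1 else opt$minimum
  list(K = K, rss = rss_at(K))
}

# reconstruct the fitted dose-response curve from a bmd_fit
fitted_spec <- function(fit) {
  sl <- unname(fit$slopes)
  switch(fit$family,
    linear = dose_response("linear", beta = sl[1],
                           threshold = fit$threshold, d_min = fit$d_min),
    log = dose_response("log", beta = sl[1],
                        threshold = fit$threshold, d_min = fit$d_min),
    kpower = dose_response("kpower", beta = sl[1], K = fit$K_hat,
                           threshold = fit$threshold, d_min = fit$d_min),
    piecewise = dose_response("piecewise", beta = sl[1], beta2 = sl[2],
                              knot_m = fit$knot_m,
                              threshold = fit$threshold, d_min = fit$d_min))
}

#' @export
print.bmd_fit <- function(x, ...) {
  cat(sprintf("<bmd_fit> %s ~ %s, %s family%s\n",
              x$outcome, x$exposure, x$family,
              if (x$threshold) sprintf(" (threshold at %.3g ng/mL)", x$d_min)
              else ""))
  est <- format(signif(x$coefficients, 4))
  cat("coefficients:\n")
  print(est, quote = FALSE)
  if (!is.null(x$K_hat)) cat(sprintf("K_hat = %.4g%s\n", x$K_hat,
    if (x$K_hat == 1) " (boundary: identical to the linear model)" else ""))
  cat(sprintf("sigma_hat = %.4f (log scale), n = %d, p = %d\n",
              x$sigma_hat, x$n, x$p))
  cat(sprintf("-2log(L): full = %.2f, low-dose (n = %d) = %.2f\n",
              x$minus2loglik_full, x$lowdose_n, x$minus2loglik_lowdose))
  invisible(x)
}

#' Tidy a fitted dose-response model
#'
#' @param x a `bmd_fit` from [fit_dose_response()].
#' @param ... unused.
#' @return a tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @exportS3Method generics::tidy
tidy.bmd_fit <- function(x, ...) {
  se <- sqrt(diag(x$covariance))
  stat <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * stats::pt(-abs(stat), df = x$df_resid)))
}

#' One-row summary of a fitted dose-response model
#'
#' @param x a `bmd_fit` from [fit_dose_response()].
#' @param ... unused.
#' @return a one-row tibble with the family, threshold flag, fitted power,
#'   residual sd, both \eqn{-2\log L} diagnostics and dimensions.
#' @exportS3Method generics::glance
glance.bmd_fit <- function(x, ...) {
  tibble::tibble(
    exposure = x$exposure, outcome = x$outcome,
    family = x$family, threshold = x$threshold,
    k_hat = x$K_hat %||% NA_real_,
    sigma = x$sigma_hat,
    minus2loglik_full = x$minus2loglik_full,
    minus2loglik_lowdose = x$minus2loglik_lowdose,
    n = x$n, p = x$p, df_resid = x$df_resid)
}

#' Rank competing dose-response fits by likelihood
#'
#' Sorts fits of the same exposure/outcome pair ascending by full-sample
#' \eqn{-2\log L} (smaller indicates better fit), reporting the low-dose
#' diagnostic alongside. Fits whose full-sample \eqn{-2\log L} agree to
#' within `tie_tol` keep their input order and are flagged as tied.
#'
#' @param fits a list of `bmd_fit` objects for one exposure/outcome pair.
#' @param tie_tol absolute tolerance for declaring a tie.
#' @return a tibble, one row per fit, ordered best-first, with a `tied`
#'   flag.
#' @export
compare_fits <- function(fits, tie_tol = 1e-9) {
  if (inherits(fits, "bmd_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "bmd_fit")))
  key <- vapply(fits, function(f) paste(f$exposure, f$outcome), character(1))
  if (length(unique(key)) > 1) {
    rlang::abort("all fits must share the same exposure and outcome",
                 class = "bmdserum_contract_error")
  }
  tbl <- purrr::map_dfr(fits, glance)
  tbl <- dplyr::mutate(tbl, .input_order = dplyr::row_number())
  tbl <- dplyr::arrange(tbl, .data$minus2loglik_full, .data$.input_order)
  v <- tbl$minus2loglik_full
  tied_lead <- c(abs(diff(v)) <= tie_tol, FALSE)
  tbl$tied <- tied_lead | dplyr::lag(tied_lead, default = FALSE)
  dplyr::select(tbl, -".input_order")
}

#' Plot a fitted dose-response model
#'
#' Partial-residual plot: the log outcome with the fitted covariate
#' contribution removed, against the serum exposure, overlaid with the
#' fitted dose-response curve.
#'
#' @param object a `bmd_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bmd_fit <- function(object, ...) {
  md <- object$model_data
  partial <- md$y - drop(md$X %*% object$alpha)
  spec <- fitted_spec(object)
  grid <- seq(0, max(md$d), length.out = 300)
  df <- tibble::tibble(dose = md$d, partial = partial)
  curve_df <- tibble::tibble(dose = grid, effect = dr_evaluate(spec, grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$partial)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = curve_df,
                       ggplot2::aes(x = .data$dose, y = .data$effect),
                       colour = "firebrick", linewidth = 0.9) +
    ggplot2::labs(
      x = sprintf("serum %s (ng/mL)", toupper(object$exposure)),
      y = sprintf("log %s antibody, covariate-adjusted", object$outcome),
      title = sprintf("%s dose-response fit", object$family)) +
    ggplot2::theme_minimal()
}
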