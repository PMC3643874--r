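#' Dose-response curve specification
#'
#' Constructs a dose-response function \eqn{f(d)} acting on the natural-log
#' outcome scale, constrained to \eqn{f(0) = 0}. Four families are supported:
#'
#' * `"linear"`: \eqn{f(d) = \beta d}
#' * `"log"`: \eqn{f(d) = \beta \log(d + 1)} (natural logarithm; `d` in ng/mL)
#' * `"kpower"`: \eqn{f(d) = \beta d^K}, \eqn{K \ge 1}
#' * `"piecewise"`: \eqn{f(d) = \beta \min(d, m) + \beta_2 \max(d - m, 0)},
#'   two slopes joined continuously at the knot `knot_m`
#'
#' Each family has a low-dose-threshold variant (`threshold = TRUE`) that is
#' flat below `d_min` and follows the base curve above it:
#' \eqn{f(d) = f_0(\max(d, d_{min})) - f_0(d_{min})}. The threshold variant
#' with `d_min = 0` is identical to the base family.
#'
#' @param family one of `"linear"`, `"log"`, `"kpower"`, `"piecewise"`.
#' @param beta slope on the natural-log outcome scale; per ng/mL for the
#'   linear family, per unit of \eqn{\log(d+1)} for the log family. Negative
#'   values encode an adverse (outcome-reducing) trend.
#' @param beta2 second-segment slope (piecewise only).
#' @param knot_m dose (ng/mL) at which the piecewise slopes change; must be
#'   positive.
#' @param K power for the K-power family; must be at least 1. `K = 1`
#'   reproduces the linear family exactly.
#' @param threshold logical; use the low-dose-threshold variant.
#' @param d_min threshold dose in ng/mL (threshold variants only);
#'   non-negative.
#'
#' @return an object of class `dose_response_spec`.
#' @examples
#' spec <- dose_response("linear", beta = log(0.95) / 2.70)
#' dr_evaluate(spec, 2.70)  # = log(0.95), a 5% outcome reduction
#' @export
dose_response <- function(family = c("linear", "log", "kpower", "piecewise"),
                          beta,
                          beta2 = NULL,
                          knot_m = NULL,
                          K = NULL,
                          threshold = FALSE,
                          d_min = 0) {
  family <- match.arg(family)
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (family == "piecewise") {
    if (is.null(beta2) || is.null(knot_m)) {
      rlang::abort("piecewise family requires `beta2` and `knot_m`",
                   class = "bmdserum_config_error")
    }
    if (!is.finite(knot_m) || knot_m <= 0) {
      rlang::abort("`knot_m` must be a positive dose",
                   class = "bmdserum_config_error")
    }
  } else if (!is.null(beta2)) {
    rlang::abort("`beta2` only applies to the piecewise family",
                 class = "bmdserum_config_error")
  }
  if (family == "kpower") {
    if (is.null(K)) K <- 1
    if (!is.finite(K) || K < 1) {
      rlang::abort("`K` must be >= 1", class = "bmdserum_config_error")
    }
  } else if (!is.null(K)) {
    rlang::abort("`K` only applies to the kpower family",
                 class = "bmdserum_config_error")
  }
  if (!is.finite(d_min) || d_min < 0) {
    rlang::abort("`d_min` must be non-negative",
                 class = "bmdserum_config_error")
  }
  structure(
    list(family = family, beta = beta, beta2 = beta2, knot_m = knot_m,
         K = K, threshold = isTRUE(threshold), d_min = d_min),
    class = "dose_response_spec"
  )
}

#' @export
print.dose_response_spec <- function(x, ...) {
  lab <- switch(x$family,
    linear = sprintf("f(d) = %.4g * d", x$beta),
    log = sprintf("f(d) = %.4g * log(d + 1)", x$beta),
    kpower = sprintf("f(d) = %.4g * d^%.4g", x$beta, x$K),
    piecewise = sprintf("f(d) = %.4g * min(d, %.4g) + %.4g * max(d - %.4g, 0)",
                        x$beta, x$knot_m, x$beta2, x$knot_m))
  cat("<dose_response_spec>", lab, "\n")
  if (x$threshold) {
    cat("  low-dose threshold at d_min =", format(x$d_min), "ng/mL\n")
  }
  invisible(x)
}

# base-family value at dose x (no threshold logic), vectorised
dr_base_value <- function(spec, x) {
  switch(spec$family,
    linear = spec$beta * x,
    log = spec$beta * log(x + 1),
    kpower = spec$beta * x^spec$K,
    piecewise = spec$beta * pmin(x, spec$knot_m) +
      spec$beta2 * pmax(x - spec$knot_m, 0))
}

#' Evaluate a dose-response curve
#'
#' Returns \eqn{f(d)} on the natural-log outcome scale. For threshold
#' variants the value is 0 for all doses at or below `d_min`.
#'
#' @param spec a [dose_response()] specification.
#' @param d vector of doses in ng/mL; must be non-negative.
#' @return numeric vector of effects on the natural-log outcome scale.
#' @export
dr_evaluate <- function(spec, d) {
  stopifnot(inherits(spec, "dose_response_spec"))
  if (any(!is.finite(d)) || any(d < 0)) {
    rlang::abort("doses must be finite and non-negative",
                 class = "bmdserum_domain_error")
  }
  if (spec$threshold) {
    dr_base_value(spec, pmax(d, spec$d_min)) - dr_base_value(spec, spec$d_min)
  } else {
    dr_base_value(spec, d)
  }
}

# Design columns for the slope parameters of a linear-in-parameters family,
# built from structural parameters only (no slopes needed). Returns an
# n x k matrix, k = 1 (linear, log) or 2 (piecewise). The kpower column for
# a *given* K is also provided since the inner fit at fixed K is linear.
dr_design_matrix <- function(family, d, knot_m = NULL, d_min = 0,
                             threshold = FALSE, K = NULL) {
  base_cols <- function(x) {
    switch(family,
      linear = cbind(beta = x),
      log = cbind(beta = log(x + 1)),
      kpower = cbind(beta = x^K),
      piecewise = cbind(beta = pmin(x, knot_m),
                        beta2 = pmax(x - knot_m, 0)))
  }
  if (threshold) {
    base_cols(pmax(d, d_min)) -
      matrix(base_cols(d_min), nrow = length(d), ncol = ncol(base_cols(d_min)),
             byrow = TRUE, dimnames = list(NULL, colnames(base_cols(d_min))))
  } else {
    base_cols(d)
  }
}

#' Design vector of a linear-in-parameters dose-response family
#'
#' For the linear, log and piecewise families (and their threshold variants)
#' the dose effect is a linear combination of the slope parameters:
#' \eqn{f(d) = c(d)^\top (\beta, \beta_2)}. This exposes \eqn{c(d)}, the
#' ingredient of the closed-form BMDL construction. The K-power family is
#' non-linear in K and is rejected.
#'
#' @param spec a [dose_response()] specification (slopes may be arbitrary;
#'   only structural parameters are used).
#' @param d vector of doses in ng/mL.
#' @return a matrix with one row per dose and one column per slope parameter.
#' @export
dr_design_vector <- function(spec, d) {
  stopifnot(inherits(spec, "dose_response_spec"))
  if (spec$family == "kpower") {
    rlang::abort(
      "the kpower family is non-linear in K; use the profile-likelihood path",
      class = "bmdserum_unsupported_family")
  }
  if (any(!is.finite(d)) || any(d < 0)) {
    rlang::abort("doses must be finite and non-negative",
                 class = "bmdserum_domain_error")
  }
  dr_design_matrix(spec$family, d, knot_m = spec$knot_m, d_min = spec$d_min,
                   threshold = spec$threshold)
}

# slope parameters of a spec as a vector aligned with dr_design_vector columns
dr_slopes <- function(spec) {
  if (spec$family == "piecewise") c(spec$beta, spec$beta2) else spec$beta
}

#' Serialize / deserialize a dose-response specification as JSON
#'
#' @param spec a [dose_response()] specification.
#' @param path file path; when `NULL`, `dr_to_json()` returns the JSON string.
#' @return `dr_to_json()`: the path (or JSON string) invisibly;
#'   `dr_from_json()`: a `dose_response_spec`.
#' @export
dr_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "dose_response_spec"))
  json <- jsonlite::toJSON(spec[!vapply(spec, is.null, logical(1))],
                           auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname dr_to_json
#' @param json a JSON string or file path produced by [dr_to_json()].
#' @export
dr_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  dose_response(family = x$family, beta = x$beta, beta2 = x$beta2,
                knot_m = x$knot_m, K = x$K,
                threshold = isTRUE(x$threshold),
                d_min = x$d_min %||% 0)
}

#' Plot a dose-response curve
#'
#' @param object a [dose_response()] specification.
#' @param from,to dose range (ng/mL) to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dose_response_spec <- function(object, from = 0, to = 50, ...) {
  d <- seq(from, to, length.out = 400)
  df <- tibble::tibble(dose = d, effect = dr_evaluate(object, d))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$effect)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "serum concentration (ng/mL)",
                  y = "effect on log outcome",
                  title = paste0(object$family,
                                 if (object$threshold) " (low-dose threshold)")) +
    ggplot2::theme_minimal()
}
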