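#' Run the full benchmark-dose analysis
#'
#' Orchestrates the whole pipeline: obtain a cohort (data frame, CSV path, or
#' [generator_config()] to simulate), fit every requested dose-response
#' family for each exposure x outcome pair, and compute BMD/BMDL at each
#' benchmark response, with or without the low-dose-threshold variant. One
#' result row is produced per outcome x exposure x family x threshold x BMR,
#' carrying the BMD, BMDL and both \eqn{-2\log L} fit diagnostics.
#'
#' When `out_dir` is given, the run writes `results.tsv` (2-decimal,
#' publication layout via [render_benchmark_table()]), `results.json` (full
#' precision) and `run.log` (seed, configuration, package versions, row
#' count, per-stage timing). Any stage failure aborts with a stage-named
#' error and removes partial outputs.
#'
#' @param input a cohort data frame, a path to a cohort CSV, or a
#'   [generator_config()] to simulate from.
#' @param exposures,outcomes,families character vectors selecting the
#'   analysis grid.
#' @param threshold `"off"`, `"on"`, or `"both"`.
#' @param bmr benchmark-response fractions (default 0.05 and 0.10).
#' @param alpha_level one-sided confidence level for BMDLs.
#' @param out_dir optional output directory.
#' @param seed optional integer; overrides the generator seed when `input`
#'   is a configuration (ignored for data-frame or CSV input, which is
#'   already deterministic).
#' @return a tibble of benchmark results (one row per combination), with the
#'   fit diagnostics joined in.
#' @examples
#' cfg <- cohort_defaults(
#'   injected_effect = dose_response("linear", beta = -0.02), seed = 3)
#' res <- run_analysis(cfg, families = c("linear", "log"))
#' @export
run_analysis <- function(input,
                         exposures = c("pfos", "pfoa"),
                         outcomes = c("tetanus", "diphtheria"),
                         families = c("linear", "log", "kpower", "piecewise"),
                         threshold = c("off", "on", "both"),
                         bmr = c(0.05, 0.10),
                         alpha_level = 0.95,
                         out_dir = NULL,
                         seed = NULL) {
  threshold <- match.arg(threshold)
  if (!length(exposures) || !length(outcomes) || !length(families)) {
    rlang::abort("config stage: at least one exposure, outcome and family required",
                 class = "bmdserum_config_error")
  }
  if (any(bmr <= 0 | bmr >= 1)) {
    rlang::abort("config stage: every `bmr` must lie strictly inside (0, 1)",
                 class = "bmdserum_config_error")
  }
  t0 <- Sys.time()
  log_lines <- c(
    sprintf("bmdserum %s | R %s", as.character(packageVersion("bmdserum")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("started %s", format(t0, "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %s", seed %||% "none (deterministic input)"),
    sprintf("exposures: %s | outcomes: %s | families: %s | threshold: %s | bmr: %s",
            paste(exposures, collapse = ","), paste(outcomes, collapse = ","),
            paste(families, collapse = ","), threshold,
            paste(bmr, collapse = ",")))

  cohort <- tryCatch({
    if (inherits(input, "generator_config")) {
      if (!is.null(seed)) input$seed <- as.integer(seed)
      generate_cohort(input)
    } else if (is.character(input) && length(input) == 1L) {
      read_cohort(input)
    } else if (is.data.frame(input)) {
      validate_cohort(input)
    } else {
      rlang::abort("unrecognised input type")
    }
  }, error = function(e) {
    rlang::abort(paste0("input stage: ", conditionMessage(e)),
                 class = "bmdserum_stage_error", parent = e)
  })
  if (nrow(cohort) == 0) {
    rlang::abort("input stage: cohort table is empty",
                 class = "bmdserum_stage_error")
  }
  log_lines <- c(log_lines, sprintf("cohort: %d children", nrow(cohort)))

  thr_values <- switch(threshold, off = FALSE, on = TRUE,
                       both = c(FALSE, TRUE))
  grid <- tidyr::expand_grid(outcome = outcomes, exposure = exposures,
                             family = families, thr = thr_values)
  t_fit <- Sys.time()
  results <- tryCatch({
    purrr::pmap_dfr(grid, function(outcome, exposure, family, thr) {
      fit <- fit_dose_response(cohort, exposure, outcome, family,
                               threshold = thr)
      dplyr::mutate(
        benchmark_doses(fit, bmr = bmr, alpha_level = alpha_level),
        k_hat = fit$K_hat %||% NA_real_,
        k_boundary = identical(fit$K_hat, 1),
        minus2loglik_full = fit$minus2loglik_full,
        minus2loglik_lowdose = fit$minus2loglik_lowdose,
        knot_m = fit$knot_m %||% NA_real_,
        d_min = fit$d_min)
    })
  }, error = function(e) {
    rlang::abort(paste0("fitting stage: ", conditionMessage(e)),
                 class = "bmdserum_stage_error", parent = e)
  })
  log_lines <- c(log_lines,
    sprintf("fitting + benchmark: %d result rows in %.2f s", nrow(results),
            as.numeric(difftime(Sys.time(), t_fit, units = "secs"))))

  if (!is.null(out_dir)) {
    paths <- file.path(out_dir, c("results.tsv", "results.json", "run.log"))
    tryCatch({
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_lines(render_benchmark_table(results, format = "tsv"),
                         paths[1])
      jsonlite::write_json(results, paths[2], auto_unbox = TRUE, digits = NA,
                           na = "null")
      log_lines <- c(log_lines,
        sprintf("finished %s (%.2f s total)", format(Sys.time(), "%H:%M:%S"),
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      readr::write_lines(log_lines, paths[3])
    }, error = function(e) {
      unlink(paths)
      rlang::abort(paste0("output stage: ", conditionMessage(e)),
                   class = "bmdserum_stage_error", parent = e)
    })
  }
  results
}

#' Render benchmark results in the publication table layout
#'
#' Produces a table with one line per outcome/exposure/model/threshold
#' combination and columns `BMD` and `BMDL` at each benchmark response
#' (ordered BMD then BMDL within ascending BMR, headers naming the BMR as a
#' percentage), followed by the full-sample and low-dose \eqn{-2\log L}.
#' Doses are printed at 2 decimals; undefined results render as `NA`.
#'
#' @param results a results tibble from [run_analysis()] or row-bound
#'   [benchmark_doses()] output.
#' @param format `"tsv"` (tab-separated lines, parseable back to numbers) or
#'   `"text"` (aligned columns for reading).
#' @return a character vector of lines.
#' @export
render_benchmark_table <- function(results, format = c("tsv", "text")) {
  format <- match.arg(format)
  if (!nrow(results)) {
    rlang::abort("no results to render", class = "bmdserum_contract_error")
  }
  has_fit <- all(c("minus2loglik_full", "minus2loglik_lowdose") %in%
                   names(results))
  fmt2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
  bmrs <- sort(unique(results$bmr))
  wide <- results |>
    dplyr::mutate(bmr_pct = paste0("BMR=", 100 * .data$bmr, "%")) |>
    dplyr::select(dplyr::any_of(c("outcome", "exposure", "family", "threshold",
                                  "bmr", "bmr_pct", "bmd", "bmdl",
                                  "minus2loglik_full", "minus2loglik_lowdose"))) |>
    tidyr::pivot_wider(names_from = "bmr_pct",
                       values_from = c("bmd", "bmdl"),
                       id_cols = dplyr::any_of(c("outcome", "exposure",
                                                 "family", "threshold",
                                                 "minus2loglik_full",
                                                 "minus2loglik_lowdose"))) |>
    dplyr::arrange(.data$outcome, .data$exposure, .data$family,
                   .data$threshold)
  header <- c("Outcome", "Exposure", "Model", "Threshold",
              unlist(lapply(bmrs, function(b)
                paste0(c("BMD", "BMDL"), "_", 100 * b, "pct"))),
              if (has_fit) c("Fit_full", "Fit_lowdose"))
  rows <- purrr::pmap_chr(wide, function(...) {
    r <- list(...)
    vals <- unlist(lapply(bmrs, function(b) {
      key <- paste0("BMR=", 100 * b, "%")
      c(fmt2(r[[paste0("bmd_", key)]]), fmt2(r[[paste0("bmdl_", key)]]))
    }))
    fields <- c(r$outcome, r$exposure, r$family,
                ifelse(isTRUE(r$threshold), "yes", "no"), vals,
                if (has_fit) c(fmt2(r$minus2loglik_full),
                               fmt2(r$minus2loglik_lowdose)))
    paste(fields, collapse = "\t")
  })
  lines <- c(paste(header, collapse = "\t"), rows)
  if (format == "text") {
    mat <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    widths <- apply(nchar(mat), 2, max)
    lines <- apply(mat, 1, function(rw)
      paste(mapply(formatC, rw, width = widths,
                   MoreArgs = list(flag = "-")), collapse = "  "))
  }
  lines
}
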