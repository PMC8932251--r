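#' Run one verification-bias analysis and build a machine-readable report
#'
#' Dispatches to the complete-case (`"cc"`), Begg-Greenes (`"bg"`) or
#' multiple-imputation (`"mi"`, `"mi-firth"`) estimator and wraps the
#' result with the input summary, configuration echo and warnings needed
#' to reproduce the run.
#'
#' @param data a `screening_data` object.
#' @param method one of `"cc"`, `"bg"`, `"mi"`, `"mi-firth"`.
#' @param seed RNG seed; required for `"bg"` (bootstrap) and the MI
#'   methods.
#' @param B bootstrap replicates for `"bg"` (default 1000).
#' @param m imputations for MI (default 100).
#' @param level confidence level (default 0.95).
#' @param ci_method complete-case interval method
#'   (`"clopper-pearson"` or `"wilson"`).
#' @return A list of class `run_report`: `input` (N, N_verified,
#'   exclusions), `method`, `config`, `estimates` (the
#'   `accuracy_estimates` data frame), `expected_cases`, `warnings`,
#'   `version`.
#' @export
estimate_accuracy <- function(data, method = c("cc", "bg", "mi", "mi-firth"),
                              seed = NULL, B = 1000, m = 100, level = 0.95,
                              ci_method = "clopper-pearson") {
  method <- match.arg(method)
  if (method != "cc" && is.null(seed))
    stop(sprintf("method '%s' consumes random numbers: supply a seed",
                 method), call. = FALSE)
  warnings <- character(0)
  expected_cases <- NULL
  est <- switch(method,
    cc = complete_case_estimates(data, level = level,
                                 ci_method = ci_method),
    bg = {
      e <- bg_estimate(data, B = B, level = level, seed = seed)
      expected_cases <- attr(e, "expected_cases")
      if ((attr(e, "n_invalid") %||% 0L) > 0L)
        warnings <- c(warnings, sprintf(
          "%d invalid bootstrap replicate(s) redrawn/dropped",
          attr(e, "n_invalid")))
      e
    },
    "mi" = ,
    "mi-firth" = {
      e <- withCallingHandlers(
        mi_estimate(data, m = m, penalized = (method == "mi-firth"),
                    seed = seed, level = level),
        warning = function(w) {
          warnings <<- c(warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      expected_cases <- attr(e, "expected_cases")
      epv <- attr(e, "epv")
      if (epv$flag)
        warnings <- c(warnings, sprintf(
          "EPV = %.2f < %g: penalized (Firth) fit recommended",
          epv$epv, epv$threshold))
      e
    })
  structure(list(
    input = list(n = nrow(data),
                 n_verified = sum(data$verified == 1L),
                 n_excluded = attr(data, "n_excluded") %||% 0L,
                 tests = test_names(data)),
    method = method,
    config = list(seed = seed, B = if (method == "bg") B else NULL,
                  m = if (method %in% c("mi", "mi-firth")) m else NULL,
                  level = level,
                  ci_method = if (method == "cc") ci_method else NULL),
    estimates = est,
    expected_cases = expected_cases,
    warnings = warnings,
    version = as.character(utils::packageVersion("veribias"))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("veribias run report (method: %s, version %s)\n",
              x$method, x$version))
  cat(sprintf("  input: N=%d, verified=%d, excluded at ingest=%d\n",
              x$input$n, x$input$n_verified, x$input$n_excluded))
  if (!is.null(x$expected_cases))
    cat(sprintf("  expected cases in completed cohort: %.2f (~%d)\n",
                x$expected_cases$raw, x$expected_cases$rounded))
  print(x$estimates)
  if (length(x$warnings))
    cat("warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

report_to_list <- function(report) {
  est <- as.data.frame(report$estimates)
  list(input = report$input, method = report$method,
       config = Filter(Negate(is.null), report$config),
       estimates = est,
       expected_cases = report$expected_cases,
       warnings = report$warnings, version = report$version)
}

#' Serialize a run report to JSON (and optionally CSV)
#'
#' JSON is the canonical form; the CSV is a flat convenience export of the
#' estimates table.
#'
#' @param report a `run_report`.
#' @param path output JSON path.
#' @param csv_path optional CSV path for the flat estimates table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv_path = NULL) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(report$estimates), csv_path,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a serialized run report
#'
#' @param path JSON path written by [write_report()].
#' @return The report as a list (estimates as a data frame).
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$estimates <- as.data.frame(rep$estimates)
  rep
}

#' Run several methods side by side on one dataset
#'
#' Produces a comparison table with tests-by-measures rows and one point
#' (and interval) column set per method.  Per-method failures are isolated:
#' a method that errors contributes `NA` columns and its message is
#' recorded.
#'
#' @param data a `screening_data` object.
#' @param ... further arguments passed to [estimate_accuracy()] (e.g. `B`,
#'   `m`; note `...` precedes the remaining arguments, so `methods` and
#'   `seed` must be spelled out in full).
#' @param methods methods to run (default all four).
#' @param seed seed passed to the stochastic methods.
#' @return A list of class `method_comparison`: `table` (wide data frame),
#'   `reports` (per-method `run_report` or error message).
#' @export
compare_methods <- function(data, ...,
                            methods = c("cc", "bg", "mi", "mi-firth"),
                            seed = NULL) {
  reports <- list()
  tabs <- list()
  for (mth in methods) {
    res <- tryCatch(estimate_accuracy(data, method = mth, seed = seed, ...),
                    error = function(e) conditionMessage(e))
    reports[[mth]] <- res
    if (inherits(res, "run_report")) {
      est <- as.data.frame(res$estimates)[, c("test", "measure", "point",
                                              "ci_low", "ci_high")]
      names(est)[3:5] <- paste(c("point", "ci_low", "ci_high"), mth,
                               sep = ".")
      tabs[[mth]] <- est
    }
  }
  if (!length(tabs)) stop("every requested method failed")
  wide <- Reduce(function(a, b) merge(a, b, by = c("test", "measure"),
                                      all = TRUE, sort = FALSE),
                 tabs)
  structure(list(table = wide, reports = reports), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, digits = 1, ...) {
  cat("Method comparison (point and interval columns in %)\n")
  y <- x$table
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) round(100 * v, digits))
  print(y, row.names = FALSE)
  failed <- names(Filter(is.character, x$reports))
  if (length(failed))
    for (mth in failed)
      cat(sprintf("method '%s' failed: %s\n", mth, x$reports[[mth]]))
  invisible(x)
}
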