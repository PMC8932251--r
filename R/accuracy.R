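#' Confusion counts for one screening test
#'
#' Holds the four cells of a 2x2 test-by-disease table.  Counts may be
#' fractional: the Begg-Greenes allocation produces expected, not observed,
#' counts, and the ratios below are defined for any non-negative reals.
#'
#' @param tp,fp,fn,tn non-negative counts (true/false positives/negatives).
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  x <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(x)) || any(x < 0)) stop("confusion counts must be >= 0")
  structure(as.list(x), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              disease = c("present", "absent")))
  print(m)
  invisible(x)
}

measure_ratio <- function(num, denom, measure) {
  if (denom <= 0)
    stop(sprintf("%s is undefined: its denominator is zero", measure),
         call. = FALSE)
  num / denom
}

#' Accuracy measures from confusion counts
#'
#' Sensitivity = Pr(test+ | disease), specificity = Pr(test- | no disease),
#' PPV = Pr(disease | test+), NPV = Pr(no disease | test-).
#'
#' @param c a `confusion_counts` object.
#' @return A proportion in `[0, 1]`.
#' @export
sensitivity <- function(c) measure_ratio(c$tp, c$tp + c$fn, "sensitivity")

#' @rdname sensitivity
#' @export
specificity <- function(c) measure_ratio(c$tn, c$tn + c$fp, "specificity")

#' @rdname sensitivity
#' @export
ppv <- function(c) measure_ratio(c$tp, c$tp + c$fp, "ppv")

#' @rdname sensitivity
#' @export
npv <- function(c) measure_ratio(c$tn, c$tn + c$fn, "npv")

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided interval from beta quantiles; requires integer counts.  The
#' lower limit is exactly 0 when `x = 0` and the upper exactly 1 when
#' `x = n`.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level coverage (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
clopper_pearson_ci <- function(x, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (abs(x - round(x)) > 1e-8 || abs(n - round(n)) > 1e-8)
    stop("exact interval requires integer counts; use wilson_ci for ",
         "fractional effective denominators")
  x <- round(x); n <- round(n)
  if (x < 0 || x > n) stop("x must lie in [0, n]")
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Wilson score confidence interval
#'
#' Score-based binomial interval computed from a proportion and a (possibly
#' non-integer) effective denominator, which makes it the interval of
#' choice after multiple-imputation pooling.
#'
#' @param p observed proportion in `[0, 1]`.
#' @param n_eff effective denominator, `> 0`, not necessarily an integer.
#' @param level coverage (default 0.95).
#' @return Numeric vector `c(lower, upper)`, contained in `[0, 1]`.
#' @export
wilson_ci <- function(p, n_eff, level = 0.95) {
  if (is.na(n_eff) || n_eff <= 0) stop("effective denominator must be > 0")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n_eff
  centre <- (p + z^2 / (2 * n_eff)) / denom
  half <- z * sqrt(p * (1 - p) / n_eff + z^2 / (4 * n_eff^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

binomial_ci <- function(x, n, level, method) {
  switch(method,
         "clopper-pearson" = clopper_pearson_ci(x, n, level),
         "wilson" = wilson_ci(x / n, n, level),
         stop("unknown ci method: ", method))
}

make_estimate <- function(measure, test, num, denom, level, ci_method) {
  if (denom <= 0) {
    return(data.frame(test = test, measure = measure, point = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      ci_method = ci_method, denominator = denom,
                      stringsAsFactors = FALSE))
  }
  ci <- binomial_ci(num, denom, level, ci_method)
  data.frame(test = test, measure = measure, point = num / denom,
             ci_low = ci[[1]], ci_high = ci[[2]], ci_method = ci_method,
             denominator = denom, stringsAsFactors = FALSE)
}

#' Complete-case accuracy estimates
#'
#' The unadjusted analysis: accuracy measures computed from verified
#' participants only, discarding everyone without a reference-standard
#' result.  Sensitivity estimates from this analysis are typically inflated
#' and specificity estimates deflated when verification depends on the
#' screening results.
#'
#' @param data a `screening_data` object with at least one verified record.
#' @param level confidence level (default 0.95).
#' @param ci_method `"clopper-pearson"` (exact, the default) or `"wilson"`.
#' @return A data frame of class `accuracy_estimates`, one row per estimate:
#'   the four measures and positive-test prevalence for each test, plus one
#'   `disease prevalence` row (test `"(all)"`).  Measures with a zero
#'   denominator are returned with `NA` point and interval.
#' @export
complete_case_estimates <- function(data, level = 0.95,
                                    ci_method = c("clopper-pearson",
                                                  "wilson")) {
  ci_method <- match.arg(ci_method)
  tn_ <- test_names(data)
  ver <- data[data$verified == 1L, , drop = FALSE]
  n_ver <- nrow(ver)
  if (n_ver == 0L) stop("no verified participants: complete-case analysis ",
                        "is undefined")
  d <- ver$disease
  rows <- list(make_estimate("prevalence", "(all)", sum(d == 1L), n_ver,
                             level, ci_method))
  for (tst in tn_) {
    x <- ver[[tst]]
    tp <- sum(x == 1L & d == 1L); fp <- sum(x == 1L & d == 0L)
    fn <- sum(x == 0L & d == 1L); tn2 <- sum(x == 0L & d == 0L)
    rows <- c(rows, list(
      make_estimate("sensitivity", tst, tp, tp + fn, level, ci_method),
      make_estimate("specificity", tst, tn2, tn2 + fp, level, ci_method),
      make_estimate("ppv", tst, tp, tp + fp, level, ci_method),
      make_estimate("npv", tst, tn2, tn2 + fn, level, ci_method),
      make_estimate("positive_test_prevalence", tst, tp + fp, n_ver,
                    level, ci_method)))
  }
  out <- do.call(rbind, rows)
  structure(out, n = nrow(data), n_verified = n_ver, method = "cc",
            class = c("accuracy_estimates", "data.frame"))
}

#' @export
print.accuracy_estimates <- function(x, digits = 1, ...) {
  cat(sprintf("Accuracy estimates (method: %s; N=%s, verified=%s)\n",
              attr(x, "method") %||% "?", attr(x, "n") %||% "?",
              attr(x, "n_verified") %||% "?"))
  y <- x
  for (cl in c("point", "ci_low", "ci_high"))
    y[[cl]] <- round(100 * y[[cl]], digits)
  print.data.frame(y, row.names = FALSE)
  cat("(point and interval columns in %)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
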