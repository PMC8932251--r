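#' Impute missing disease statuses once from a fitted disease model
#'
#' Every non-verified participant receives `disease = 1` with probability
#' `predict_prob(model, tests)`, by comparing a single uniform draw per
#' participant to that probability.  Verified records are untouched.
#'
#' @param data a `screening_data` object.
#' @param model a `logistic_model` fitted on the verified subset (main
#'   effects on the K tests, unless a wider design is supplied through
#'   `design_fun`).
#' @param design_fun function mapping the test-result matrix to the model's
#'   covariate matrix; defaults to identity (main effects).
#' @return A `screening_data` object with no missing disease values.
#' @export
impute_once <- function(data, model, design_fun = identity) {
  miss <- data$verified == 0L
  if (!any(miss)) return(data)
  tests <- as.matrix(data[miss, test_names(data), drop = FALSE])
  p <- predict_prob(model, design_fun(tests))
  data$disease[miss] <- as.integer(stats::runif(sum(miss)) < p)
  data
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' @param points per-imputation point estimates (length m).
#' @param variances per-imputation (within) variances (length m).
#' @return List with `point` (mean of points), `within` (mean variance),
#'   `between` (sample variance of points, divisor m-1) and `total`
#'   (`within + (1 + 1/m) * between`).
#' @export
rubin_pool <- function(points, variances) {
  m <- length(points)
  if (m < 2) stop("Rubin's rules need at least two imputations")
  if (length(variances) != m) stop("points and variances differ in length")
  pbar <- mean(points)
  wbar <- mean(variances)
  bvar <- stats::var(points)
  list(point = pbar, within = wbar, between = bvar,
       total = wbar + (1 + 1 / m) * bvar, m = m)
}

#' Effective sample size for a pooled proportion
#'
#' The denominator `n_eff` at which a binomial variance matches the total
#' multiple-imputation variance: `n_eff = p (1 - p) / T`, capped at the
#' nominal denominator.  Feeding `n_eff` to the Wilson interval makes the
#' interval reflect both within- and between-imputation uncertainty.
#'
#' @param p pooled proportion.
#' @param total total (Rubin) variance; `0` means no missing information
#'   and returns `nominal_n`.
#' @param nominal_n the complete-data denominator (cap).
#' @param eps boundary guard: `p` is clamped to `[eps, 1 - eps]` before the
#'   ratio; default `0.5 / (nominal_n + 1)`, the shrinkage point a
#'   penalized intercept-only fit would give.
#' @return Effective denominator in `(0, nominal_n]`.
#' @export
effective_sample_size <- function(p, total, nominal_n,
                                  eps = 0.5 / (nominal_n + 1)) {
  if (total < 0) stop("total variance must be >= 0")
  if (total == 0) return(nominal_n)
  p <- min(max(p, eps), 1 - eps)
  min(p * (1 - p) / total, nominal_n)
}

#' Wilson interval for a pooled proportion
#'
#' Delegates to [wilson_ci()] with the effective denominator; wider than
#' the complete-data Wilson interval whenever between-imputation variance
#' is positive.
#'
#' @param p pooled proportion.
#' @param n_eff effective denominator from [effective_sample_size()].
#' @param level coverage (default 0.95).
#' @return `c(lower, upper)`.
#' @export
pooled_wilson_ci <- function(p, n_eff, level = 0.95)
  wilson_ci(p, n_eff, level)

#' Events-per-variable check for the disease model
#'
#' EPV = (events among verified) / (number of design columns).  Below 10,
#' unpenalized logistic coefficients are prone to small-sample bias and the
#' Firth-penalized fit is recommended.
#'
#' @param data a `screening_data` object.
#' @param n_covariates number of design columns (default: number of tests,
#'   the main-effects model).
#' @param threshold flag level (default 10).
#' @return List of class `epv_report`: `events`, `n_covariates`, `epv`,
#'   `flag` (TRUE when EPV below threshold), `estimable` (FALSE when there
#'   are no events).
#' @export
epv_check <- function(data, n_covariates = length(test_names(data)),
                      threshold = 10) {
  events <- sum(data$verified == 1L & data$disease == 1L, na.rm = TRUE)
  epv <- events / n_covariates
  structure(list(events = events, n_covariates = n_covariates, epv = epv,
                 flag = epv < threshold, estimable = events > 0,
                 threshold = threshold),
            class = "epv_report")
}

#' @export
print.epv_report <- function(x, ...) {
  cat(sprintf("EPV = %d events / %d covariates = %.2f\n",
              x$events, x$n_covariates, x$epv))
  if (!x$estimable)
    cat("  no events: the disease model is not estimable\n")
  else if (x$flag)
    cat(sprintf("  EPV < %g: use the Firth-penalized fit\n", x$threshold))
  invisible(x)
}

mi_measure_rows <- function(completed, tn_) {
  # per-completed-dataset numerators and denominators, same ordering as
  # complete-case/bg reports: prevalence first, then 5 rows per test
  d <- completed$disease
  n <- nrow(completed)
  rows <- list(c(sum(d == 1L), n))
  for (tst in tn_) {
    x <- completed[[tst]]
    tp <- sum(x == 1L & d == 1L); fp <- sum(x == 1L & d == 0L)
    fn <- sum(x == 0L & d == 1L); tn2 <- sum(x == 0L & d == 0L)
    rows <- c(rows, list(c(tp, tp + fn), c(tn2, tn2 + fp),
                         c(tp, tp + fp), c(tn2, tn2 + fn),
                         c(tp + fp, n)))
  }
  do.call(rbind, rows)
}

#' Multiple-imputation estimate of screening-test accuracy
#'
#' The imputation algorithm: (1) fit the logistic disease model on the
#' verified records (Firth-penalized when `penalized = TRUE`, the default
#' given low-EPV screening data); (2) for each non-verified participant
#' draw disease status from the model's predicted probability; (3) compute
#' all accuracy measures on the completed cohort; (4) repeat for `m`
#' imputations; (5) average the per-imputation estimates; (6) combine
#' variances by Rubin's rules and form Wilson intervals on the effective
#' sample size.  The model is fitted once on the observed verified data and
#' held fixed across imputations; `proper = TRUE` additionally draws the
#' coefficient vector per imputation from its asymptotic normal
#' approximation.
#'
#' Within-imputation variance for each proportion is `p (1 - p) / n` on
#' that imputation's completed-data denominator, with boundary proportions
#' clamped to `0.5 / (n + 1)` so pooling never divides by zero.
#'
#' @param data a `screening_data` object whose verified subset has at least
#'   one event and one non-event.
#' @param m number of imputations (default 100).
#' @param penalized use the Firth fit (default `TRUE`).
#' @param seed RNG seed (set it for reproducibility).
#' @param level confidence level (default 0.95).
#' @param proper draw the model coefficients per imputation (default
#'   `FALSE`).
#' @return A data frame of class `accuracy_estimates` with pooled points,
#'   Wilson intervals on the effective sample size and columns
#'   `within`, `between`, `total`, `n_eff`, `m_used`; attributes
#'   `expected_cases` (mean imputed case count, raw and rounded), `model`
#'   (the fitted disease model) and `epv` (the [epv_check()] report).
#' @export
mi_estimate <- function(data, m = 100, penalized = TRUE, seed = NULL,
                        level = 0.95, proper = FALSE) {
  if (m < 2) stop("m must be >= 2: Rubin's between-imputation variance ",
                  "needs at least two imputations")
  if (!is.null(seed)) set.seed(seed)
  tn_ <- test_names(data)
  ver <- data[data$verified == 1L, , drop = FALSE]
  if (nrow(ver) == 0L) stop("no verified participants")
  y <- ver$disease
  X <- as.matrix(ver[tn_])
  if (!penalized && (all(y == 1) || all(y == 0)))
    stop("verified subset has no events or no non-events; use the ",
         "penalized fit")
  model <- if (penalized) fit_firth(X, y) else fit_ml(X, y)
  if (!model$converged)
    stop("disease model did not converge", if (model$separation)
      " (separation detected; use penalized = TRUE)" else "")

  n_measures <- 1L + 5L * length(tn_)
  points <- matrix(NA_real_, m, n_measures)
  vars <- matrix(NA_real_, m, n_measures)
  denoms <- matrix(NA_real_, m, n_measures)
  cases <- numeric(m)
  base_model <- model
  for (l in seq_len(m)) {
    if (proper && !is.null(base_model$vcov)) {
      ch <- chol(base_model$vcov)
      model$coefficients <- base_model$coefficients +
        drop(crossprod(ch, stats::rnorm(length(base_model$coefficients))))
    }
    completed <- impute_once(data, model)
    cases[l] <- sum(completed$disease == 1L)
    nd <- mi_measure_rows(completed, tn_)
    ok <- nd[, 2] > 0
    p_l <- ifelse(ok, nd[, 1] / nd[, 2], NA_real_)
    eps <- 0.5 / (nd[, 2] + 1)
    p_cl <- pmin(pmax(p_l, eps), 1 - eps)
    points[l, ] <- p_l
    vars[l, ] <- ifelse(ok, p_cl * (1 - p_cl) / nd[, 2], NA_real_)
    denoms[l, ] <- nd[, 2]
  }

  measure_names <- c("prevalence",
                     as.vector(t(outer(tn_, c("sensitivity", "specificity",
                                              "ppv", "npv",
                                              "positive_test_prevalence"),
                                       function(a, b) b))))
  test_col <- c("(all)", rep(tn_, each = 5))
  rows <- vector("list", n_measures)
  n_undefined <- 0L
  for (i in seq_len(n_measures)) {
    ok <- !is.na(points[, i])
    m_used <- sum(ok)
    n_undefined <- n_undefined + (m - m_used)
    if (m_used < 2) {
      rows[[i]] <- data.frame(test = test_col[i], measure = measure_names[i],
                              point = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, ci_method = "wilson-mi",
                              denominator = NA_real_, within = NA_real_,
                              between = NA_real_, total = NA_real_,
                              n_eff = NA_real_, m_used = m_used,
                              stringsAsFactors = FALSE)
      next
    }
    pooled <- rubin_pool(points[ok, i], vars[ok, i])
    nominal <- mean(denoms[ok, i])
    n_eff <- effective_sample_size(pooled$point, pooled$total, nominal)
    ci <- pooled_wilson_ci(pooled$point, n_eff, level)
    rows[[i]] <- data.frame(test = test_col[i], measure = measure_names[i],
                            point = pooled$point, ci_low = ci[[1]],
                            ci_high = ci[[2]], ci_method = "wilson-mi",
                            denominator = nominal, within = pooled$within,
                            between = pooled$between, total = pooled$total,
                            n_eff = n_eff, m_used = m_used,
                            stringsAsFactors = FALSE)
  }
  if (n_undefined > 0)
    warning(sprintf(
      "%d imputation-measure combinations had a zero denominator and were ",
      n_undefined), "excluded from pooling", call. = FALSE)
  out <- do.call(rbind, rows)
  structure(out, n = nrow(data), n_verified = nrow(ver),
            method = if (penalized) "mi-firth" else "mi",
            expected_cases = list(raw = mean(cases),
                                  rounded = round(mean(cases))),
            model = base_model, epv = epv_check(data),
            seed = seed, m = m,
            class = c("accuracy_estimates", "data.frame"))
}
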