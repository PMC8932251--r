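#' Allocate non-verified participants across disease status (Begg-Greenes)
#'
#' Under the missing-at-random assumption, the disease split observed among
#' verified participants of a screening-result stratum applies to the
#' non-verified participants of the same stratum.  Each stratum's
#' non-verified total is therefore split in proportion to the verified
#' disease split, producing expected (fractional) counts that are kept at
#' full precision: rounding before summation would break conservation of
#' the cohort size.
#'
#' @param table a `stratum_table`.
#' @return A data frame of class `allocated_table`: the stratum table plus
#'   columns `e_dis` and `e_nodis`, the expected numbers of non-verified
#'   participants with and without the condition
#'   (`e_dis + e_nodis = n_unver` exactly, per stratum).
#' @export
allocate_nonverified <- function(table) {
  check <- validate_for_begg_greenes(table)
  if (!check$pass) {
    pats <- apply(check$offending_patterns, 1, paste, collapse = "")
    stop(sprintf(
      paste("Begg-Greenes allocation impossible: stratum(s) %s contain",
            "non-verified participants but no verified ones; consider",
            "multiple imputation, which models disease status across",
            "strata"),
      paste(pats, collapse = ", ")), call. = FALSE)
  }
  frac <- ifelse(table$n_ver > 0, table$n_ver_dis / table$n_ver, 0)
  table$e_dis <- table$n_unver * frac
  table$e_nodis <- table$n_unver - table$e_dis
  structure(table, class = c("allocated_table", class(table)))
}

# expected completed-cohort disease-split columns of an allocated table
allocated_cells <- function(allocated) {
  list(d1 = allocated$n_ver_dis + allocated$e_dis,
       d0 = allocated$n_ver_nodis + allocated$e_nodis)
}

#' Begg-Greenes adjusted accuracy measures
#'
#' Marginalizes the allocated stratum table to per-test accuracy measures:
#' sensitivity is the expected number of diseased participants in
#' test-positive strata over the expected number of diseased participants
#' overall, and analogously for the other measures.  This stratum-sum form
#' is algebraically identical to the Bayes-theorem expression
#' `Pr(R | D) = sum_q Pr(Q = q) Pr(D | Q = q, V = 1)` restricted to strata
#' with the test positive, with both probabilities estimated from the data.
#' With no non-verified participants it reduces exactly to the
#' complete-case estimator.
#'
#' @param allocated an `allocated_table` from [allocate_nonverified()].
#' @param tests which tests to report (names or indices; default all).
#' @return A data frame of class `accuracy_estimates` of point estimates
#'   (no intervals; see [bg_bootstrap()]): the four measures and
#'   positive-test prevalence per test plus the adjusted disease
#'   prevalence.  Zero-denominator measures are `NA`.
#' @export
bg_accuracy <- function(allocated, tests = NULL) {
  tn_ <- test_names(allocated)
  if (is.null(tests)) tests <- tn_
  if (is.numeric(tests)) tests <- tn_[tests]
  cells <- allocated_cells(allocated)
  N <- sum(cells$d1 + cells$d0)
  total_d1 <- sum(cells$d1)
  total_d0 <- sum(cells$d0)
  point_row <- function(measure, tst, num, denom)
    data.frame(test = tst, measure = measure,
               point = if (denom > 0) num / denom else NA_real_,
               ci_low = NA_real_, ci_high = NA_real_,
               ci_method = "none", denominator = denom,
               stringsAsFactors = FALSE)
  rows <- list(point_row("prevalence", "(all)", total_d1, N))
  for (tst in tests) {
    pos <- allocated[[tst]] == 1L
    d1_pos <- sum(cells$d1[pos]); d0_pos <- sum(cells$d0[pos])
    d1_neg <- total_d1 - d1_pos;  d0_neg <- total_d0 - d0_pos
    rows <- c(rows, list(
      point_row("sensitivity", tst, d1_pos, total_d1),
      point_row("specificity", tst, d0_neg, total_d0),
      point_row("ppv", tst, d1_pos, d1_pos + d0_pos),
      point_row("npv", tst, d0_neg, d0_neg + d1_neg),
      point_row("positive_test_prevalence", tst, d1_pos + d0_pos, N)))
  }
  out <- do.call(rbind, rows)
  structure(out, n = N, n_verified = sum(allocated$n_ver), method = "bg",
            class = c("accuracy_estimates", "data.frame"))
}

#' Expected number of cases in the completed cohort
#'
#' Sum over strata of observed verified cases plus allocated expected cases
#' among the non-verified.
#'
#' @param allocated an `allocated_table`.
#' @return A list with `raw` (fractional) and `rounded` counts.
#' @export
bg_expected_cases <- function(allocated) {
  raw <- sum(allocated$n_ver_dis + allocated$e_dis)
  list(raw = raw, rounded = round(raw))
}

#' Begg-Greenes estimate with bootstrap confidence intervals
#'
#' Point estimates from [bg_accuracy()] on the full data plus intervals
#' from `B` participant-level resamples with replacement (verified and
#' non-verified together).  A resample can lose all verified members of a
#' stratum that still holds non-verified ones — most plausibly the single
#' verified all-negative participant — making the allocation undefined for
#' that replicate; such replicates are redrawn (default) or dropped,
#' according to `invalid_policy`, and the number encountered is reported.
#'
#' @param data a `screening_data` object passing
#'   [validate_for_begg_greenes()].
#' @param B number of bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed; required for a reproducible interval.
#' @param type `"percentile"` (default) or `"basic"` bootstrap interval.
#' @param invalid_policy `"redraw"` (default) or `"drop"` for replicates
#'   violating the identifiability condition.
#' @param max_redraws total extra draws allowed before giving up (default
#'   `100 * B`).
#' @return A data frame of class `accuracy_estimates` with percentile (or
#'   basic) intervals attached to the full-data points; attributes
#'   `n_invalid` (invalid replicates encountered) and `B_used`.
#' @export
bg_bootstrap <- function(data, B = 1000, level = 0.95, seed = NULL,
                         type = c("percentile", "basic"),
                         invalid_policy = c("redraw", "drop"),
                         max_redraws = 100 * B) {
  type <- match.arg(type)
  invalid_policy <- match.arg(invalid_policy)
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  tn_ <- test_names(data)
  K <- length(tn_)
  nbin <- 2^K
  n <- nrow(data)
  # per-participant cell index: stratum x {verified-diseased, verified-not,
  # non-verified}; a resample's stratum table is one tabulate() call
  q <- stratum_code(data[tn_])
  cell <- 3L * q + ifelse(data$verified == 1L,
                          ifelse(data$disease == 1L, 1L, 2L), 3L)
  pat <- stratum_patterns(K, tn_)
  base_tab <- build_stratum_table(data)
  est0 <- bg_accuracy(allocate_nonverified(base_tab))
  stats_from_counts <- function(counts) {
    m <- matrix(counts, nrow = nbin, byrow = TRUE)  # dis, nodis, unver
    n_ver <- m[, 1] + m[, 2]
    if (any(m[, 3] > 0 & n_ver == 0)) return(NULL)
    frac <- ifelse(n_ver > 0, m[, 1] / n_ver, 0)
    d1 <- m[, 1] + m[, 3] * frac
    d0 <- m[, 2] + m[, 3] * (1 - frac)
    td1 <- sum(d1); td0 <- sum(d0)
    out <- c(if (td1 + td0 > 0) td1 / (td1 + td0) else NA_real_)
    for (j in seq_len(K)) {
      pos <- pat[, j] == 1L
      d1p <- sum(d1[pos]); d0p <- sum(d0[pos])
      d1n <- td1 - d1p; d0n <- td0 - d0p
      out <- c(out,
               if (td1 > 0) d1p / td1 else NA_real_,
               if (td0 > 0) d0n / td0 else NA_real_,
               if (d1p + d0p > 0) d1p / (d1p + d0p) else NA_real_,
               if (d0n + d1n > 0) d0n / (d0n + d1n) else NA_real_,
               (d1p + d0p) / (td1 + td0))
    }
    out
  }

  reps <- matrix(NA_real_, nrow = B, ncol = 1 + 5 * K)
  n_invalid <- 0L
  kept <- 0L
  draws_left <- B + max_redraws
  while (kept < B && draws_left > 0L) {
    draws_left <- draws_left - 1L
    idx <- sample.int(n, n, replace = TRUE)
    counts <- tabulate(cell[idx], nbins = 3L * nbin)
    s <- stats_from_counts(counts)
    if (is.null(s)) {
      n_invalid <- n_invalid + 1L
      if (invalid_policy == "drop") { B <- B - 1L }
      next
    }
    kept <- kept + 1L
    reps[kept, ] <- s
  }
  if (kept == 0L)
    stop("no valid bootstrap replicate: nearly every resample loses the ",
         "verified anchor of a stratum with non-verified participants; ",
         "the verified audit fraction is too small for bootstrap intervals")
  if (kept < B)
    stop("exceeded max_redraws while redrawing invalid bootstrap ",
         "replicates; the verified audit fraction is too small")
  reps <- reps[seq_len(kept), , drop = FALSE]

  alpha <- 1 - level
  est <- est0
  for (i in seq_len(nrow(est))) {
    col <- i  # rows of bg_accuracy follow the same measure ordering
    vals <- reps[, col]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) next
    # type 6 implements the (B+1)*alpha order-statistic convention for
    # percentile endpoints
    qs <- stats::quantile(vals, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                          type = 6)
    if (type == "percentile") {
      est$ci_low[i] <- qs[1]; est$ci_high[i] <- qs[2]
    } else {
      est$ci_low[i] <- max(0, 2 * est$point[i] - qs[2])
      est$ci_high[i] <- min(1, 2 * est$point[i] - qs[1])
    }
    est$ci_method[i] <- paste0("bootstrap-", type)
  }
  attr(est, "B_used") <- kept
  attr(est, "n_invalid") <- n_invalid
  attr(est, "seed") <- seed
  est
}

#' One-call Begg-Greenes analysis of a screening dataset
#'
#' Tabulates, allocates and marginalizes; optionally adds bootstrap
#' intervals.
#'
#' @inheritParams bg_bootstrap
#' @param boot if `TRUE` (default when `seed` is given), attach bootstrap
#'   intervals.
#' @return An `accuracy_estimates` data frame with attribute
#'   `expected_cases`.
#' @export
bg_estimate <- function(data, B = 1000, level = 0.95, seed = NULL,
                        boot = !is.null(seed), ...) {
  allocated <- allocate_nonverified(build_stratum_table(data))
  est <- if (boot) {
    bg_bootstrap(data, B = B, level = level, seed = seed, ...)
  } else {
    bg_accuracy(allocated)
  }
  attr(est, "expected_cases") <- bg_expected_cases(allocated)
  est
}
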