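#' Participant-level screening data
#'
#' A `screening_data` object is a data frame with one row per participant:
#' an `id` column, one 0/1 column per screening test, a 0/1 verification
#' indicator `verified` (1 = underwent the reference standard) and a
#' `disease` column holding the reference-standard result, which is `NA`
#' exactly when `verified == 0` (condition status is unobservable without
#' the reference standard).
#'
#' @param tests data frame or matrix of 0/1 test results, one column per test.
#' @param verified integer vector of 0/1 verification indicators.
#' @param disease integer vector of 0/1 disease statuses; values supplied for
#'   non-verified participants are discarded with a warning, since disease
#'   status is missing by design when the reference standard was not done.
#' @param id optional participant identifiers; defaults to row numbers.
#' @param test_names optional test labels; defaults to the column names of
#'   `tests`.
#'
#' @return A data frame of class `screening_data` with attribute
#'   `test_names`.
#' @export
screening_data <- function(tests, verified, disease, id = NULL,
                           test_names = NULL) {
  tests <- as.data.frame(tests)
  if (is.null(test_names)) {
    test_names <- names(tests)
    if (is.null(test_names) || any(!nzchar(test_names)))
      test_names <- paste0("test", seq_along(tests))
  }
  names(tests) <- test_names
  K <- length(test_names)
  if (K < 1L) stop("at least one screening test column is required")
  n <- nrow(tests)
  if (length(verified) != n || length(disease) != n)
    stop("'verified' and 'disease' must have one entry per participant")
  if (is.null(id)) id <- seq_len(n)

  for (j in seq_len(K)) {
    bad <- which(!(tests[[j]] %in% c(0L, 1L)) | is.na(tests[[j]]))
    if (length(bad))
      stop(sprintf("non-binary value in test column '%s' at row %d",
                   test_names[j], bad[1]), call. = FALSE)
  }
  bad <- which(!(verified %in% c(0L, 1L)) | is.na(verified))
  if (length(bad))
    stop(sprintf("non-binary value in verified column at row %d", bad[1]),
         call. = FALSE)
  if (any(!is.na(disease) & !(disease %in% c(0L, 1L))))
    stop("disease column must be 0/1 or missing", call. = FALSE)
  if (any(verified == 1L & is.na(disease)))
    stop("verified participants must have an observed disease status",
         call. = FALSE)
  stray <- verified == 0L & !is.na(disease)
  if (any(stray)) {
    warning(sprintf(
      "%d non-verified participant(s) carried a disease value; set to missing",
      sum(stray)), call. = FALSE)
    disease[stray] <- NA_integer_
  }

  out <- data.frame(id = id, tests, verified = as.integer(verified),
                    disease = as.integer(disease),
                    check.names = FALSE, stringsAsFactors = FALSE)
  structure(out, test_names = test_names,
            class = c("screening_data", "data.frame"))
}

#' @export
print.screening_data <- function(x, ...) {
  tn <- test_names(x)
  cat(sprintf("Screening dataset: %d participants, %d tests (%s)\n",
              nrow(x), length(tn), paste(tn, collapse = ", ")))
  nv <- sum(x$verified == 1L)
  cat(sprintf("  verified: %d (%.1f%%); disease among verified: %d\n",
              nv, if (nrow(x)) 100 * nv / nrow(x) else 0,
              sum(x$disease == 1L, na.rm = TRUE)))
  invisible(x)
}

#' Test labels of a screening dataset
#' @param x a `screening_data` object.
#' @return Character vector of test names.
#' @export
test_names <- function(x) attr(x, "test_names")

#' Read a participant-level screening study from a delimited file
#'
#' Reads a CSV with a header row, keeps only participants with all K test
#' results present and 0/1-coded, and reports the number excluded.  Disease
#' status is set to missing wherever the participant was not verified.
#'
#' @param path file path of a delimited text table.
#' @param test_columns character vector naming the K test-result columns.
#' @param verified_column name of the 0/1 verification column.
#' @param disease_column name of the 0/1 disease-status column.
#' @param id_column optional name of an identifier column.
#' @param na_strings values interpreted as missing (default empty string
#'   and `"NA"`).
#' @param sep field separator.
#'
#' @return A `screening_data` object; the number of rows dropped for missing
#'   test results is available as `attr(, "n_excluded")` and is also
#'   messaged.
#' @export
read_screening_data <- function(path, test_columns,
                                verified_column = "verified",
                                disease_column = "disease",
                                id_column = NULL,
                                na_strings = c("", "NA"),
                                sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = na_strings,
                           stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(test_columns, verified_column, disease_column, id_column)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop(sprintf("input file lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)

  keep <- !Reduce(`|`, lapply(raw[test_columns], is.na))
  if (length(keep) == 0L) keep <- logical(0)
  n_excl <- sum(!keep)
  dat <- raw[keep, , drop = FALSE]

  for (cl in c(test_columns, verified_column)) {
    v <- dat[[cl]]
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("non-binary value in column '%s' at data row %d",
                   cl, bad[1]), call. = FALSE)
  }
  id <- if (is.null(id_column)) rownames(dat) else dat[[id_column]]
  if (length(id) == 0L) id <- integer(0)

  out <- screening_data(
    tests = dat[test_columns],
    verified = as.integer(dat[[verified_column]]),
    disease = suppressWarnings(as.integer(dat[[disease_column]])),
    id = id, test_names = test_columns)
  attr(out, "n_excluded") <- n_excl
  if (n_excl > 0)
    message(sprintf("%d participant(s) excluded for missing test results",
                    n_excl))
  out
}

# Integer stratum code in 0..2^K-1: test 1 is the most significant bit, so
# codes enumerate combinations in the fixed binary order used everywhere.
stratum_code <- function(tests) {
  tests <- as.matrix(tests)
  K <- ncol(tests)
  as.integer(tests %*% (2 ^ ((K - 1):0)))
}

stratum_patterns <- function(K, test_names = paste0("test", seq_len(K))) {
  codes <- 0:(2^K - 1)
  pat <- sapply((K - 1):0, function(b) bitwAnd(codes, bitwShiftL(1L, b)) > 0L)
  pat <- matrix(as.integer(pat), nrow = 2^K)
  colnames(pat) <- test_names
  pat
}

#' Tabulate a screening dataset over the 2^K screening-result strata
#'
#' Produces the stratum table all estimators consume: for each of the 2^K
#' combinations of test results, the number of verified participants with
#' and without the condition and the number of non-verified participants.
#' Strata are listed in binary order with the first test as the most
#' significant bit.
#'
#' @param data a `screening_data` object.
#' @return A data frame of class `stratum_table` with one row per stratum:
#'   the K test-result columns, `n_ver_dis`, `n_ver_nodis`, `n_unver`, and
#'   `n_ver` (= `n_ver_dis + n_ver_nodis`).
#' @export
build_stratum_table <- function(data) {
  tn <- test_names(data)
  K <- length(tn)
  nbin <- 2^K
  q <- stratum_code(data[tn])
  ver <- data$verified == 1L
  dis <- !is.na(data$disease) & data$disease == 1L
  tab <- data.frame(stratum_patterns(K, tn),
                    n_ver_dis = tabulate(q[ver & dis] + 1L, nbins = nbin),
                    n_ver_nodis = tabulate(q[ver & !dis] + 1L, nbins = nbin),
                    n_unver = tabulate(q[!ver] + 1L, nbins = nbin),
                    check.names = FALSE)
  tab$n_ver <- tab$n_ver_dis + tab$n_ver_nodis
  structure(tab, test_names = tn,
            class = c("stratum_table", "data.frame"))
}

#' @export
print.stratum_table <- function(x, ...) {
  cat(sprintf("Stratum table: %d strata over tests (%s)\n",
              nrow(x), paste(test_names(x), collapse = ", ")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Reconstruct a participant-level dataset from a stratum table
#'
#' Inverse of [build_stratum_table()] up to participant identity: expands
#' each stratum's counts into synthetic records.  Useful for building
#' fixtures and for feeding count-level published tables to the estimators.
#'
#' @param table a `stratum_table` (integer counts).
#' @return A `screening_data` object with synthetic ids.
#' @export
expand_stratum_table <- function(table) {
  tn <- test_names(table)
  counts <- cbind(table$n_ver_dis, table$n_ver_nodis, table$n_unver)
  if (any(counts != round(counts)))
    stop("stratum counts must be integers to expand into records")
  reps <- rowSums(counts)
  idx <- rep(seq_len(nrow(table)), reps)
  ver <- unlist(lapply(seq_len(nrow(table)), function(i)
    rep(c(1L, 1L, 0L), counts[i, ])))
  dis <- unlist(lapply(seq_len(nrow(table)), function(i)
    rep(c(1L, 0L, NA_integer_), counts[i, ])))
  screening_data(tests = as.data.frame(table[idx, tn, drop = FALSE],
                                       check.names = FALSE),
                 verified = if (length(idx)) ver else integer(0),
                 disease = if (length(idx)) dis else integer(0),
                 test_names = tn)
}

#' Check a stratum table against the Begg-Greenes identifiability condition
#'
#' The allocation estimator needs, in every stratum that contains
#' non-verified participants, at least one verified participant to supply
#' the disease split.  The all-negative stratum is flagged specially: the
#' method's identifying assumption is that the disease prevalence among
#' verified screen-negatives applies to all screen-negatives, which fails
#' by design when no screen-negative participant is ever verified.
#'
#' @param table a `stratum_table`, or a `screening_data` object (tabulated
#'   first).
#' @return A list of class `bg_validation` with elements `pass` (logical),
#'   `offending` (row indices of strata with non-verified participants but
#'   no verified ones) and `all_negative_unidentified` (logical).
#' @export
validate_for_begg_greenes <- function(table) {
  if (inherits(table, "screening_data")) table <- build_stratum_table(table)
  off <- which(table$n_unver > 0 & table$n_ver == 0)
  allneg <- 1L  # binary order puts the all-negative stratum first
  structure(list(
    pass = length(off) == 0L,
    offending = off,
    offending_patterns = as.data.frame(
      table[off, test_names(table), drop = FALSE], check.names = FALSE),
    all_negative_unidentified = allneg %in% off),
    class = "bg_validation")
}

#' @export
print.bg_validation <- function(x, ...) {
  if (x$pass) {
    cat("Begg-Greenes identifiability: PASS\n")
  } else {
    cat("Begg-Greenes identifiability: FAIL\n")
    cat("  strata with non-verified participants but no verified ones:\n")
    print(x$offending_patterns, row.names = FALSE)
    if (x$all_negative_unidentified)
      cat("  the all-negative stratum is unidentified: no screen-negative",
          "participant was verified, so the screen-negative prevalence",
          "assumption cannot be anchored.\n")
    cat("  consider multiple imputation, which borrows strength across",
        "strata through the disease model.\n")
  }
  invisible(x)
}

#' Dichotomize continuous marker columns at fixed cutoffs
#'
#' Convenience pre-processing: applies `value >= cutoff -> 1` per named
#' column, leaving the core estimators strictly binary.
#'
#' @param data a data frame.
#' @param cutoffs named numeric vector; names are columns of `data`.
#' @return `data` with the named columns replaced by 0/1 indicators.
#' @export
apply_thresholds <- function(data, cutoffs) {
  missing_cols <- setdiff(names(cutoffs), names(data))
  if (length(missing_cols))
    stop(sprintf("no such column(s): %s", paste(missing_cols, collapse = ", ")))
  for (cl in names(cutoffs))
    data[[cl]] <- as.integer(data[[cl]] >= cutoffs[[cl]])
  data
}

#' Packaged synthetic screening-study fixture
#'
#' Loads the participant-level CSV shipped with the package: a 403-record,
#' three-test (MRI, ultrasound, PSA) prostate-cancer screening cohort with
#' an any-positive verification rule.  The non-verified stratum counts are
#' the published ones (237 non-verified, 220 of them all-negative); the
#' joint allocation of the 166 verified participants across strata is
#' synthetic, constructed to match every published complete-case marginal
#' (16 cases; per-test confusion tables) since the verified joint counts
#' were never published.
#'
#' @return A `screening_data` object with tests `mri`, `ultrasound`, `psa`.
#' @export
prostagram_fixture <- function() {
  path <- system.file("extdata", "prostagram_synthetic.csv",
                      package = "veribias", mustWork = TRUE)
  read_screening_data(path, test_columns = c("mri", "ultrasound", "psa"),
                      verified_column = "verified",
                      disease_column = "disease", id_column = "id")
}
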