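# fixtures built in code

# dataset from per-stratum counts: counts is a data.frame with the K test
# columns plus n_ver_dis / n_ver_nodis / n_unver
dataset_from_counts <- function(counts, test_cols) {
  tab <- build_stratum_table(
    screening_data(tests = counts[0, test_cols, drop = FALSE],
                   verified = integer(0), disease = integer(0),
                   test_names = test_cols))
  key_tab <- do.call(paste, tab[test_cols])
  key_in <- do.call(paste, counts[test_cols])
  for (cl in c("n_ver_dis", "n_ver_nodis", "n_unver"))
    tab[[cl]][match(key_in, key_tab)] <- counts[[cl]]
  tab$n_ver <- tab$n_ver_dis + tab$n_ver_nodis
  expand_stratum_table(tab)
}

random_stratum_table <- function(K = 2, max_count = 8) {
  nbin <- 2^K
  repeat {
    tab <- data.frame(stratum_patterns_for_test(K),
                      n_ver_dis = sample(0:max_count, nbin, replace = TRUE),
                      n_ver_nodis = sample(0:max_count, nbin, replace = TRUE),
                      n_unver = sample(0:max_count, nbin, replace = TRUE),
                      check.names = FALSE)
    tab$n_ver <- tab$n_ver_dis + tab$n_ver_nodis
    # keep only identifiable tables with at least one case and one control
    if (all(tab$n_ver > 0 | tab$n_unver == 0) &&
        sum(tab$n_ver_dis) > 0 && sum(tab$n_ver_nodis) > 0) break
  }
  structure(tab, test_names = colnames(stratum_patterns_for_test(K)),
            class = c("stratum_table", "data.frame"))
}

stratum_patterns_for_test <- function(K) {
  codes <- 0:(2^K - 1)
  pat <- sapply((K - 1):0, function(b) bitwAnd(codes, bitwShiftL(1L, b)) > 0L)
  pat <- matrix(as.integer(pat), nrow = 2^K)
  colnames(pat) <- paste0("test", seq_len(K))
  pat
}

# independent oracle: the Bayes-theorem form of the adjusted measures, via
# estimated probabilities Pr(Q) and Pr(D = 1 | Q, V = 1)
bayes_oracle <- function(table, test_col) {
  N <- sum(table$n_ver + table$n_unver)
  Pq <- (table$n_ver + table$n_unver) / N
  PD <- ifelse(table$n_ver > 0, table$n_ver_dis / table$n_ver, 0)
  pos <- table[[test_col]] == 1L
  num_d1 <- sum(Pq[pos] * PD[pos])
  den_d1 <- sum(Pq * PD)
  num_d0 <- sum(Pq[!pos] * (1 - PD[!pos]))
  den_d0 <- sum(Pq * (1 - PD))
  list(sensitivity = num_d1 / den_d1,
       specificity = num_d0 / den_d0,
       ppv = sum(Pq[pos] * PD[pos]) / sum(Pq[pos]),
       npv = sum(Pq[!pos] * (1 - PD[!pos])) / sum(Pq[!pos]),
       prevalence = den_d1)
}

get_est <- function(est, tst, msr) {
  df <- as.data.frame(est)
  df[df$test == tst & df$measure == msr, , drop = FALSE]
}

point_of <- function(est, tst, msr) get_est(est, tst, msr)$point

`%||%` <- function(a, b) if (is.null(a)) b else a
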