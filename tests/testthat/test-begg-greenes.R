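test_that("allocation splits each stratum by its verified disease fraction", {
  counts <- data.frame(a = c(0, 1), b = c(0, 0),
                       n_ver_dis = c(1, 2), n_ver_nodis = c(3, 2),
                       n_unver = c(8, 5))
  dat <- dataset_from_counts(counts, c("a", "b"))
  alloc <- allocate_nonverified(build_stratum_table(dat))
  row <- alloc[alloc$a == 0 & alloc$b == 0, ]
  expect_equal(row$e_dis, 2)    # 1/4 of 8
  expect_equal(row$e_nodis, 6)  # 3/4 of 8
  row2 <- alloc[alloc$a == 1 & alloc$b == 0, ]
  expect_equal(row2$e_dis, 2.5)  # fractional expected counts kept
  expect_equal(row2$e_nodis, 2.5)
  empty <- alloc[alloc$n_unver == 0, ]
  expect_true(all(empty$e_dis == 0 & empty$e_nodis == 0))
})

test_that("allocation conserves totals and is exact per stratum", {
  set.seed(20)
  for (i in 1:50) {
    K <- sample(1:3, 1)
    tab <- random_stratum_table(K)
    alloc <- allocate_nonverified(tab)
    expect_true(all(abs(alloc$e_dis + alloc$e_nodis - alloc$n_unver) < 1e-12))
    expect_equal(sum(alloc$n_ver_dis + alloc$n_ver_nodis +
                       alloc$e_dis + alloc$e_nodis),
                 sum(tab$n_ver + tab$n_unver))
  }
})

test_that("allocation refuses unidentified strata and points to MI", {
  counts <- data.frame(a = c(0, 1), b = c(0, 0),
                       n_ver_dis = c(1, 0), n_ver_nodis = c(3, 0),
                       n_unver = c(8, 4))
  dat <- dataset_from_counts(counts, c("a", "b"))
  expect_error(allocate_nonverified(build_stratum_table(dat)),
               "10.*imputation")
})

test_that("with everyone verified the adjusted and complete-case estimates coincide", {
  set.seed(21)
  n <- 300
  tests <- data.frame(x = rbinom(n, 1, 0.4), y = rbinom(n, 1, 0.3))
  dat <- screening_data(tests, verified = rep(1L, n),
                        disease = rbinom(n, 1, 0.2))
  bg <- bg_accuracy(allocate_nonverified(build_stratum_table(dat)))
  cc <- complete_case_estimates(dat)
  expect_equal(bg$point, cc$point)
  expect_equal(bg$denominator, cc$denominator)
})

test_that("stratum-sum estimator equals the Bayes-theorem oracle", {
  set.seed(22)
  for (i in 1:200) {
    K <- sample(1:3, 1)
    tab <- random_stratum_table(K)
    alloc <- allocate_nonverified(tab)
    est <- bg_accuracy(alloc)
    for (tst in attr(tab, "test_names")) {
      oracle <- bayes_oracle(tab, tst)
      for (msr in c("sensitivity", "specificity", "ppv", "npv")) {
        got <- point_of(est, tst, msr)
        if (!is.na(got) && is.finite(oracle[[msr]]))
          expect_equal(got, oracle[[msr]], tolerance = 1e-10)
      }
    }
    expect_equal(point_of(est, "(all)", "prevalence"),
                 bayes_oracle(tab, attr(tab, "test_names")[1])$prevalence,
                 tolerance = 1e-10)
  }
})

test_that("K = 1 reproduces the classic single-test estimator", {
  # classic 2x2-with-missing layout: verified split by test result,
  # plus unverified totals per result
  counts <- data.frame(t = c(1, 0),
                       n_ver_dis = c(18, 3), n_ver_nodis = c(40, 60),
                       n_unver = c(10, 200))
  dat <- dataset_from_counts(counts, "t")
  est <- bg_accuracy(allocate_nonverified(build_stratum_table(dat)))
  # single-test closed form: within each result stratum the disease odds
  # of the verified apply to everyone
  d1_pos <- (18 + 40 + 10) * 18 / 58
  d1_neg <- (3 + 60 + 200) * 3 / 63
  d0_pos <- (18 + 40 + 10) * 40 / 58
  d0_neg <- (3 + 60 + 200) * 60 / 63
  expect_equal(point_of(est, "t", "sensitivity"), d1_pos / (d1_pos + d1_neg))
  expect_equal(point_of(est, "t", "specificity"), d0_neg / (d0_pos + d0_neg))
  expect_equal(point_of(est, "t", "ppv"), 18 / 58)
  expect_equal(point_of(est, "t", "npv"), 60 / 63)
})

test_that("expected case count sums observed and allocated cases", {
  dat <- prostagram_fixture()
  alloc <- allocate_nonverified(build_stratum_table(dat))
  cases <- bg_expected_cases(alloc)
  expect_equal(cases$rounded, 18)
  expect_gt(cases$raw, 16)

  counts <- data.frame(z = 0, n_ver_dis = 1, n_ver_nodis = 3, n_unver = 8)
  dat2 <- dataset_from_counts(counts, "z")
  expect_equal(bg_expected_cases(
    allocate_nonverified(build_stratum_table(dat2)))$raw, 3)

  all_ver <- screening_data(data.frame(z = rep(c(0, 1), 8)), rep(1L, 16),
                            rep(c(1, 0), 8))
  expect_equal(bg_expected_cases(
    allocate_nonverified(build_stratum_table(all_ver)))$raw, 8)
})

test_that("bootstrap is seed-reproducible and stable across seeds", {
  s <- simulate_screening(2000, 0.1, sens = c(0.85, 0.6), spec = c(0.75, 0.85),
                          audit_fraction = 0.1, seed = 30)
  b1 <- bg_bootstrap(s$data, B = 200, seed = 1)
  b1b <- bg_bootstrap(s$data, B = 200, seed = 1)
  expect_equal(b1$ci_low, b1b$ci_low)
  expect_equal(b1$ci_high, b1b$ci_high)
  b2 <- bg_bootstrap(s$data, B = 200, seed = 2)
  ok <- !is.na(b1$ci_low)
  expect_true(all(abs(b1$ci_low[ok] - b2$ci_low[ok]) < 0.03))
  expect_true(all(abs(b1$ci_high[ok] - b2$ci_high[ok]) < 0.03))
})

test_that("a degenerate one-stratum cohort bootstraps to a point", {
  dat <- screening_data(data.frame(t = rep(1L, 30)), rep(1L, 30),
                        rep(1L, 30))
  b <- bg_bootstrap(dat, B = 50, seed = 4)
  sens <- get_est(b, "t", "sensitivity")
  expect_equal(sens$point, 1)
  expect_equal(sens$ci_low, 1)
  expect_equal(sens$ci_high, 1)
})

test_that("replicates that lose a stratum anchor are redrawn and counted", {
  # one verified all-negative participant among many unverified: resamples
  # frequently drop it, so the redraw counter must engage
  counts <- data.frame(t = c(0, 1), n_ver_dis = c(0, 10),
                       n_ver_nodis = c(1, 20), n_unver = c(60, 0))
  dat <- dataset_from_counts(counts, "t")
  b <- bg_bootstrap(dat, B = 100, seed = 5)
  expect_gt(attr(b, "n_invalid"), 0)
  expect_equal(attr(b, "B_used"), 100)
})
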