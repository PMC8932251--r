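test_that("Rubin pooling follows the stated arithmetic", {
  p1 <- rubin_pool(rep(0.4, 5), rep(0.01, 5))
  expect_equal(p1$point, 0.4)
  expect_equal(p1$between, 0)
  expect_equal(p1$total, 0.01)

  p2 <- rubin_pool(c(0.2, 0.4), c(0.01, 0.01))
  expect_equal(p2$point, 0.3)
  expect_equal(p2$between, 0.02)
  expect_equal(p2$total, 0.01 + 1.5 * 0.02)

  # total collapses to the within term as spread vanishes
  set.seed(50)
  pts <- 0.35 + rnorm(100, sd = 1e-9)
  p3 <- rubin_pool(pts, rep(0.02, 100))
  expect_equal(p3$total, 0.02, tolerance = 1e-8)

  # identity T = W + (1 + 1/m) B on random inputs
  for (i in 1:20) {
    m <- sample(2:50, 1)
    pts <- runif(m)
    vs <- runif(m, 0, 0.05)
    p <- rubin_pool(pts, vs)
    expect_equal(p$total, p$within + (1 + 1 / m) * p$between,
                 tolerance = 1e-12)
    expect_true(p$point >= min(pts) && p$point <= max(pts))
  }
  expect_error(rubin_pool(0.4, 0.01), "two imputations")
})

test_that("effective sample size is the binomial moment match", {
  n <- 250
  p <- 0.3
  expect_equal(effective_sample_size(p, p * (1 - p) / n, n), n)
  expect_equal(effective_sample_size(p, 2 * p * (1 - p) / n, n), n / 2)
  expect_equal(effective_sample_size(0.1, 0.0009, 403), 100)
  expect_equal(effective_sample_size(0.5, 0, 77), 77)   # no missing info
  expect_lte(effective_sample_size(0.5, 1e-9, 100), 100)  # capped
  # boundary proportions use the shrinkage clamp instead of collapsing
  expect_gt(effective_sample_size(0, 0.001, 50), 0)
})

test_that("pooled Wilson interval widens exactly as n_eff shrinks", {
  expect_equal(pooled_wilson_ci(0.4, 80), wilson_ci(0.4, 80))
  w1 <- pooled_wilson_ci(0.3, 200)
  w2 <- pooled_wilson_ci(0.3, 100)
  expect_lt(w2[1], w1[1])
  expect_gt(w2[2], w1[2])
  r <- diff(pooled_wilson_ci(0.5, 25)) / diff(pooled_wilson_ci(0.5, 100))
  expect_equal(unname(r), 1.897478, tolerance = 1e-5)  # close to 2:1
})

test_that("EPV report flags sparse-event designs", {
  dat <- prostagram_fixture()
  rep <- epv_check(dat)
  expect_equal(rep$events, 16)
  expect_equal(rep$epv, 16 / 3)
  expect_true(rep$flag)

  rich <- screening_data(data.frame(a = rep(0:1, 60), b = rep(0:1, 60),
                                    c = rep(0:1, 60)),
                         verified = rep(1L, 120),
                         disease = rep(c(0, 1), each = 60))
  expect_false(epv_check(rich)$flag)

  none <- screening_data(data.frame(a = rep(0:1, 5)), rep(1L, 10),
                         rep(0L, 10))
  r0 <- epv_check(none)
  expect_equal(r0$epv, 0)
  expect_true(r0$flag)
  expect_false(r0$estimable)
})

test_that("single imputation draws match the predicted probability", {
  # 1000 copies of one non-verified record with predicted p
  model <- structure(list(coefficients = c(`(Intercept)` = qlogis(0.3),
                                           t = 0)),
                     class = "logistic_model")
  dat <- screening_data(data.frame(t = rep(1L, 1000)),
                        verified = rep(0L, 1000),
                        disease = rep(NA_integer_, 1000))
  set.seed(51)
  done <- impute_once(dat, model)
  expect_false(anyNA(done$disease))
  expect_lt(abs(mean(done$disease) - 0.3), 0.04)

  # fully verified data pass through untouched
  full <- screening_data(data.frame(t = 0:1), c(1L, 1L), c(0L, 1L))
  expect_identical(impute_once(full, model), full)

  # a large negative intercept forces disease = 0
  model0 <- structure(list(coefficients = c(`(Intercept)` = -30, t = 0)),
                      class = "logistic_model")
  set.seed(52)
  done0 <- impute_once(dat, model0)
  expect_true(all(done0$disease == 0L))
})

test_that("MI on fully verified data reduces to complete case with B = 0", {
  set.seed(53)
  n <- 200
  tests <- data.frame(x = rbinom(n, 1, 0.4), y = rbinom(n, 1, 0.3))
  d <- rbinom(n, 1, plogis(-2 + tests$x + tests$y))
  dat <- screening_data(tests, rep(1L, n), d)
  mi <- mi_estimate(dat, m = 5, penalized = TRUE, seed = 9)
  cc <- complete_case_estimates(dat)
  expect_equal(mi$point, cc$point)
  expect_true(all(mi$between == 0))
  # intervals equal the complete-data Wilson intervals
  for (i in seq_len(nrow(mi))) {
    w <- wilson_ci(cc$point[i], cc$denominator[i])
    expect_equal(mi$ci_low[i], unname(w[1]), tolerance = 1e-12)
    expect_equal(mi$ci_high[i], unname(w[2]), tolerance = 1e-12)
  }
})

test_that("MI is deterministic under a seed and traceable at m = 2", {
  dat <- prostagram_fixture()
  a <- mi_estimate(dat, m = 10, seed = 99)
  b <- mi_estimate(dat, m = 10, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # hand trace of two imputations under a fixed seed
  m2 <- mi_estimate(dat, m = 2, penalized = TRUE, seed = 7)
  model <- fit_firth(as.matrix(dat[dat$verified == 1, test_names(dat)]),
                     dat$disease[dat$verified == 1])
  set.seed(7)
  imp1 <- impute_once(dat, model)
  imp2 <- impute_once(dat, model)
  hand <- function(completed) {
    d <- completed$disease
    x <- completed$mri
    sum(x == 1 & d == 1) / sum(d == 1)
  }
  s1 <- hand(imp1); s2 <- hand(imp2)
  expect_equal(point_of(m2, "mri", "sensitivity"), mean(c(s1, s2)))
  expect_equal(get_est(m2, "mri", "sensitivity")$between,
               var(c(s1, s2)))
})

test_that("MI and Begg-Greenes agree on simulated MAR data", {
  s <- simulate_screening(2000, 0.1, sens = c(0.85, 0.6, 0.4),
                          spec = c(0.75, 0.8, 0.9), audit_fraction = 0.1,
                          withdrawal_prob = 0.05, seed = 54)
  bg <- bg_accuracy(allocate_nonverified(build_stratum_table(s$data)))
  mi <- mi_estimate(s$data, m = 100, penalized = TRUE, seed = 55)
  for (tst in test_names(s$data)) {
    for (msr in c("sensitivity", "specificity")) {
      row <- get_est(mi, tst, msr)
      mcse <- sqrt(row$total)
      expect_lt(abs(row$point - point_of(bg, tst, msr)), 2 * mcse)
    }
  }
})

test_that("pooled points recover generating values at scale", {
  s <- simulate_screening(20000, 0.1, sens = c(0.85, 0.6), spec = c(0.8, 0.9),
                          audit_fraction = 0.1, seed = 56)
  mi <- mi_estimate(s$data, m = 20, penalized = FALSE, seed = 57)
  cfg <- s$config
  for (j in 1:2) {
    tst <- cfg$test_names[j]
    row_s <- get_est(mi, tst, "sensitivity")
    expect_lt(abs(row_s$point - cfg$sens[j]), 2 * sqrt(row_s$total) + 0.02)
    row_p <- get_est(mi, tst, "specificity")
    expect_lt(abs(row_p$point - cfg$spec[j]), 2 * sqrt(row_p$total) + 0.02)
  }
})

test_that("more missingness does not shrink between-imputation variance", {
  set.seed(58)
  bvars <- sapply(c(0.6, 0.05), function(audit) {
    mean(replicate(20, {
      s <- simulate_screening(600, 0.15, sens = c(0.8, 0.6),
                              spec = c(0.75, 0.85), audit_fraction = audit)
      mi <- mi_estimate(s$data, m = 10, penalized = TRUE,
                        seed = sample.int(1e6, 1))
      get_est(mi, "test1", "specificity")$between
    }))
  })
  # smaller audit fraction -> more unverified -> at least as much
  # between-imputation variance on average
  expect_gte(bvars[2], bvars[1])
})

test_that("m below 2 and unverifiable inputs are rejected", {
  dat <- prostagram_fixture()
  expect_error(mi_estimate(dat, m = 1, seed = 1), "m must be >= 2")
  allneg <- screening_data(data.frame(t = c(1, 1)), c(1L, 1L), c(1L, 1L))
  expect_error(mi_estimate(allneg, m = 2, penalized = FALSE, seed = 1),
               "penalized")
})
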