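# Heterogeneity, pleiotropy, leave-one-out, funnel and directionality.

test_that("Cochran's Q matches the closed form and its limits", {
  # homogeneous ratios: Q = 0, p = 1
  hc <- harmonized_set(c(0.1, 0.2, 0.4), rep(0.01, 3),
                       c(0.05, 0.10, 0.20), rep(0.01, 3))
  q0 <- cochran_q(hc)
  expect_equal(q0$q_stat, 0, tolerance = 1e-20)
  expect_equal(q0$q_pval, 1)

  # worked 2-variant example: theta = (0.5, 0.4), both w = 100
  h2 <- harmonized_set(c(0.1, 0.1), c(0.01, 0.01), c(0.05, 0.04),
                       c(0.01, 0.01))
  q <- cochran_q(h2)
  expect_equal(q$q_stat, 0.5, tolerance = 1e-12)
  expect_equal(q$q_df, 1L)
  expect_equal(q$q_pval, pchisq(0.5, 1, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(cochran_q(harmonized_set(0.1, 0.01, 0.05, 0.01)), "at least 2")
})

test_that("Q is invariant to row order and allele-frame flips", {
  set.seed(9)
  k <- 12
  bx <- rnorm(k, 0.1, 0.03)
  h <- harmonized_set(bx, rep(0.01, k), 0.4 * bx + rnorm(k, 0, 0.005),
                      runif(k, 0.005, 0.02))
  qh <- cochran_q(h)$q_stat
  perm <- sample(k)
  hp <- harmonized_set(h$beta_exposure[perm], h$se_exposure[perm],
                       h$beta_outcome[perm], h$se_outcome[perm])
  expect_equal(cochran_q(hp)$q_stat, qh, tolerance = 1e-12)
  flip <- sample(c(-1, 1), k, replace = TRUE)
  hf <- harmonized_set(h$beta_exposure * flip, h$se_exposure,
                       h$beta_outcome * flip, h$se_outcome)
  expect_equal(cochran_q(hf)$q_stat, qh, tolerance = 1e-12)
})

test_that("Q p-values are uniform under homogeneity", {
  set.seed(31)
  reps <- 1000
  pv <- vapply(seq_len(reps), function(r) {
    h <- simulate_summary_study(n_snps = 20, theta = 0, seed = 31 + r)
    cochran_q(h)$q_pval
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("Egger intercept test behaves on exact, noisy and degenerate data", {
  bx <- c(0.1, 0.2, 0.3)
  degen <- egger_intercept_test(harmonized_set(bx, rep(0.01, 3),
                                               0.01 + 0.5 * bx, rep(0.01, 3)))
  expect_equal(degen$intercept, 0.01, tolerance = 1e-10)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$pval))

  set.seed(17)
  k <- 40
  bx2 <- runif(k, 0.05, 0.3)
  h <- harmonized_set(bx2, rep(0.01, k), 0.5 * bx2 + rnorm(k, 0, 0.01),
                      rep(0.01, k))
  t0 <- egger_intercept_test(h)
  expect_lt(abs(t0$intercept), 3 * t0$se)
  expect_false(t0$degenerate)
})

test_that("Egger intercept type-I error is nominal under balanced pleiotropy", {
  set.seed(23)
  reps <- 1000
  rej <- vapply(seq_len(reps), function(r) {
    h <- simulate_summary_study(n_snps = 30, theta = 0.1,
                                pleiotropy = list(type = "balanced", sd = 0.003),
                                seed = 5000 + r)
    egger_intercept_test(h)$pval < 0.05
  }, logical(1))
  band <- qbinom(c(0.025, 0.975), reps, 0.05)
  expect_gte(sum(rej), band[1])
  expect_lte(sum(rej), band[2])
})

test_that("leave-one-out isolates influential variants", {
  # identical variants: every reduced estimate equals the full one
  hc <- harmonized_set(rep(0.1, 5), rep(0.01, 5), rep(0.05, 5), rep(0.01, 5))
  loo <- leave_one_out(hc)
  expect_equal(nrow(loo), 5L)
  full <- mr_ivw(hc)
  expect_true(all(abs(loo$beta - full$beta) < 1e-6))

  # 10 concordant variants + 1 constructed outlier: exactly one
  # exclusion moves the estimate by more than 2 full-fit SEs
  bx <- rep(0.1, 11)
  by <- c(rep(0.05, 10), 0.2)
  h <- harmonized_set(bx, rep(0.01, 11), by, rep(0.01, 11))
  fullh <- mr_ivw(h, effects_model = "fixed")
  looh <- leave_one_out(h, effects_model = "fixed")
  moved <- abs(looh$beta - fullh$beta) > 2 * fullh$se
  expect_equal(sum(moved), 1L)
  expect_equal(which(moved), 11L)

  expect_error(leave_one_out(harmonized_set(c(0.1, 0.2), c(0.01, 0.01),
                                            c(0.1, 0.2), c(0.01, 0.01))),
               "at least 3")
})

test_that("funnel data pairs ratios with inverse SEs and scales correctly", {
  h1 <- harmonized_set(0.1, 0.02, 0.05, 0.01)
  f1 <- funnel_data(h1)
  expect_equal(nrow(f1), 1L)
  expect_equal(f1$theta, 0.5)
  expect_equal(f1$inv_se, 0.1 / 0.01)

  set.seed(2)
  k <- 10
  h <- harmonized_set(rnorm(k, 0.1, 0.02), rep(0.01, k),
                      rnorm(k, 0.04, 0.01), rep(0.01, k))
  f <- funnel_data(h)
  h_double <- harmonized_set(h$beta_exposure, h$se_exposure,
                             h$beta_outcome, h$se_outcome * 2)
  f2 <- funnel_data(h_double)
  expect_equal(f2$inv_se, f$inv_se / 2)
  expect_equal(f2$theta, f$theta)
})

test_that("funnel ratios are symmetric about the IVW estimate", {
  h <- simulate_summary_study(n_snps = 60, theta = 0.25, seed = 77)
  f <- funnel_data(h)
  theta_ivw <- mr_ivw(h, effects_model = "fixed")$beta
  expect_gt(stats::wilcox.test(f$theta - theta_ivw)$p.value, 0.01)
})

test_that("Steiger directionality compares variance explained", {
  h <- harmonized_set(rep(0.1, 5), rep(0.01, 5), rep(0.01, 5), rep(0.01, 5),
                      n_exposure = 10000, n_outcome = 10000)
  st <- steiger_directionality(h)
  expect_true(st$correct_causal_direction)
  expect_lt(st$steiger_pval, 1e-10)
  expect_true(st$r2_exposure > st$r2_outcome)

  # exact tie: z = 0, p = 1, direction FALSE under strict inequality
  h_tie <- harmonized_set(0.1, 0.01, 0.1, 0.01,
                          n_exposure = 5000, n_outcome = 5000)
  st_tie <- steiger_directionality(h_tie)
  expect_false(st_tie$correct_causal_direction)
  expect_equal(st_tie$steiger_pval, 1)

  # swapping the traits flips the direction
  h_swap <- harmonized_set(h$beta_outcome, h$se_outcome, h$beta_exposure,
                           h$se_exposure, n_exposure = 10000,
                           n_outcome = 10000)
  expect_false(steiger_directionality(h_swap)$correct_causal_direction)

  expect_error(steiger_directionality(harmonized_set(0.1, 0.01, 0.1, 0.01)),
               "sample size")
})

test_that("exposure-causes-outcome studies are called TRUE nearly always", {
  calls <- vapply(1:100, function(r) {
    h <- simulate_summary_study(n_snps = 50, theta = 0.2, seed = 900 + r)
    steiger_directionality(h)$correct_causal_direction
  }, logical(1))
  expect_gte(mean(calls), 0.95)
})

test_that("sensitivity_report bundles all components consistently", {
  st <- small_study()
  inst <- select_instruments(st$exposure, st$ld)
  sub <- summary_stats(as.data.frame(
    st$exposure[st$exposure$snp_id %in% inst$snp_ids, ]),
    trait_id = "sim_exposure")
  h <- harmonise(sub, st$outcome)
  rep_ <- sensitivity_report(h)
  k <- nrow(retained(h))
  expect_equal(rep_$q_df, k - 1L)
  expect_equal(nrow(rep_$loo), k)
  expect_equal(nrow(rep_$funnel), k)
  expect_true(rep_$q_pval >= 0 && rep_$q_pval <= 1)
  expect_false(is.null(rep_$steiger))
})
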