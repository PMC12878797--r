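# The five causal estimators and odds-ratio reporting.

test_that("wald_ratio implements the first-order delta method", {
  e <- wald_ratio(0.1, 0.02, 0.05, 0.01)
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 0.1)
  expect_equal(e$pval, 2 * pnorm(-5))
  expect_equal(e$nsnp, 1L)

  null <- wald_ratio(0.1, 0.02, 0, 0.01)
  expect_equal(null$beta, 0)
  expect_equal(null$or, 1)

  expect_error(wald_ratio(0, 0.02, 0.05, 0.01), "bX = 0")

  # allele-frame invariance
  flipped <- wald_ratio(-0.1, 0.02, -0.05, 0.01)
  expect_equal(flipped$beta, e$beta)
  expect_equal(flipped$se, e$se)

  # second-order option adds the bY^2 seX^2 / bX^4 term
  e2 <- wald_ratio(0.1, 0.02, 0.05, 0.01, second_order = TRUE)
  expect_equal(e2$se, sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.02^2 / 0.1^4))
})

test_that("IVW matches the closed-form weighted-LS oracle", {
  h <- harmonized_set(beta_exposure = c(0.1, 0.2), se_exposure = c(0.01, 0.01),
                      beta_outcome = c(0.05, 0.08), se_outcome = c(0.01, 0.02))
  e <- mr_ivw(h, effects_model = "fixed")
  expect_equal(e$beta, 0.45, tolerance = 1e-12)
  expect_equal(e$se, 1 / sqrt(200), tolerance = 1e-12)

  # k identical variants: consensus equals the common Wald ratio
  hc <- harmonized_set(rep(0.1, 5), rep(0.01, 5), rep(0.05, 5), rep(0.01, 5))
  expect_equal(mr_ivw(hc)$beta, 0.5, tolerance = 1e-12)

  # a single row delegates to the Wald ratio
  h1 <- harmonized_set(0.1, 0.02, 0.05, 0.01)
  e1 <- mr_ivw(h1)
  expect_equal(e1$method, "wald_ratio")
  expect_equal(e1$beta, 0.5)

  hz <- harmonized_set(c(0, 0), c(0.01, 0.01), c(0.01, 0.02), c(0.01, 0.01))
  expect_error(mr_ivw(hz), "degenerate")
})

test_that("fixed-effect IVW SE never exceeds the multiplicative-random SE", {
  set.seed(5)
  for (i in 1:20) {
    k <- sample(4:30, 1)
    h <- harmonized_set(rnorm(k, 0.1, 0.03), rep(0.01, k),
                        rnorm(k, 0.05, 0.02), runif(k, 0.005, 0.02))
    expect_lte(mr_ivw(h, "fixed")$se, mr_ivw(h, "multiplicative_random")$se)
  }
})

test_that("MR-Egger recovers exact linear and affine fits", {
  bx <- c(0.1, 0.2, 0.3)
  h_lin <- harmonized_set(bx, rep(0.01, 3), 0.5 * bx, rep(0.01, 3))
  e <- mr_egger(h_lin)
  expect_equal(e$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$extra$intercept, 0, tolerance = 1e-10)
  expect_true(e$extra$degenerate)  # zero residual: p flagged, not crashed
  expect_true(is.na(e$pval))

  h_aff <- harmonized_set(bx, rep(0.01, 3), 0.01 + 0.5 * bx, rep(0.01, 3))
  e2 <- mr_egger(h_aff)
  expect_equal(e2$beta, 0.5, tolerance = 1e-10)
  expect_equal(e2$extra$intercept, 0.01, tolerance = 1e-10)

  expect_error(mr_egger(harmonized_set(bx[1:2], rep(0.01, 2),
                                       bx[1:2], rep(0.01, 2))),
               "at least 3")
})

test_that("Egger orients rows to non-negative bX before fitting", {
  bx <- c(0.1, 0.2, 0.3, 0.15)
  by <- 0.02 + 0.4 * bx + c(1, -1, 1, -1) * 0.003
  h <- harmonized_set(bx, rep(0.01, 4), by, rep(0.01, 4))
  flip <- c(1, -1, 1, -1)
  h_flip <- harmonized_set(bx * flip, rep(0.01, 4), by * flip, rep(0.01, 4))
  e <- mr_egger(h); ef <- mr_egger(h_flip)
  expect_equal(ef$beta, e$beta)
  expect_equal(ef$extra$intercept, e$extra$intercept)
})

test_that("weighted median interpolates at cumulative weight one half", {
  # consensus
  hc <- harmonized_set(rep(0.1, 4), rep(0.01, 4), rep(0.05, 4), rep(0.01, 4))
  expect_equal(mr_weighted_median(hc, n_boot = 50, seed = 1)$beta, 0.5)

  # equal weights, theta = (0.1, 0.5, 0.9): middle element
  h3 <- harmonized_set(rep(0.1, 3), rep(0.01, 3), c(0.01, 0.05, 0.09),
                       rep(0.01, 3))
  expect_equal(mr_weighted_median(h3, n_boot = 50, seed = 1)$beta, 0.5)

  # one instrument holding > 50% of total weight pins the estimate to
  # its own ratio (up to interpolation across its weight mass)
  hdom <- harmonized_set(c(1, 0.05, 0.05), c(0.001, 0.01, 0.01),
                         c(0.3, 0.01, 0.045), c(0.001, 0.01, 0.01))
  expect_equal(mr_weighted_median(hdom, n_boot = 50, seed = 1)$beta, 0.3,
               tolerance = 1e-3)

  # bootstrap SE is reproducible under a fixed seed
  e1 <- mr_weighted_median(h3, n_boot = 100, seed = 7)
  e2 <- mr_weighted_median(h3, n_boot = 100, seed = 7)
  expect_identical(e1$se, e2$se)
})

test_that("mode estimators find the dominant cluster", {
  h <- harmonized_set(rep(0.1, 4), rep(0.01, 4),
                      c(0.05, 0.05, 0.05, 0.5), rep(0.01, 4))
  m <- mr_mode(h, n_boot = 50, seed = 1)
  expect_equal(m$simple_mode$beta, 0.5, tolerance = 0.05)
  expect_equal(m$weighted_mode$beta, 0.5, tolerance = 0.05)

  hc <- harmonized_set(rep(0.2, 3), rep(0.01, 3), rep(0.08, 3), rep(0.01, 3))
  for (phi in c(0.5, 1, 2)) {
    mc <- mr_mode(hc, phi = phi, n_boot = 20, seed = 1)
    expect_equal(mc$simple_mode$beta, 0.4)
    expect_equal(mc$weighted_mode$beta, 0.4)
  }
})

test_that("run_all_methods applies exactly the methods the data admit", {
  h1 <- harmonized_set(0.1, 0.02, 0.05, 0.01)
  r1 <- run_all_methods(h1)
  expect_named(r1$estimates, "wald_ratio")
  expect_equal(r1$primary, "wald_ratio")

  h2 <- harmonized_set(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.1),
                       c(0.01, 0.01))
  expect_named(run_all_methods(h2)$estimates, "ivw")

  bx <- c(0.1, 0.2, 0.3)
  h3 <- harmonized_set(bx, rep(0.01, 3), 0.5 * bx, rep(0.01, 3))
  r3 <- run_all_methods(h3, seed = 1, n_boot = 50)
  expect_setequal(names(r3$estimates),
                  c("ivw", "egger", "weighted_median", "simple_mode",
                    "weighted_mode"))
  # consensus data: all five estimates coincide
  for (e in r3$estimates) expect_equal(e$beta, 0.5, tolerance = 1e-6)
  expect_equal(r3$primary, "ivw")
})

test_that("every estimator is invariant to the allele frame", {
  set.seed(42)
  for (i in 1:5) {
    k <- 8
    bx <- rnorm(k, 0.1, 0.05); bx[abs(bx) < 0.01] <- 0.05
    h <- harmonized_set(bx, runif(k, 0.005, 0.02),
                        0.3 * bx + rnorm(k, 0, 0.01), runif(k, 0.005, 0.02))
    flip <- sample(c(-1, 1), k, replace = TRUE)
    hf <- harmonized_set(h$beta_exposure * flip, h$se_exposure,
                         h$beta_outcome * flip, h$se_outcome)
    expect_equal(mr_ivw(hf)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
    expect_equal(mr_egger(hf)$beta, mr_egger(h)$beta, tolerance = 1e-12)
    expect_equal(mr_weighted_median(hf, n_boot = 10, seed = 3)$beta,
                 mr_weighted_median(h, n_boot = 10, seed = 3)$beta,
                 tolerance = 1e-12)
    expect_equal(mr_mode(hf, n_boot = 5, seed = 3)$simple_mode$beta,
                 mr_mode(h, n_boot = 5, seed = 3)$simple_mode$beta,
                 tolerance = 1e-12)
  }
})

test_that("to_odds_ratio maps the log scale correctly", {
  null <- to_odds_ratio(0, 0.1)
  expect_equal(unname(null["or"]), 1)
  expect_equal(log(null[["ci_high"]]), -log(null[["ci_low"]]))

  degen <- to_odds_ratio(log(2), 0)
  expect_equal(unname(degen), c(2, 2, 2))
})

test_that("weighted median tolerates 40% invalid instruments where IVW breaks", {
  # summary-level studies: 40% of instruments carry a directional
  # pleiotropic ratio offset of +0.4; truth 0.2
  set.seed(202)
  wm <- ivw <- numeric(30)
  for (r in 1:30) {
    k <- 30
    maf <- runif(k, 0.1, 0.5)
    a <- (0.28 + runif(k, 0, 0.04)) * sample(c(-1, 1), k, TRUE)
    sex <- sey <- sqrt(1 / (100000 * 2 * maf * (1 - maf)))
    alpha <- c(0.4 * a[1:12], rep(0, 18))  # 40% invalid
    bx <- rnorm(k, a, sex)
    by <- rnorm(k, 0.2 * a + alpha, sey)
    h <- harmonized_set(bx, sex, by, sey)
    wm[r] <- mr_weighted_median(h, n_boot = 10, seed = r)$beta
    ivw[r] <- mr_ivw(h)$beta
  }
  # weighted median stays near the truth (residual bias from the finite
  # spread of the valid cluster is bounded), IVW absorbs the full
  # weighted pleiotropy
  expect_lt(abs(median(wm) - 0.2), 0.025)
  expect_gt(abs(mean(ivw) - 0.2), 0.1)
})
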