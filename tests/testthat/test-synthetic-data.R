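# The synthetic-data generator: genotypes, phenotypes, marginal scans
# and end-to-end determinism.

test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(h2_exposure = 1, seed = 1))
  expect_error(sim_config(ld_blocks = data.frame(size = 5, within_r2 = 0.5),
                          n_snps = 10, seed = 1), "sum")
  expect_error(sim_config(ld_blocks = data.frame(size = 10, within_r2 = 1),
                          n_snps = 10, seed = 1), "within_r2")
  expect_error(sim_config(pleiotropy = list(type = "bogus"), seed = 1))
})

test_that("genotypes follow Hardy-Weinberg means and the LD block design", {
  layout_1 <- data.frame(snp_id = "s1", chrom = "1", pos = 1L, block = 1L,
                         maf = 0.5)
  set.seed(1)
  g <- simulate_genotypes(20000, layout_1,
                          data.frame(size = 1L, within_r2 = 0))
  expect_lt(abs(mean(g) - 1), 3 * sqrt(0.5 / 20000))

  # independent variants: off-diagonal realized r2 near zero
  layout_k <- data.frame(snp_id = sprintf("s%d", 1:8), chrom = "1",
                         pos = 1:8, block = 1:8, maf = rep(0.3, 8))
  set.seed(2)
  gk <- simulate_genotypes(5000, layout_k,
                           data.frame(size = rep(1L, 8), within_r2 = 0))
  r2 <- cor(gk)^2; diag(r2) <- 0
  expect_lt(max(r2), 0.01)

  # a (10, 0.8) block at n = 10,000: mean within-block r2 in [0.75, 0.85]
  layout_b <- data.frame(snp_id = sprintf("b%d", 1:10), chrom = "1",
                         pos = 1:10, block = 1L, maf = rep(0.3, 10))
  set.seed(3)
  gb <- simulate_genotypes(10000, layout_b,
                           data.frame(size = 10L, within_r2 = 0.8))
  r2b <- cor(gb)^2
  mean_off <- mean(r2b[upper.tri(r2b)])
  expect_gt(mean_off, 0.75)
  expect_lt(mean_off, 0.85)
})

test_that("phenotypes follow the structural model", {
  cfg <- sim_config(n_snps = 20, n_exposure = 10000, seed = 10,
                    beta1_true = 0.3, confounding_strength = 0)
  set.seed(10)
  layout <- data.frame(snp_id = sprintf("s%d", 1:20), chrom = "1",
                       pos = 1:20, block = 1:20,
                       maf = rep(0.3, 20))
  g <- simulate_genotypes(10000, layout,
                          data.frame(size = rep(1L, 20), within_r2 = 0))
  effects <- list(a = rep(0.05, 20), m = rep(0, 20), alpha = rep(0, 20))
  ph <- simulate_phenotypes(g, effects, cfg)
  # M on X recovers beta1 within 3 SEs
  fit <- summary(lm(ph$m ~ ph$x))
  expect_lt(abs(fit$coefficients["ph$x", "Estimate"] - 0.3),
            3 * fit$coefficients["ph$x", "Std. Error"] + 0.02)
})

test_that("a fully null model yields no exposure-outcome association", {
  cfg0 <- sim_config(n_snps = 10, n_exposure = 10000, seed = 1,
                     theta_direct = 0, beta1_true = 0, beta2_true = 0,
                     confounding_strength = 0)
  layout <- data.frame(snp_id = sprintf("s%d", 1:10), chrom = "1",
                       pos = 1:10, block = 1:10, maf = rep(0.3, 10))
  blocks <- data.frame(size = rep(1L, 10), within_r2 = 0)
  sig <- vapply(1:30, function(r) {
    set.seed(r)
    g <- simulate_genotypes(10000, layout, blocks)
    ph <- simulate_phenotypes(g, list(a = rep(0.05, 10), m = rep(0.05, 10),
                                      alpha = rep(0, 10)), cfg0)
    summary(lm(ph$y ~ ph$x))$coefficients[2, 4] < 0.01
  }, logical(1))
  expect_gte(mean(!sig), 0.9)
})

test_that("marginal_summary_stats is an exact per-variant regression", {
  layout <- data.frame(snp_id = c("s1", "s2"), chrom = "1", pos = c(1L, 2L),
                       block = 1:2, maf = c(0.3, 0.3))
  alleles <- data.frame(effect_allele = c("A", "C"),
                        other_allele = c("G", "T"))
  set.seed(4)
  g <- cbind(rbinom(500, 2, 0.3), rbinom(500, 2, 0.4))
  colnames(g) <- layout$snp_id
  y <- 2 * g[, 1]  # exact, noiseless
  tab <- marginal_summary_stats(g, y, layout, alleles, trait_id = "t")
  expect_equal(tab$beta[1], 2, tolerance = 1e-10)
  expect_lt(tab$se[1], 1e-8)
  expect_equal(tab$eaf, unname(colMeans(g) / 2))
  expect_equal(tab$n, c(500, 500))

  # monomorphic variant flagged, not emitted
  g2 <- g; g2[, 2] <- 1L
  expect_warning(tab2 <- marginal_summary_stats(g2, y, layout, alleles,
                                                trait_id = "t"),
                 "monomorphic")
  expect_equal(attr(tab2, "flagged"), "s2")
  expect_equal(tab2$snp_id, "s1")
})

test_that("null phenotypes give uniform marginal p-values", {
  k <- 800
  layout <- data.frame(snp_id = sprintf("s%03d", 1:k), chrom = "1",
                       pos = seq_len(k), block = seq_len(k),
                       maf = runif(k, 0.1, 0.5))
  alleles <- data.frame(effect_allele = rep("A", k),
                        other_allele = rep("G", k))
  set.seed(6)
  g <- sapply(layout$maf, function(p) rbinom(1500, 2, p))
  colnames(g) <- layout$snp_id
  y <- rnorm(1500)
  tab <- marginal_summary_stats(g, y, layout, alleles, trait_id = "null")
  expect_gt(stats::ks.test(tab$pval, "punif")$p.value, 0.01)
})

test_that("three-node studies are seed-deterministic byte for byte", {
  cfg <- sim_config(n_snps = 30, n_exposure = 2000, n_mediator = 2000,
                    n_outcome = 2000, seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(suppressWarnings(simulate_three_node_study(cfg)), d1)
  write_study(suppressWarnings(simulate_three_node_study(cfg)), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("truth sidecar is internally consistent and LD blocks are realized", {
  cfg <- sim_config(n_snps = 40, n_exposure = 4000, n_mediator = 1000,
                    n_outcome = 1000,
                    ld_blocks = data.frame(size = c(rep(1L, 30), 10L),
                                           within_r2 = c(rep(0, 30), 0.7)),
                    seed = 13)
  st <- suppressWarnings(simulate_three_node_study(cfg))
  expect_equal(st$truth$theta_total,
               st$truth$theta_direct + st$truth$beta1_true * st$truth$beta2_true)
  # realized within-block r2 close to the target
  blk <- st$truth$per_snp$snp_id[st$truth$per_snp$block == 31]
  sub <- st$ld$r2[blk, blk]
  expect_equal(mean(sub[upper.tri(sub)]), 0.7, tolerance = 0.08)
  # disjoint exposure/mediator effect supports
  expect_length(intersect(st$truth$exposure_snps, st$truth$mediator_snps), 0)
})

test_that("binary outcomes reproduce the extreme case-control scale", {
  cfg <- sim_config(n_snps = 20, n_exposure = 2000, n_mediator = 2000,
                    n_outcome = 20000, outcome_type = "binary",
                    case_fraction = 0.001, seed = 5)
  st <- suppressWarnings(simulate_three_node_study(cfg))
  expect_equal(attr(st$outcome, "trait_type"), "binary")
  expect_equal(unique(st$outcome$n), 20000)
  # linear-probability betas at a 0.1% case fraction are tiny, matching
  # near-unity odds ratios when exponentiated
  expect_lt(max(abs(st$outcome$beta)), 0.05)
  expect_true(all(abs(exp(st$outcome$beta) - 1) < 0.05))
})

test_that("the fast summary-level generator recovers its stated effect", {
  est <- vapply(1:50, function(r)
    mr_ivw(simulate_summary_study(n_snps = 50, theta = 0.2, seed = r))$beta,
    numeric(1))
  expect_lt(abs(mean(est) - 0.2), 3 * sd(est) / sqrt(50) + 0.002)
  # directional pleiotropy shifts the Egger intercept by its mean
  # strong instruments (large exposure cohort) so regression dilution of
  # the Egger slope does not leak into the intercept
  ints <- vapply(1:100, function(r) {
    h <- simulate_summary_study(
      n_snps = 50, theta = 0.1, n_exposure = 1000000,
      pleiotropy = list(type = "directional", mean = 0.002, sd = 0.001),
      seed = 300 + r)
    mr_egger(h)$extra$intercept
  }, numeric(1))
  expect_lt(abs(mean(ints) - 0.002), 3 * sd(ints) / sqrt(100))
})
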