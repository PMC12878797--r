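# Synthetic three-node studies: individual-level cohorts under the causal
# diagram exposure -> mediator -> outcome (with a shared confounder and
# optional instrument pleiotropy on the outcome), their marginal GWAS
# summary statistics, and a fast variance-matched summary-level generator
# for large Monte-Carlo designs.

#' Simulation configuration for three-node studies
#'
#' The generative model: a panel of biallelic variants in LD blocks; an
#' exposure X with heritability `h2_exposure` spread in equal per-variant
#' contributions over the polygenic majority of the panel; a mediator
#' `M = beta1_true * X + (own genetic effects on the remaining
#' `mediator_snp_fraction` of the panel, heritability h2_mediator) +
#' confounder + noise`, emulating a protein with a few strong pQTLs
#' downstream of a polygenic metabolite; an outcome
#' liability `Y = theta_direct * X + beta2_true * M + pleiotropy +
#' confounder + noise`, optionally dichotomised at the `case_fraction`
#' quantile. Cohorts for the three traits are non-overlapping (two-sample
#' structure). Defaults emulate a well-powered metabolite/protein GWAS
#' setting: 100 variants, 50,000 individuals per cohort, moderate
#' confounding, no pleiotropy.
#'
#' @param n_snps Panel size (default 100).
#' @param maf_range Minor-allele-frequency range (default `c(0.1, 0.5)`).
#' @param n_exposure,n_mediator,n_outcome Cohort sizes (default 50,000).
#' @param h2_exposure Exposure variance explained by its variants
#'   (default 0.3).
#' @param h2_mediator Mediator variance explained by its own variants
#'   (default 0.5, emulating strong cis-pQTL architecture); the mediator
#'   also inherits genetic signal through `beta1_true * X`.
#' @param mediator_snp_fraction Fraction of the panel carrying direct
#'   mediator effects (default 0.2: few strong pQTL-like loci, the rest
#'   polygenic exposure loci).
#' @param theta_direct True direct exposure -> outcome effect
#'   (default 0.1).
#' @param beta1_true True exposure -> mediator effect (default 0.3).
#' @param beta2_true True mediator -> outcome effect (default 0.2).
#' @param pleiotropy `list(type = "none")`,
#'   `list(type = "balanced", sd = )` or
#'   `list(type = "directional", mean = , sd = )`; per-variant direct
#'   effects on the outcome. Directional offsets are defined on the
#'   exposure-increasing allele orientation (the convention under which
#'   an Egger intercept is interpretable); balanced offsets are
#'   orientation-free.
#' @param confounding_strength Loading of the shared standard-normal
#'   confounder on all three traits (default 0.2).
#' @param outcome_type `"continuous"` (default) or `"binary"`.
#' @param case_fraction Case fraction for binary outcomes (default
#'   `157/172171`, an extremely imbalanced case-control setting).
#' @param ld_blocks Data frame with columns `size` and `within_r2`, or
#'   `NULL` for a fully independent panel.
#' @param seed Integer seed (required).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 100, maf_range = c(0.1, 0.5),
                       n_exposure = 50000, n_mediator = 50000,
                       n_outcome = 50000,
                       h2_exposure = 0.3, h2_mediator = 0.5,
                       mediator_snp_fraction = 0.2,
                       theta_direct = 0.1, beta1_true = 0.3, beta2_true = 0.2,
                       pleiotropy = list(type = "none"),
                       confounding_strength = 0.2,
                       outcome_type = c("continuous", "binary"),
                       case_fraction = 157 / 172171,
                       ld_blocks = NULL, seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(n_snps >= 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            h2_exposure >= 0, h2_exposure < 1,
            h2_mediator >= 0, h2_mediator < 1,
            mediator_snp_fraction > 0, mediator_snp_fraction < 1,
            case_fraction > 0, case_fraction < 1,
            n_exposure > 0, n_mediator > 0, n_outcome > 0,
            pleiotropy$type %in% c("none", "balanced", "directional"))
  if (is.null(ld_blocks))
    ld_blocks <- data.frame(size = rep(1L, n_snps), within_r2 = 0)
  if (sum(ld_blocks$size) != n_snps)
    stop_domain("ld_blocks sizes must sum to n_snps")
  if (any(ld_blocks$within_r2 < 0 | ld_blocks$within_r2 >= 1))
    stop_domain("within_r2 must lie in [0, 1)")
  structure(list(n_snps = n_snps, maf_range = maf_range,
                 n_exposure = n_exposure, n_mediator = n_mediator,
                 n_outcome = n_outcome, h2_exposure = h2_exposure,
                 h2_mediator = h2_mediator,
                 mediator_snp_fraction = mediator_snp_fraction,
                 theta_direct = theta_direct,
                 beta1_true = beta1_true, beta2_true = beta2_true,
                 pleiotropy = pleiotropy,
                 confounding_strength = confounding_strength,
                 outcome_type = outcome_type, case_fraction = case_fraction,
                 ld_blocks = ld_blocks, seed = as.integer(seed)),
            class = "sim_config")
}

# block-structured panel metadata: per-SNP maf, block id, chrom, pos
panel_layout <- function(config) {
  blocks <- config$ld_blocks
  block_id <- rep(seq_len(nrow(blocks)), blocks$size)
  maf_block <- stats::runif(nrow(blocks), config$maf_range[1], config$maf_range[2])
  pos <- integer(config$n_snps)
  p <- 0L
  for (i in seq_len(config$n_snps)) {
    p <- p + if (i > 1L && block_id[i] != block_id[i - 1L]) 1000000L else 1000L
    pos[i] <- p
  }
  data.frame(snp_id = sprintf("rs%06d", seq_len(config$n_snps)),
             chrom = "1", pos = pos, block = block_id,
             maf = maf_block[block_id], stringsAsFactors = FALSE)
}

#' Simulate genotypes for one cohort
#'
#' Allele counts in `{0, 1, 2}`. Variants within an LD block share a
#' block-constant allele frequency and are generated per haplotype by
#' copying a latent anchor allele with probability `within_r2^{1/4}`
#' (giving pairwise allele correlation `within_r2^{1/2}`, hence genotype
#' r-squared approximately `within_r2`); cross-block variants are
#' independent.
#'
#' @param n Number of individuals.
#' @param layout Panel layout from the configuration (internal callers
#'   pass it; see [simulate_three_node_study()]).
#' @param ld_blocks Block definition aligned with `layout$block`.
#' @return Integer matrix `n x n_snps` with `layout$snp_id` as column
#'   names.
#' @export
simulate_genotypes <- function(n, layout, ld_blocks) {
  m <- nrow(layout)
  g <- matrix(0L, n, m, dimnames = list(NULL, layout$snp_id))
  for (b in unique(layout$block)) {
    cols <- which(layout$block == b)
    maf <- layout$maf[cols[1L]]
    r2 <- ld_blocks$within_r2[b]
    if (length(cols) == 1L || r2 <= 0) {
      g[, cols] <- matrix(stats::rbinom(n * length(cols), 2L, maf), n)
      next
    }
    copy_p <- r2^(1 / 4)
    for (hap in 1:2) {
      anchor <- stats::rbinom(n, 1L, maf)
      for (j in cols) {
        take <- stats::runif(n) < copy_p
        allele <- ifelse(take, anchor, stats::rbinom(n, 1L, maf))
        g[, j] <- g[, j] + allele
      }
    }
  }
  g
}

# per-variant pleiotropic outcome effects; directional offsets ride on
# the exposure-increasing allele orientation so a nonzero mean is
# detectable by the Egger intercept rather than cancelling across
# arbitrarily labelled alleles
draw_pleiotropy <- function(pleiotropy, a) {
  k <- length(a)
  switch(pleiotropy$type,
         none = numeric(k),
         balanced = stats::rnorm(k, 0, pleiotropy$sd),
         directional = {
           orient <- ifelse(a == 0, 1, sign(a))
           orient * stats::rnorm(k, pleiotropy$mean, pleiotropy$sd)
         })
}

# equal-per-variant effect sizes delivering a target variance share;
# equal contributions keep every instrument comparably strong, so
# threshold selection induces no appreciable winner's curse
equal_contribution_effects <- function(maf, target_var) {
  per_var <- target_var / length(maf)
  sign <- sample(c(-1, 1), length(maf), replace = TRUE)
  sign * sqrt(per_var / (2 * maf * (1 - maf)))
}

#' Simulate the three phenotypes for one cohort
#'
#' Implements the structural model: `X = a'g + c U + ex`,
#' `M = beta1 X + m'g + c U + em`,
#' `Y = theta_direct X + beta2 M + alpha'g + c U + ey` (liability), with
#' `U, ex, em, ey` standard normal and optional binary thresholding of Y
#' at the case-fraction quantile.
#'
#' @param g Genotype matrix from [simulate_genotypes()].
#' @param effects List with per-variant `a` (exposure), `m` (mediator)
#'   and `alpha` (outcome pleiotropy) effects.
#' @param config A `sim_config`.
#' @return List `x`, `m`, `y` (numeric; `y` is 0/1 for binary outcomes)
#'   and `y_liability`.
#' @export
simulate_phenotypes <- function(g, effects, config) {
  n <- nrow(g)
  cs <- config$confounding_strength
  u <- stats::rnorm(n)
  x <- as.numeric(g %*% effects$a) + cs * u + stats::rnorm(n)
  m <- config$beta1_true * x + as.numeric(g %*% effects$m) + cs * u + stats::rnorm(n)
  y <- config$theta_direct * x + config$beta2_true * m +
    as.numeric(g %*% effects$alpha) + cs * u + stats::rnorm(n)
  liability <- y
  if (config$outcome_type == "binary")
    y <- as.numeric(y >= stats::quantile(y, 1 - config$case_fraction))
  list(x = x, m = m, y = y, y_liability = liability)
}

#' Per-variant marginal association scan
#'
#' Simple per-variant linear regression of the phenotype on allele count
#' (for binary traits: linear-probability regression on case status,
#' matching the observed-scale betas of linear-model case-control GWAS).
#' Monomorphic variants are emitted with missing beta and flagged in the
#' `flagged` attribute.
#'
#' @param g Genotype matrix (columns = variants).
#' @param phenotype Numeric vector (0/1 for binary traits).
#' @param layout Panel layout (snp_id, chrom, pos, maf).
#' @param alleles Data frame with `effect_allele`, `other_allele` per
#'   variant (the emission frame).
#' @param trait_id,trait_type Metadata for the returned table.
#' @return A `summary_stats` table; `eaf` is the realized effect-allele
#'   frequency and `n` the cohort size.
#' @export
marginal_summary_stats <- function(g, phenotype, layout, alleles,
                                   trait_id, trait_type = "continuous") {
  n <- nrow(g)
  gm <- colMeans(g)
  sxx <- colSums(g^2) - n * gm^2
  yc <- phenotype - mean(phenotype)
  sxy <- as.numeric(crossprod(g, yc))
  syy <- sum(yc^2)
  mono <- sxx <= 0
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  sse <- pmax(syy - beta * sxy, 0)
  # floor the SE at the smallest positive double so noiseless phenotypes
  # (se exactly 0) still satisfy the se > 0 table invariant
  se <- ifelse(mono, NA_real_,
               pmax(sqrt(sse / ((n - 2) * sxx)), .Machine$double.xmin))
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pval <- pmax(pval, .Machine$double.xmin)  # keep within (0, 1]
  tab <- data.frame(
    snp_id = layout$snp_id, chrom = layout$chrom, pos = layout$pos,
    effect_allele = alleles$effect_allele, other_allele = alleles$other_allele,
    eaf = gm / 2, beta = beta, se = se, pval = pval, n = n,
    stringsAsFactors = FALSE)
  flagged <- layout$snp_id[mono]
  if (any(mono)) {
    tab <- tab[!mono, , drop = FALSE]
    warning(sprintf("%d monomorphic variant(s) dropped from %s", sum(mono), trait_id),
            call. = FALSE)
  }
  out <- summary_stats(tab, trait_id = trait_id, trait_type = trait_type)
  if (length(flagged)) attr(out, "flagged") <- flagged
  out
}

BASES <- c("A", "C", "G", "T")

# random canonical allele pair per variant; a fraction palindromic
draw_alleles <- function(m, palindromic_fraction = 0.15) {
  pairs <- t(vapply(seq_len(m), function(i) {
    if (stats::runif(1) < palindromic_fraction) {
      if (stats::runif(1) < 0.5) c("A", "T") else c("G", "C")
    } else {
      repeat {
        p <- sample(BASES, 2L)
        if (!identical(unname(COMPLEMENT[p[1L]]), p[2L])) return(p)
      }
      p
    }
  }, character(2)))
  data.frame(effect_allele = pairs[, 1L], other_allele = pairs[, 2L],
             stringsAsFactors = FALSE)
}

# scramble a table's allele representation: swap labels (negating beta,
# reflecting eaf) and/or complement the strand; records the action
scramble_alleles <- function(tab, actions = NULL) {
  m <- nrow(tab)
  if (is.null(actions))
    actions <- sample(c("none", "swap", "complement", "complement_swap"),
                      m, replace = TRUE)
  swap <- actions %in% c("swap", "complement_swap")
  comp <- actions %in% c("complement", "complement_swap")
  ea <- tab$effect_allele; oa <- tab$other_allele
  ea[comp] <- unname(COMPLEMENT[ea[comp]]); oa[comp] <- unname(COMPLEMENT[oa[comp]])
  tmp <- ea[swap]; ea[swap] <- oa[swap]; oa[swap] <- tmp
  tab$effect_allele <- ea; tab$other_allele <- oa
  tab$beta[swap] <- -tab$beta[swap]
  tab$eaf[swap] <- 1 - tab$eaf[swap]
  attr(tab, "scramble_actions") <- actions
  tab
}

#' Simulate a complete three-node two-sample study
#'
#' Draws three non-overlapping cohorts over one SNP panel with shared
#' true effects, computes each trait's marginal summary statistics from
#' its own cohort, scrambles the mediator and outcome tables' allele
#' representation (to exercise harmonization) and returns the tables,
#' the realized LD matrix (from the exposure cohort genotypes) and a
#' ground-truth sidecar. Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List `exposure`, `mediator`, `outcome` (`summary_stats`),
#'   `ld` (`ld_matrix`) and `truth` (per-SNP true effects, the scramble
#'   actions, and the global effects including
#'   `theta_total = theta_direct + beta1_true * beta2_true`).
#' @export
simulate_three_node_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    layout <- panel_layout(config)
    alleles <- draw_alleles(config$n_snps)
    n_med <- max(2L, round(config$n_snps * config$mediator_snp_fraction))
    exp_idx <- seq_len(config$n_snps - n_med)
    med_idx <- setdiff(seq_len(config$n_snps), exp_idx)
    a <- numeric(config$n_snps)
    m_eff <- numeric(config$n_snps)
    a[exp_idx] <- equal_contribution_effects(layout$maf[exp_idx],
                                             target_var_for(config, "exposure"))
    m_eff[med_idx] <- equal_contribution_effects(layout$maf[med_idx],
                                                 target_var_for(config, "mediator"))
    alpha <- draw_pleiotropy(config$pleiotropy, a)
    effects <- list(a = a, m = m_eff, alpha = alpha)

    g_exp <- simulate_genotypes(config$n_exposure, layout, config$ld_blocks)
    g_med <- simulate_genotypes(config$n_mediator, layout, config$ld_blocks)
    g_out <- simulate_genotypes(config$n_outcome, layout, config$ld_blocks)
    ph_exp <- simulate_phenotypes(g_exp, effects, config)
    ph_med <- simulate_phenotypes(g_med, effects, config)
    ph_out <- simulate_phenotypes(g_out, effects, config)

    exposure <- marginal_summary_stats(g_exp, ph_exp$x, layout, alleles,
                                       trait_id = "sim_exposure")
    mediator <- marginal_summary_stats(g_med, ph_med$m, layout, alleles,
                                       trait_id = "sim_mediator")
    outcome <- marginal_summary_stats(g_out, ph_out$y, layout, alleles,
                                      trait_id = "sim_outcome",
                                      trait_type = if (config$outcome_type == "binary")
                                        "binary" else "continuous")

    med_actions <- sample(c("none", "swap", "complement", "complement_swap"),
                          nrow(mediator), replace = TRUE)
    out_actions <- sample(c("none", "swap", "complement", "complement_swap"),
                          nrow(outcome), replace = TRUE)
    truth_beta_outcome <- outcome$beta  # pre-scramble, exposure-allele frame
    truth_beta_mediator <- mediator$beta
    mediator_s <- scramble_alleles(as.data.frame(mediator), med_actions)
    outcome_s <- scramble_alleles(as.data.frame(outcome), out_actions)
    mediator <- summary_stats(mediator_s, trait_id = "sim_mediator")
    outcome <- summary_stats(outcome_s, trait_id = "sim_outcome",
                             trait_type = if (config$outcome_type == "binary")
                               "binary" else "continuous")

    r2 <- stats::cor(g_exp)^2
    ld <- ld_matrix(layout$snp_id, r2, positions = layout$pos,
                    chrom = layout$chrom)

    align <- function(values, ids) values[match(layout$snp_id, ids)]
    truth <- list(
      per_snp = data.frame(layout,
                           a_exposure = a, m_mediator = m_eff,
                           alpha_pleiotropy = alpha,
                           beta_outcome_truth_frame = align(truth_beta_outcome, outcome$snp_id),
                           beta_mediator_truth_frame = align(truth_beta_mediator, mediator$snp_id),
                           scramble_mediator = align(med_actions, mediator$snp_id),
                           scramble_outcome = align(out_actions, outcome$snp_id),
                           stringsAsFactors = FALSE),
      theta_direct = config$theta_direct,
      beta1_true = config$beta1_true, beta2_true = config$beta2_true,
      theta_total = config$theta_direct + config$beta1_true * config$beta2_true,
      exposure_snps = layout$snp_id[exp_idx],
      mediator_snps = layout$snp_id[med_idx])
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         ld = ld, truth = truth, config = config)
  })
}

# genetic-variance targets: h2 is the share of total trait variance, with
# total variance 1 (noise) + confounding^2 + genetic
target_var_for <- function(config, trait) {
  cs2 <- config$confounding_strength^2
  h2 <- if (trait == "exposure") config$h2_exposure else config$h2_mediator
  h2 * (1 + cs2) / (1 - h2)
}

#' Write a simulated study as TSV fixtures
#'
#' Emits `exposure.tsv`, `mediator.tsv`, `outcome.tsv`, `ld.tsv` and
#' `truth.tsv` in `outdir`.
#'
#' @param study Output of [simulate_three_node_study()].
#' @param outdir Output directory (created if missing).
#' @return Vector of written paths, invisibly.
#' @export
write_study <- function(study, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(
    write_summary_stats(study$exposure, file.path(outdir, "exposure.tsv")),
    write_summary_stats(study$mediator, file.path(outdir, "mediator.tsv")),
    write_summary_stats(study$outcome, file.path(outdir, "outcome.tsv")),
    write_ld_matrix(study$ld, file.path(outdir, "ld.tsv")))
  truth_path <- file.path(outdir, "truth.tsv")
  utils::write.table(study$truth$per_snp, truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paths, truth_path))
}

#' Fast summary-level study generator
#'
#' Variance-matched approximation of [simulate_three_node_study()] for
#' large Monte-Carlo designs (e.g. 1000-replicate type-I-error studies):
#' per-variant effects are drawn directly on the summary scale,
#' `bX_j ~ N(a_j, seX_j)` and `bY_j ~ N(theta a_j + alpha_j, seY_j)`,
#' with SEs set to the single-variant regression values implied by the
#' cohort sizes. This skips genotype sampling while preserving the
#' sampling distribution the estimators see under independent variants.
#'
#' @param n_snps Number of instruments (default 100).
#' @param n_exposure,n_outcome Implied cohort sizes (default 50,000).
#' @param theta True causal effect (default 0).
#' @param h2_exposure Exposure variance explained (default 0.25).
#' @param maf_range Allele-frequency range (default `c(0.1, 0.5)`).
#' @param pleiotropy As in [sim_config()].
#' @param seed Integer seed or `NULL`.
#' @return A `harmonized_set` with sample-size attributes.
#' @export
simulate_summary_study <- function(n_snps = 100, n_exposure = 50000,
                                   n_outcome = 50000, theta = 0,
                                   h2_exposure = 0.25,
                                   maf_range = c(0.1, 0.5),
                                   pleiotropy = list(type = "none"),
                                   seed = NULL) {
  with_seed(seed, {
    maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
    a <- equal_contribution_effects(maf, h2_exposure / (1 - h2_exposure))
    v <- 2 * maf * (1 - maf)
    sex <- sqrt(1 / (n_exposure * v))
    sey <- sqrt(1 / (n_outcome * v))
    alpha <- draw_pleiotropy(pleiotropy, a)
    bx <- stats::rnorm(n_snps, a, sex)
    by <- stats::rnorm(n_snps, theta * a + alpha, sey)
    harmonized_set(bx, sex, by, sey,
                   exposure_id = "sim_exposure", outcome_id = "sim_outcome",
                   n_exposure = n_exposure, n_outcome = n_outcome)
  })
}
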