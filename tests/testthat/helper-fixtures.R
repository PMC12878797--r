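# Shared fixture builders: small summary-statistics tables, LD matrices
# and harmonized sets constructed in code.

# quick summary_stats builder with sensible defaults
make_ss <- function(snp_id, beta, se,
                    effect_allele = rep("A", length(snp_id)),
                    other_allele = rep("G", length(snp_id)),
                    eaf = rep(0.3, length(snp_id)),
                    chrom = rep("1", length(snp_id)),
                    pos = seq_along(snp_id) * 1000L,
                    pval = NULL, n = rep(10000, length(snp_id)),
                    trait_id = "trait", trait_type = "continuous") {
  validate <- is.null(pval)  # explicit p-values are test constructions
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  summary_stats(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                           effect_allele = effect_allele,
                           other_allele = other_allele, eaf = eaf,
                           beta = beta, se = se, pval = pval, n = n,
                           stringsAsFactors = FALSE),
                trait_id = trait_id, trait_type = trait_type,
                validate = validate)
}

# identity LD (all variants independent)
identity_ld <- function(snp_ids) ld_matrix(snp_ids, diag(1, length(snp_ids)))

# block-diagonal LD with constant within-block r2
block_ld <- function(snp_ids, block, within_r2) {
  m <- outer(block, block, function(a, b) ifelse(a == b, within_r2, 0))
  diag(m) <- 1
  ld_matrix(snp_ids, m)
}

# small default-config simulated study, cached per session (the default
# cohorts are large; tests that only need structure use this small one)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(simulate_three_node_study(
        sim_config(n_snps = 60, n_exposure = 8000, n_mediator = 8000,
                   n_outcome = 8000, seed = 42)))
    cache
  }
})
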