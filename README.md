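# mrpathway

Two-sample Mendelian randomization (MR) with mediation screening, built
entirely on GWAS summary statistics.

## The problem

Observational associations between circulating biomarkers (metabolites,
inflammatory proteins) and disease are confounded and prone to reverse
causation. MR sidesteps both by using genetic variants — randomly
allocated at meiosis and fixed at conception — as instrumental
variables: a variant that raises a metabolite but can affect disease
only through that metabolite identifies the causal effect of the
metabolite. Extending this to a three-node design
(exposure → mediator → outcome) decomposes a total causal effect into
the part transmitted through an intermediate trait and the residual
direct part, e.g. asking how much of a metabolite's effect on cancer
risk runs through an inflammatory protein.

`mrpathway` implements the full chain for this kind of screen:

* **I/O and harmonization** — canonical TSV summary-statistics tables
  (`snp_id chrom pos effect_allele other_allele eaf beta se pval n`),
  dialect mapping for nonstandard headers, and harmonization of
  exposure/outcome pairs onto a common effect-allele frame, including
  strand complements and the intermediate-frequency palindrome drop.
* **Instrument selection** — association threshold (default
  `p < 5e-6`), greedy LD clumping (`r² ≤ 0.001` within 10,000 kb),
  per-variant F-statistic filter (`F = (β/se)² ≥ 10`), and per-variant
  Steiger filtering (variance explained in exposure must exceed that in
  the outcome).
* **Five estimators** — Wald ratio (single variant), inverse-variance
  weighted (IVW; the primary method), MR-Egger regression, weighted
  median, and simple/weighted kernel-mode estimators; odds-ratio
  reporting `OR = exp(β)` with 95% Wald intervals.
* **Sensitivity suite** — Cochran's Q (`Q = Σ wⱼ(θⱼ − θ_IVW)²`,
  `wⱼ = (bXⱼ/seYⱼ)²`), Egger intercept test (t, k−2 df),
  leave-one-out IVW, funnel-plot tables, and the Steiger directionality
  test with `r²ⱼ = tⱼ²/(tⱼ² + n − 2)`.
* **Mediation** — six directional MR assessments per
  exposure/mediator/outcome triple, then the product-of-coefficients
  decomposition
  `β_mediation = β₁·β₂`, `β_direct = β_all − β_mediation`,
  `β_mediation_ratio = β_mediation / β_all`,
  with sign-concordance screening of pathways.
* **Batch screening** — many exposures against one outcome, with
  Benjamini–Hochberg FDR alongside raw p-values, effect-direction
  classification, and deterministic TSV reports.
* **Synthetic data** — a fully seeded generator producing three
  non-overlapping cohorts over one SNP panel (LD blocks, shared
  confounder, optional pleiotropy, optional extreme case-control
  imbalance) plus marginal summary statistics, allele-label scrambling,
  and a ground-truth sidecar, so the whole pipeline is testable offline.

## Worked example

Simulate a three-node study (true direct effect 0.1, exposure→mediator
0.3, mediator→outcome 0.2, so total = 0.16 and mediated share
0.06/0.16 = 0.375) and run the six-assessment mediation analysis:

```r
library(mrpathway)
study <- simulate_three_node_study(
  sim_config(n_snps = 60, n_exposure = 8000, n_mediator = 8000,
             n_outcome = 8000, seed = 42))
res <- run_mediation(study$exposure, study$mediator, study$outcome,
                     study$ld, seed = 1)
res
#> mediation_result: sim_exposure -> sim_mediator -> sim_outcome
#>   beta_all = 0.133068, beta1 = 0.338147, beta2 = 0.191847
#>   beta_mediation = 0.0648724, beta_direct = 0.0681955, ratio = 0.4875, valid_pathway = TRUE
```

At these small cohort sizes the estimates sit within sampling error of
the truth (0.16, 0.3, 0.2); `valid_pathway = TRUE` records that all
three forward legs were significant and no reverse leg showed evidence
of reverse causation. The total-effect leg with all five estimators and
its sensitivity report:

```r
res$assessments$exposure_outcome$result
#> mr_result_set: sim_exposure -> sim_outcome (primary: ivw, significant)
#> ivw: beta = 0.133068 (se 0.0212), p = 3.47e-10, nsnp = 40, OR = 1.14233 [1.09583, 1.19080]
#> egger: beta = 0.10175 (se 0.124), p = 0.417, nsnp = 40, OR = 1.10711 [0.86845, 1.41135]
#> weighted_median: beta = 0.130444 (se 0.0283), p = 4.03e-06, nsnp = 40, OR = 1.13933 [1.07787, 1.20431]
#> simple_mode: beta = 0.0927156 (se 0.051), p = 0.0691, nsnp = 40, OR = 1.09715 [0.99276, 1.21252]
#> weighted_mode: beta = 0.102684 (se 0.0453), p = 0.0233, nsnp = 40, OR = 1.10814 [1.01408, 1.21093]

sensitivity_report(res$assessments$exposure_outcome$h)
#> Q = 48.24 (df 39, p = 0.147); Egger intercept = 0.0050 (p = 0.799)
#> steiger: r2_exposure = 0.27, r2_outcome = 0.0121, correct_causal_direction = TRUE, p = 1.15e-190
```

The near-unity ORs typical of published linear-model case-control GWAS
(e.g. 0.99898 for a strongly protective metabolite) arise because
linear-probability betas at extreme case-control imbalance are tiny;
`to_odds_ratio()` exponentiates betas exactly as supplied and the
methods vignette discusses the scale caveat.

A command-line front end covering simulate / select-instruments / mr /
sensitivity / mediate lives at `inst/cli/mrpathway.R`:

```sh
Rscript inst/cli/mrpathway.R simulate --n-snps 60 --n-cohort 8000 --seed 42 --out fixtures/
Rscript inst/cli/mrpathway.R mediate --exposure fixtures/exposure.tsv \
  --mediator fixtures/mediator.tsv --outcome fixtures/outcome.tsv \
  --ld fixtures/ld.tsv --seed 17 --out mediation.tsv
```

## Layout

```
R/                  implementation (io/harmonise, instruments, estimators,
                    sensitivity, mediation, screening, synthetic data)
inst/extdata/       bundled reported screen tables (regression fixtures)
inst/cli/           command-line front end
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R
vignettes/          methods vignette (source)
```
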