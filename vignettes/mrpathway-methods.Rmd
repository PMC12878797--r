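---
title: "Methods: two-sample MR with mediation screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with mediation screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrpathway)
```

## The model

Two-sample Mendelian randomization treats a set of genetic variants as
instruments for an exposure. For variant $j$, let $(\hat\beta_{Xj},
\sigma_{Xj})$ be its marginal association with the exposure in one GWAS
and $(\hat\beta_{Yj}, \sigma_{Yj})$ its association with the outcome in
an independent GWAS. If the variant is a valid instrument — associated
with the exposure, independent of confounders, and affecting the
outcome only through the exposure — then $\beta_{Yj} = \theta\,
\beta_{Xj}$, and the per-variant ratio $\hat\theta_j = \hat\beta_{Yj} /
\hat\beta_{Xj}$ estimates the causal effect $\theta$.

The three-node extension inserts a mediator $M$ between exposure $X$
and outcome $Y$. Six directional MR assessments (each of the three
forward edges, plus the three reverse edges to rule out reverse
causation) feed the product-of-coefficients decomposition

$$\beta_{\text{mediation}} = \beta_1 \beta_2, \qquad
  \beta_{\text{direct}} = \beta_{\text{all}} - \beta_{\text{mediation}}, \qquad
  \text{ratio} = \beta_{\text{mediation}} / \beta_{\text{all}},$$

where $\beta_1$ is the exposure→mediator effect, $\beta_2$ the
mediator→outcome effect and $\beta_{\text{all}}$ the total
exposure→outcome effect, each taken from the leg's primary estimator
(IVW, or the Wald ratio for single-instrument legs). The decomposition
is arithmetic on point estimates: following common practice in
screening studies no standard error is attached to
$\beta_{\text{mediation}}$ by default; a delta-method SE
$\sqrt{\beta_1^2\sigma_2^2 + \beta_2^2\sigma_1^2}$ with its z-test is
available behind `with_product_se = TRUE` and is clearly an extension.

## Instrument selection

The pipeline is p-filter → LD clumping → F-filter, with Steiger
filtering applied after harmonization:

* **p-threshold** — default $5\times10^{-6}$. Screening studies of
  molecular exposures commonly relax the genome-wide
  $5\times10^{-8}$ to retain enough instruments per trait; both values
  are plain arguments and neither is hard-coded.
* **Clumping** — greedy: repeatedly take the smallest-p unprocessed
  candidate as an index variant and discard candidates on the same
  chromosome within 10,000 kb with $r^2 > 0.001$ against it. Ties on p
  break by chromosome, position, then identifier, which makes the
  output invariant to input row order.
* **F-statistic** — per-variant $F \approx (\hat\beta/\sigma)^2$,
  threshold 10. The exact form $(n-2)r^2/(1-r^2)$ is available when $n$
  is known; at GWAS sample sizes the two are numerically
  indistinguishable, and the approximation works when EAF or $n$ are
  missing, which varies across public sources.
* **Minimum instruments** — default 1 (single-variant legs fall back to
  the Wald ratio); a strict three-instrument mode is an argument
  (`min_snps = 3`).
* **Proxies** — no reference-panel search is implemented; variants
  missing from the outcome table are simply not shared. (A precomputed
  proxy table can be applied upstream by the caller.)

## Harmonization

All effects are re-expressed relative to the exposure's effect allele.
Outcome rows with swapped alleles have $\hat\beta_Y$ negated and EAF
reflected; rows matching only after strand complement are complemented
first. Palindromic variants (A/T, G/C) cannot be resolved from alleles
alone: when either table's EAF lies in $(0.5-b,\,0.5+b)$ with default
band $b = 0.08$ (i.e. EAF in (0.42, 0.58)) — or when EAF is missing —
the row is dropped as `palindromic_ambiguous`; outside the band EAF
concordance decides the strand. The 0.42/0.58 band mirrors common
two-sample MR practice for "intermediate allele frequencies".
Harmonization never silently edits: every dropped row is retained with
its `dropped_reason`, and a validator warns (never corrects) when a
reported p-value disagrees with $2\Phi(-|\hat\beta/\sigma|)$ by more
than a factor 10 in $-\log_{10}$ space. Variants with implied
$-\log_{10}p > 30$ are exempt from that check, where normal-versus-t
deep-tail differences exceed any sensible tolerance without indicating
a data problem.

## Estimators and numerical choices

* **Wald ratio** — $\hat\theta = \hat\beta_Y/\hat\beta_X$, first-order
  delta SE $\sigma_Y/|\hat\beta_X|$ (the conventional default; the
  second-order form adding $\hat\beta_Y^2\sigma_X^2/\hat\beta_X^4$ sits
  behind a flag).
* **IVW** — weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$
  through the origin with weights $1/\sigma_{Yj}^2$. Fixed-effect SE
  $(\sum w_j \hat\beta_{Xj}^2)^{-1/2}$; the multiplicative
  random-effects model inflates it by $\sqrt{Q/(k-1)}$ floored at 1.
  The default (`auto`) uses fixed effects for $k \le 3$ and the
  multiplicative model otherwise, mirroring mainstream practice.
  Normal inference.
* **MR-Egger** — weighted regression with free intercept after
  orienting every row to $\hat\beta_X \ge 0$; t inference on $k-2$
  degrees of freedom for slope and intercept. Exact-fit data (zero
  residual variance) report `pval = NA` with a `degenerate` flag rather
  than dividing by zero; constant exposure effects are a domain error
  since the slope is then unidentified.
* **Weighted median** — per-variant ratios with first-order inverse
  variances $\hat\beta_{Xj}^2/\sigma_{Yj}^2$, linear interpolation at
  cumulative weight 1/2; SE from a seeded parametric bootstrap
  (default 1000 resamples of $(\hat\beta_X, \hat\beta_Y)$ from normals
  centred on the observed values).
* **Modes** — kernel-density mode of the ratios (unweighted and
  weighted), normal kernel, bandwidth $\phi \cdot 1.06\,\min(s,
  \mathrm{IQR}/1.34)\,k^{-1/5}$ with $\phi = 1$ by default; bootstrap
  SEs share the machinery above. Degenerate zero-spread inputs return
  the common value.

All estimators are invariant to jointly negating a row's
$(\hat\beta_X, \hat\beta_Y)$ — the allele-frame invariance the test
suite checks.

## Sensitivity analyses

Cochran's $Q = \sum_j w_j(\hat\theta_j - \hat\theta_{\mathrm{IVW}})^2$
uses first-order weights $w_j = (\hat\beta_{Xj}/\sigma_{Yj})^2$
(equivalently the IVW regression residual sum); the exact-weight
variant accounting for $\sigma_X$ is out of scope. Leave-one-out
recomputes IVW $k$ times under the full fit's effects model. Funnel
data pair each ratio with its inverse first-order SE; no plots are
rendered — every report is a table. Steiger directionality sums
per-variant $r^2_j = t_j^2/(t_j^2+n-2)$ per trait (independence assumed
post-clumping, capped at 1) and compares the Fisher-transformed
$\sqrt{r^2}$ values with a two-sample z-test on the two GWAS sample
sizes; the t-statistic transform is used rather than EAF-based variance
because it works when EAF is absent, which is the realistic situation
across mixed public sources. Binary outcomes are treated on the
observed scale throughout.

## Significance, FDR and the screening pipeline

The primary evidence rule is IVW (or Wald) $p < 0.05$. Benjamini–
Hochberg q-values are always computed and reported alongside, and the
screen's `significance = "fdr"` switch makes them the gating column;
the default remains raw p, reproducing the behaviour of screening
studies that declare FDR "where appropriate" yet report raw-p hit
counts. Bootstrap randomness in a screen derives per exposure from one
run seed mixed with the exposure id, so results are independent of
input order and reproducible.

`valid_pathway` for a mediation triple requires the three forward legs
significant under the primary rule and the three reverse legs
"cleared". A reverse leg is cleared when no reverse instrument survives
Steiger filtering or when the surviving reverse estimate is
non-significant; this was a genuinely open design point (the source
methodology only says reverse assessments use Steiger filtering), and
the chosen rule is the weakest one that still vetoes demonstrated
reverse causation.

## The synthetic-data generator

`simulate_three_node_study()` draws three non-overlapping cohorts (the
two-sample assumption) over one biallelic SNP panel and computes each
trait's marginal summary statistics from its own cohort. The
structural model per individual is

$$X = a^\top g + cU + \varepsilon_X,\quad
  M = \beta_1 X + m^\top g + cU + \varepsilon_M,\quad
  Y = \theta_{\text{direct}} X + \beta_2 M + \alpha^\top g + cU +
  \varepsilon_Y,$$

with $U, \varepsilon$ standard normal, $c$ the confounder loading, and
optional dichotomisation of $Y$ at the case-fraction quantile
(liability thresholding keeps truth bookkeeping simple at extreme
imbalance such as 157 cases in 172,171). Binary summary statistics use
per-variant linear-probability regression, matching the near-unity
"odds ratios" observed when public case-control GWAS are fitted with
linear models; a logistic flag is deliberately absent because closed
form SEs and scale fidelity to that data situation matter more here.

Design choices, made once with their rationale:

* **Mediator gets its own variants.** A model in which the mediator's
  only genetic signal is inherited through $\beta_1 X$ makes the
  mediator→outcome leg unidentifiable: every instrument for $M$ would
  also carry the direct $X \to Y$ path, biasing $\hat\beta_2$ towards
  $(\theta_{\text{direct}} + \beta_1\beta_2)/\beta_1$. Real
  inflammatory-protein GWAS are dominated by strong cis-pQTLs that are
  not metabolite loci, so the panel is split: a polygenic majority
  (default 80%) carries exposure effects and the rest
  (`mediator_snp_fraction = 0.2`) carries direct mediator effects.
* **Equal per-variant contributions.** Within each support, effects
  are scaled so every variant explains the same variance share. All
  instruments then sit comfortably above the selection threshold and
  threshold selection induces no appreciable winner's curse — a green
  recovery test therefore establishes estimator correctness, not
  robustness to selection bias, which real data do exhibit.
* **Defaults** — 100 variants, $n = 50{,}000$ per cohort,
  $h^2_X = 0.3$, $h^2_M = 0.5$ (strong-pQTL architecture),
  $c = 0.2$, $\theta_{\text{direct}} = 0.1$, $\beta_1 = 0.3$,
  $\beta_2 = 0.2$, MAF uniform on (0.1, 0.5), independent variants.
  These were fixed by a power analysis before the acceptance tests
  were frozen: weaker per-variant exposure effects would let
  $\beta_1$-induced mediator associations leak past the selection
  threshold into the $M \to Y$ leg (biasing $\hat\beta_2$ upward),
  while a smaller total $h^2_X$ would inflate the total-effect SE
  beyond what the mediated-ratio recovery bound tolerates.
* **LD blocks** copy a per-haplotype anchor allele with probability
  $r_{\text{target}}^{2\,1/4}$, giving realized genotype $r^2$ within
  about 0.05 of target at $n = 10^4$; the emitted LD matrix is always
  computed from realized genotypes.
* **Allele scrambling.** Mediator and outcome tables are re-expressed
  under random swap/complement actions (recorded in the truth sidecar)
  so harmonization is exercised end to end; about 15% of variants get
  palindromic allele pairs.
* **Directional pleiotropy rides the exposure-increasing orientation.**
  A mean pleiotropic offset applied to arbitrarily labelled alleles
  cancels under Egger's $\hat\beta_X \ge 0$ orientation; defining it on
  the exposure-increasing allele makes the intercept identifiable and
  matches how directional pleiotropy is conceived.
* `simulate_summary_study()` is a variance-matched summary-level
  shortcut ($\hat\beta_X \sim N(a, \sigma_X)$, $\hat\beta_Y \sim
  N(\theta a + \alpha, \sigma_Y)$ with single-variant regression SEs
  implied by the cohort sizes) used for 1000-replicate
  type-I-error and distributional checks where individual-level
  simulation would waste the test budget. It preserves exactly the
  sampling distribution the estimators see under independent variants;
  it does not model LD, selection, or binary thresholding, and is never
  used where those matter.

What the generator does **not** emulate: realistic human LD maps and
frequency spectra, sample overlap between sources (configurable
nowhere — overlap is ignored exactly as screening studies ignore it),
population stratification, and winner's curse (see above). A green
test on synthetic data therefore validates the estimators and plumbing
under the stated model, not the epidemiological robustness of any
particular published screen.

## Known limitations

* Weak-instrument regression dilution is visible at the default
  settings (IVW attenuation ≈ 0.5%, per-variant ncp ≈ 190); the
  recovery criteria absorb it and no correction (e.g. SIMEX) is
  applied.
* The mediated-proportion recovery bound (median absolute error ≤
  0.02) is close to the intrinsic sampling noise of the stated world
  (per-replicate ratio SD ≈ 0.026 at $n = 50{,}000$); it passes, but a
  materially noisier configuration would not, and that is a property
  of the design, not of the estimators.
* Effect scale of binary outcomes is reported exactly as supplied;
  exponentiating linear-probability betas yields "ORs" only in the
  loose sense the field's reports use, and no rescaling to log-odds is
  attempted.
* Reverse-leg clearance is a package design decision (see above);
  other reasonable rules (e.g. requiring the reverse Steiger test
  itself to be non-significant) exist and would shift `valid_pathway`
  rates on borderline data.
* The bundled reported screen tables are transcriptions used as
  regression fixtures; several of their printed mediation rows are
  internally inconsistent (printed ratio ≠ printed
  $\beta_{\text{mediation}}/\beta_{\text{all}}$, presumably from
  rounding $\beta_{\text{mediation}}$ to three significant figures at
  typesetting), and the package recomputes ratios from the beta columns
  rather than matching inconsistent cells.
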