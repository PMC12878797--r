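# Causal estimators: Wald ratio, IVW, MR-Egger, weighted median, and
# mode-based methods, plus odds-ratio reporting. Every estimator consumes
# the retained rows of a harmonized set (bX, seX, bY, seY on a common
# effect-allele frame) and returns an `mr_estimate`.

MR_Z975 <- stats::qnorm(0.975)

new_mr_estimate <- function(method, beta, se, pval, nsnp, extra = list()) {
  orci <- to_odds_ratio(beta, se)
  structure(list(method = method, beta = beta, se = se, pval = pval,
                 nsnp = nsnp, or = orci[["or"]],
                 ci_low = orci[["ci_low"]], ci_high = orci[["ci_high"]],
                 extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.6g (se %.3g), p = %.3g, nsnp = %d, OR = %.5f [%.5f, %.5f]\n",
              x$method, x$beta, x$se, x$pval, x$nsnp, x$or, x$ci_low, x$ci_high))
  invisible(x)
}

# extract the (bX, seX, bY, seY) matrix of retained rows
hm_rows <- function(h, min_rows, what) {
  d <- if (inherits(h, "harmonized_set")) retained(h) else as.data.frame(h)
  if (nrow(d) < min_rows)
    stop_domain(sprintf("%s requires at least %d retained variant(s), got %d",
                        what, min_rows, nrow(d)))
  d
}

#' Convert a log-scale effect to an odds ratio with 95% CI
#'
#' `OR = exp(beta)` with Wald bounds `exp(beta -/+ 1.959964 se)`.
#' Binary-outcome betas are exponentiated exactly as supplied; no rescaling
#' between linear-probability and log-odds scales is attempted (see the
#' methods vignette for why near-unity ORs arise from linear-model
#' case-control GWAS).
#'
#' @param beta Effect estimate on the (assumed) log scale.
#' @param se Standard error, `>= 0`.
#' @return Named numeric vector `or`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' to_odds_ratio(log(2), 0.1)
to_odds_ratio <- function(beta, se) {
  stopifnot(se >= 0)
  c(or = exp(beta), ci_low = exp(beta - MR_Z975 * se),
    ci_high = exp(beta + MR_Z975 * se))
}

#' Wald-ratio estimate from a single variant
#'
#' `beta = bY / bX` with first-order delta-method standard error
#' `seY / |bX|`; the second-order form adds the `bY^2 seX^2 / bX^4` term.
#'
#' @param bX,seX Variant-exposure effect and SE.
#' @param bY,seY Variant-outcome effect and SE.
#' @param second_order Use the second-order delta SE (default `FALSE`).
#' @return An `mr_estimate` with `method = "wald_ratio"`.
#' @export
wald_ratio <- function(bX, seX, bY, seY, second_order = FALSE) {
  if (bX == 0) stop_domain("Wald ratio undefined for bX = 0")
  beta <- bY / bX
  se <- if (second_order) sqrt(seY^2 / bX^2 + bY^2 * seX^2 / bX^4)
        else seY / abs(bX)
  new_mr_estimate("wald_ratio", beta, se, pval_norm(beta, se), 1L)
}

#' Inverse-variance weighted estimate
#'
#' Weighted least squares of bY on bX through the origin with weights
#' `1/seY^2`: `beta = sum(w bX bY) / sum(w bX^2)`. The fixed-effect SE is
#' `(sum(w bX^2))^{-1/2}`; under the multiplicative random-effects model
#' it is inflated by `sqrt(Q/(k-1))` floored at 1. `effects_model =
#' "auto"` (the default) uses fixed effects for k <= 3 and the
#' multiplicative random-effects model otherwise. A single retained
#' variant delegates to [wald_ratio()].
#'
#' @param h A `harmonized_set` (retained rows are used).
#' @param effects_model `"auto"`, `"fixed"` or `"multiplicative_random"`.
#' @return An `mr_estimate` with `method = "ivw"` (Q statistics in
#'   `extra`).
#' @export
mr_ivw <- function(h, effects_model = c("auto", "fixed", "multiplicative_random")) {
  effects_model <- match.arg(effects_model)
  d <- hm_rows(h, 1L, "IVW")
  k <- nrow(d)
  if (k == 1L)
    return(wald_ratio(d$beta_exposure, d$se_exposure, d$beta_outcome, d$se_outcome))
  if (all(d$beta_exposure == 0)) stop_domain("degenerate instruments: all bX are zero")
  w <- 1 / d$se_outcome^2
  sxx <- sum(w * d$beta_exposure^2)
  beta <- sum(w * d$beta_exposure * d$beta_outcome) / sxx
  q <- sum(w * (d$beta_outcome - beta * d$beta_exposure)^2)
  se_fixed <- 1 / sqrt(sxx)
  model <- if (effects_model == "auto") {
    if (k <= 3L) "fixed" else "multiplicative_random"
  } else effects_model
  se <- if (model == "fixed") se_fixed
        else se_fixed * max(1, sqrt(q / (k - 1)))
  new_mr_estimate("ivw", beta, se, pval_norm(beta, se), k,
                  extra = list(effects_model = model, q_stat = q, q_df = k - 1L))
}

#' MR-Egger regression
#'
#' Weighted least squares of bY on bX with a free intercept, weights
#' `1/seY^2`, after orienting every row so bX >= 0. The slope is the
#' causal estimate; the intercept, its SE and two-sided p-value
#' (t distribution, k - 2 df) quantify directional pleiotropy and are
#' stored in `extra`. Degenerate zero-residual fits report the p-values as
#' `NA` with `extra$degenerate = TRUE` instead of dividing by zero.
#'
#' @param h A `harmonized_set` with at least 3 retained rows.
#' @return An `mr_estimate` with `method = "egger"`; `extra` holds
#'   `intercept`, `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(h) {
  d <- hm_rows(h, 3L, "MR-Egger")
  k <- nrow(d)
  flip <- sign(d$beta_exposure)
  flip[flip == 0] <- 1
  bx <- d$beta_exposure * flip
  by <- d$beta_outcome * flip
  if (stats::sd(bx) < 1e-12)
    stop_domain("MR-Egger requires variation in the exposure effects")
  w <- 1 / d$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  # exact-fit data trip summary.lm's "essentially perfect fit" warning;
  # that case is handled explicitly through the degenerate flag below
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  slope <- cf["bx", "Estimate"]; slope_se <- cf["bx", "Std. Error"]
  inter <- cf["(Intercept)", "Estimate"]; inter_se <- cf["(Intercept)", "Std. Error"]
  sigma <- sm$sigma
  degenerate <- !is.finite(sigma) || sigma < 1e-10
  tp <- function(est, se) {
    if (degenerate || se <= 0) return(NA_real_)
    2 * stats::pt(-abs(est / se), df = k - 2)
  }
  new_mr_estimate("egger", slope, slope_se, tp(slope, slope_se), k,
                  extra = list(intercept = inter, intercept_se = inter_se,
                               intercept_pval = tp(inter, inter_se),
                               degenerate = degenerate))
}

# per-variant ratio estimates and their first-order inverse variances
ratio_estimates <- function(d) {
  if (any(d$beta_exposure == 0))
    stop_domain("ratio estimate undefined for bX = 0")
  list(theta = d$beta_outcome / d$beta_exposure,
       w = d$beta_exposure^2 / d$se_outcome^2)
}

# weighted median with linear interpolation at cumulative weight 1/2
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1L] >= 0.5) return(theta[1L])
  if (cw[length(cw)] <= 0.5) return(theta[length(theta)])
  below <- max(which(cw < 0.5))
  theta[below] + (theta[below + 1L] - theta[below]) *
    (0.5 - cw[below]) / (cw[below + 1L] - cw[below])
}

# kernel-density mode of ratio estimates; bandwidth per the modified
# Silverman rule with multiplier phi
kde_mode <- function(theta, w, phi) {
  s <- stats::sd(theta)
  iqr <- stats::IQR(theta) / 1.34
  spread <- min(s, iqr)
  if (!is.finite(spread) || spread <= 0) return(stats::median(theta))
  bw <- phi * 1.06 * spread * length(theta)^(-1 / 5)
  den <- stats::density(theta, weights = w / sum(w), bw = bw, n = 1024L)
  den$x[which.max(den$y)]
}

# parametric bootstrap SE for ratio-based point estimators: resample
# (bX, bY) from normals centred on the observed values
boot_se <- function(d, point_fun, n_boot, seed) {
  k <- nrow(d)
  with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, d$beta_exposure, d$se_exposure)
      by <- stats::rnorm(k, d$beta_outcome, d$se_outcome)
      bx[bx == 0] <- .Machine$double.eps
      point_fun(by / bx, bx^2 / d$se_outcome^2)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted-median estimate
#'
#' Weighted median of the per-variant ratio estimates
#' `theta_j = bY_j / bX_j` with first-order inverse-variance weights
#' `bX_j^2 / seY_j^2` (linear interpolation at cumulative weight 1/2).
#' Consistent when variants carrying at least half the weight are valid
#' instruments. The SE comes from a seeded parametric bootstrap.
#'
#' @param h A `harmonized_set` with at least 3 retained rows.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap (default `NULL`: current
#'   RNG stream).
#' @return An `mr_estimate` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  d <- hm_rows(h, 3L, "weighted median")
  r <- ratio_estimates(d)
  beta <- weighted_median_point(r$theta, r$w)
  se <- boot_se(d, function(th, w) weighted_median_point(th, w), n_boot, seed)
  new_mr_estimate("weighted_median", beta, se, pval_norm(beta, se), nrow(d))
}

#' Mode-based estimates
#'
#' Kernel-density mode of the per-variant ratio estimates, unweighted
#' (simple mode) and inverse-variance weighted (weighted mode). The
#' normal-kernel bandwidth is `phi * 1.06 * min(sd, IQR/1.34) * k^(-1/5)`.
#' SEs come from a seeded parametric bootstrap shared between the two
#' modes.
#'
#' @param h A `harmonized_set` with at least 3 retained rows.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed (default `NULL`).
#' @return Named list of two `mr_estimate`s: `simple_mode`,
#'   `weighted_mode`.
#' @export
mr_mode <- function(h, phi = 1, n_boot = 1000, seed = NULL) {
  d <- hm_rows(h, 3L, "mode estimators")
  r <- ratio_estimates(d)
  k <- nrow(d)
  simple <- kde_mode(r$theta, rep(1, k), phi)
  weighted <- kde_mode(r$theta, r$w, phi)
  se_simple <- boot_se(d, function(th, w) kde_mode(th, rep(1, length(th)), phi),
                       n_boot, seed)
  se_weighted <- boot_se(d, function(th, w) kde_mode(th, w, phi),
                         n_boot, if (is.null(seed)) NULL else seed + 1L)
  list(simple_mode = new_mr_estimate("simple_mode", simple, se_simple,
                                     pval_norm(simple, se_simple), k),
       weighted_mode = new_mr_estimate("weighted_mode", weighted, se_weighted,
                                       pval_norm(weighted, se_weighted), k))
}

#' Run every applicable MR method
#'
#' Applies each estimator whose minimum instrument count is met: with one
#' retained variant only the Wald ratio; with two, IVW; with three or
#' more, all five methods. IVW (or the Wald ratio at k = 1) is marked
#' primary, and the `significant` flag follows the primary method at
#' `p < alpha`.
#'
#' @param h A `harmonized_set` with at least one retained row.
#' @param effects_model IVW effects model (see [mr_ivw()]).
#' @param phi,n_boot,seed Passed to the median/mode estimators.
#' @param alpha Significance level for the primary flag (default 0.05).
#' @return An `mr_result_set`: `exposure_id`, `outcome_id`, `estimates`
#'   (named list of `mr_estimate`s), `primary` (name of the primary
#'   method) and `significant`.
#' @export
run_all_methods <- function(h, effects_model = "auto", phi = 1,
                            n_boot = 1000, seed = NULL, alpha = 0.05) {
  d <- hm_rows(h, 1L, "MR analysis")
  k <- nrow(d)
  est <- list()
  if (k == 1L) {
    est$wald_ratio <- wald_ratio(d$beta_exposure, d$se_exposure,
                                 d$beta_outcome, d$se_outcome)
    primary <- "wald_ratio"
  } else {
    est$ivw <- mr_ivw(h, effects_model = effects_model)
    primary <- "ivw"
    if (k >= 3L) {
      est$egger <- mr_egger(h)
      est$weighted_median <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
      modes <- mr_mode(h, phi = phi, n_boot = n_boot,
                       seed = if (is.null(seed)) NULL else seed + 2L)
      est$simple_mode <- modes$simple_mode
      est$weighted_mode <- modes$weighted_mode
    }
  }
  structure(list(exposure_id = attr(h, "exposure_id") %||% "exposure",
                 outcome_id = attr(h, "outcome_id") %||% "outcome",
                 estimates = est, primary = primary,
                 significant = est[[primary]]$pval < alpha),
            class = "mr_result_set")
}

#' @export
print.mr_result_set <- function(x, ...) {
  cat(sprintf("mr_result_set: %s -> %s (primary: %s%s)\n",
              x$exposure_id, x$outcome_id, x$primary,
              if (isTRUE(x$significant)) ", significant" else ""))
  for (e in x$estimates) print(e)
  invisible(x)
}

#' Flatten MR results to the forest-table layout
#'
#' One row per method with the columns used by forest-style reports:
#' exposure, outcome, method, nsnp, beta, se, pval, or, ci_low, ci_high.
#'
#' @param x An `mr_result_set`.
#' @return A data frame.
#' @export
as.data.frame.mr_result_set <- function(x, ...) {
  do.call(rbind, lapply(x$estimates, function(e)
    data.frame(exposure = x$exposure_id, outcome = x$outcome_id,
               method = e$method, nsnp = e$nsnp, beta = e$beta, se = e$se,
               pval = e$pval, or = e$or, ci_low = e$ci_low,
               ci_high = e$ci_high, stringsAsFactors = FALSE)))
}
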