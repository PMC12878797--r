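# Validity suite: Cochran's Q heterogeneity, Egger intercept pleiotropy
# test, leave-one-out, funnel data, and Steiger directionality.

#' Cochran's Q heterogeneity test
#'
#' With per-variant ratios `theta_j = bY_j / bX_j`, first-order weights
#' `w_j = (bX_j / seY_j)^2` and the fixed-effect IVW estimate
#' `theta_ivw`, computes `Q = sum w_j (theta_j - theta_ivw)^2` with a
#' chi-square reference on k - 1 df.
#'
#' @param h A `harmonized_set` with at least 2 retained rows.
#' @return List `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(h) {
  d <- hm_rows(h, 2L, "Cochran's Q")
  r <- ratio_estimates(d)
  theta_ivw <- sum(r$w * r$theta) / sum(r$w)
  q <- sum(r$w * (r$theta - theta_ivw)^2)
  df <- nrow(d) - 1L
  list(q_stat = q, q_df = df, q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Egger intercept test for directional pleiotropy
#'
#' The intercept fields of [mr_egger()]: estimate, SE and two-sided
#' p-value from the t distribution on k - 2 df. Degenerate zero-residual
#' fits report `pval = NA` with `degenerate = TRUE`.
#'
#' @param h A `harmonized_set` with at least 3 retained rows.
#' @return List `intercept`, `se`, `pval`, `degenerate`.
#' @export
egger_intercept_test <- function(h) {
  e <- mr_egger(h)
  list(intercept = e$extra$intercept, se = e$extra$intercept_se,
       pval = e$extra$intercept_pval, degenerate = e$extra$degenerate)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate k times, excluding one retained variant at
#' a time (same effects model as the full fit), to expose estimates
#' driven by a single instrument.
#'
#' @param h A `harmonized_set` with at least 3 retained rows.
#' @param effects_model IVW effects model (see [mr_ivw()]).
#' @return Data frame with one row per excluded variant: `snp_id`,
#'   `beta`, `se`, `pval`.
#' @export
leave_one_out <- function(h, effects_model = "auto") {
  d <- hm_rows(h, 3L, "leave-one-out")
  rows <- lapply(seq_len(nrow(d)), function(j) {
    dj <- d[-j, , drop = FALSE]
    e <- mr_ivw(dj, effects_model = effects_model)
    data.frame(snp_id = d$snp_id[j], beta = e$beta, se = e$se,
               pval = e$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Funnel-plot data
#'
#' Per-variant Wald ratios paired with their inverse first-order SEs
#' (`|bX|/seY`); the table behind a funnel plot, no rendering.
#'
#' @param h A `harmonized_set` with at least 1 retained row.
#' @return Data frame `snp_id`, `theta`, `inv_se`.
#' @export
funnel_data <- function(h) {
  d <- hm_rows(h, 1L, "funnel data")
  r <- ratio_estimates(d)
  data.frame(snp_id = d$snp_id, theta = r$theta, inv_se = sqrt(r$w),
             stringsAsFactors = FALSE)
}

#' Steiger directionality test
#'
#' Sums the per-variant variance explained (`r2_j = t_j^2 / (t_j^2 + n - 2)`,
#' independence assumed post-clumping, capped at 1) over retained
#' instruments for each trait. The causal direction is judged correct when
#' instruments explain strictly more variance in the exposure than the
#' outcome; the p-value compares the Fisher-transformed multiple
#' correlations `sqrt(r2)` with a two-sample z-test using each trait's
#' sample size.
#'
#' @param h A `harmonized_set` with at least 1 retained row.
#' @param n_exposure,n_outcome Sample sizes; default from `h`'s
#'   attributes.
#' @return A `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `correct_causal_direction`, `steiger_pval`.
#' @export
steiger_directionality <- function(h, n_exposure = attr(h, "n_exposure"),
                                   n_outcome = attr(h, "n_outcome")) {
  d <- hm_rows(h, 1L, "Steiger directionality")
  if (is.null(n_exposure) || is.na(n_exposure) || is.null(n_outcome) || is.na(n_outcome))
    stop_domain("Steiger directionality requires sample sizes for both traits")
  r2x <- min(1, sum(snp_r2(d$beta_exposure, d$se_exposure, n_exposure)))
  r2y <- min(1, sum(snp_r2(d$beta_outcome, d$se_outcome, n_outcome)))
  zx <- atanh(min(sqrt(r2x), 1 - 1e-15))
  zy <- atanh(min(sqrt(r2y), 1 - 1e-15))
  z <- (zx - zy) / sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  structure(list(r2_exposure = r2x, r2_outcome = r2y,
                 correct_causal_direction = r2x > r2y,
                 steiger_pval = 2 * stats::pnorm(-abs(z))),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("steiger: r2_exposure = %.3g, r2_outcome = %.3g, correct_causal_direction = %s, p = %.3g\n",
              x$r2_exposure, x$r2_outcome, x$correct_causal_direction, x$steiger_pval))
  invisible(x)
}

#' Full sensitivity report for one harmonized pair
#'
#' Bundles Cochran's Q, the Egger intercept test (k >= 3), leave-one-out
#' (k >= 3), funnel data and Steiger directionality (when sample sizes
#' are available) into one object.
#'
#' @param h A `harmonized_set` with at least 2 retained rows.
#' @param effects_model IVW effects model for leave-one-out.
#' @return A `sensitivity_report` list.
#' @export
sensitivity_report <- function(h, effects_model = "auto") {
  d <- hm_rows(h, 2L, "sensitivity report")
  k <- nrow(d)
  q <- cochran_q(h)
  egger <- if (k >= 3L) egger_intercept_test(h) else NULL
  loo <- if (k >= 3L) leave_one_out(h, effects_model) else NULL
  st <- tryCatch(steiger_directionality(h), error = function(e) NULL)
  structure(list(q_stat = q$q_stat, q_df = q$q_df, q_pval = q$q_pval,
                 egger_intercept = egger$intercept,
                 egger_intercept_se = egger$se,
                 egger_intercept_pval = egger$pval,
                 loo = loo, funnel = funnel_data(h), steiger = st,
                 nsnp = k),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Q = %.2f (df %d, p = %.3f)", x$q_stat, x$q_df, x$q_pval))
  if (!is.null(x$egger_intercept))
    cat(sprintf("; Egger intercept = %.4f (p = %.3f)",
                x$egger_intercept, x$egger_intercept_pval))
  cat("\n")
  if (!is.null(x$steiger)) print(x$steiger)
  invisible(x)
}
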