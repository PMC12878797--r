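# Three-node mediation: six directional MR assessments per
# exposure -> mediator -> outcome triple and the product-of-coefficients
# effect decomposition.

#' Product-of-coefficients mediated effect
#'
#' `beta_mediation = beta1 * beta2`, where beta1 is the exposure ->
#' mediator effect and beta2 the mediator -> outcome effect.
#'
#' @param beta1,beta2 Leg estimates.
#' @return The mediated (indirect) effect.
#' @export
mediation_product <- function(beta1, beta2) beta1 * beta2

#' Decompose a total effect into direct effect and mediated proportion
#'
#' `beta_direct = beta_all - beta_mediation` (exact, by construction) and
#' `beta_mediation_ratio = beta_mediation / beta_all`. A zero total
#' effect leaves the proportion undefined and is rejected.
#'
#' @param beta_all Total exposure -> outcome effect.
#' @param beta_mediation Mediated effect (product of coefficients).
#' @return List `beta_direct`, `beta_mediation_ratio`.
#' @export
#' @examples
#' mediation_decompose(0.000489279, 8.52e-05)
mediation_decompose <- function(beta_all, beta_mediation) {
  if (beta_all == 0) stop_domain("mediated proportion undefined for beta_all = 0")
  list(beta_direct = beta_all - beta_mediation,
       beta_mediation_ratio = beta_mediation / beta_all)
}

# delta-method SE of beta1*beta2 and its z-test: an extension beyond the
# plain decomposition, off by default
mediation_product_se <- function(beta1, se1, beta2, se2) {
  se <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  list(se = se, pval = pval_norm(beta1 * beta2, se))
}

# one directional MR assessment: instrument selection on `exposure`,
# harmonization against `outcome`, Steiger filtering, then estimation
mr_leg <- function(exposure, outcome, ld, p_threshold = 5e-6,
                   r2_threshold = 0.001, window_kb = 10000,
                   f_threshold = 10, min_snps = 1,
                   steiger = TRUE, n_boot = 1000, seed = NULL,
                   palindrome_maf_band = 0.08) {
  inst <- select_instruments(exposure, ld, p_threshold = p_threshold,
                             r2_threshold = r2_threshold, window_kb = window_kb,
                             f_threshold = f_threshold, min_snps = min_snps)
  if (inst$insufficient)
    return(list(instruments = inst, h = NULL, result = NULL,
                insufficient = TRUE, n_retained = 0L))
  sub <- exposure[exposure$snp_id %in% inst$snp_ids, , drop = FALSE]
  attributes(sub)[c("trait_id", "trait_type", "ancestry_label", "class")] <-
    attributes(exposure)[c("trait_id", "trait_type", "ancestry_label", "class")]
  h <- harmonise(sub, outcome, palindrome_maf_band = palindrome_maf_band)
  if (steiger) h <- steiger_filter(h)
  n_ret <- sum(is.na(h$dropped_reason))
  if (n_ret < min_snps)
    return(list(instruments = inst, h = h, result = NULL,
                insufficient = TRUE, n_retained = n_ret))
  res <- run_all_methods(h, n_boot = n_boot, seed = seed)
  list(instruments = inst, h = h, result = res,
       insufficient = FALSE, n_retained = n_ret)
}

#' Run the six-assessment mediation analysis for one triple
#'
#' Performs the six directional MR assessments for an
#' exposure -> mediator -> outcome triple: (1) exposure -> outcome
#' (total effect), (2) outcome -> exposure, (3) mediator -> outcome,
#' (4) outcome -> mediator, (5) exposure -> mediator, (6) mediator ->
#' exposure; Steiger filtering is applied to every leg, and the reverse
#' legs (2), (4), (6) exist purely to rule out reverse causation. The
#' betas entering the decomposition are each forward leg's primary (IVW
#' or Wald-ratio) estimate: `beta_mediation = beta1 * beta2`,
#' `beta_direct = beta_all - beta_mediation`,
#' `beta_mediation_ratio = beta_mediation / beta_all`.
#'
#' `valid_pathway` requires all three forward legs significant at the
#' primary method's `p < 0.05` and all three reverse legs cleared: a
#' reverse leg is cleared when no instrument survives Steiger filtering,
#' or the surviving reverse estimate is non-significant.
#'
#' @param exposure,mediator,outcome `summary_stats` objects.
#' @param ld An `ld_matrix` covering all candidate instruments.
#' @param p_threshold,r2_threshold,window_kb,f_threshold,min_snps
#'   Instrument-selection settings (defaults 5e-6, 0.001, 10000, 10, 1).
#' @param n_boot,seed Bootstrap settings for the median/mode estimators.
#' @param with_product_se Also attach the delta-method SE and z-test of
#'   `beta1 * beta2` (an extension; the plain decomposition reports no
#'   SE). Default `FALSE`.
#' @return A `mediation_result`.
#' @export
run_mediation <- function(exposure, mediator, outcome, ld,
                          p_threshold = 5e-6, r2_threshold = 0.001,
                          window_kb = 10000, f_threshold = 10, min_snps = 1,
                          n_boot = 1000, seed = NULL,
                          with_product_se = FALSE) {
  args <- list(ld = ld, p_threshold = p_threshold, r2_threshold = r2_threshold,
               window_kb = window_kb, f_threshold = f_threshold,
               min_snps = min_snps, n_boot = n_boot)
  leg_seed <- function(k) if (is.null(seed)) NULL else seed + k
  legs <- list(
    exposure_outcome = do.call(mr_leg, c(list(exposure, outcome, seed = leg_seed(1L)), args)),
    outcome_exposure = do.call(mr_leg, c(list(outcome, exposure, seed = leg_seed(2L)), args)),
    mediator_outcome = do.call(mr_leg, c(list(mediator, outcome, seed = leg_seed(3L)), args)),
    outcome_mediator = do.call(mr_leg, c(list(outcome, mediator, seed = leg_seed(4L)), args)),
    exposure_mediator = do.call(mr_leg, c(list(exposure, mediator, seed = leg_seed(5L)), args)),
    mediator_exposure = do.call(mr_leg, c(list(mediator, exposure, seed = leg_seed(6L)), args))
  )
  forward <- c("exposure_outcome", "mediator_outcome", "exposure_mediator")
  failed <- forward[vapply(legs[forward], function(l) l$insufficient, logical(1))]
  ids <- list(exposure_id = attr(exposure, "trait_id"),
              mediator_id = attr(mediator, "trait_id"),
              outcome_id = attr(outcome, "trait_id"))
  if (length(failed))
    return(structure(c(ids, list(evaluable = FALSE, failed_legs = failed,
                                 assessments = legs, valid_pathway = FALSE)),
                     class = "mediation_result"))
  primary_beta <- function(l) l$result$estimates[[l$result$primary]]$beta
  primary_se <- function(l) l$result$estimates[[l$result$primary]]$se
  beta_all <- primary_beta(legs$exposure_outcome)
  beta2 <- primary_beta(legs$mediator_outcome)
  beta1 <- primary_beta(legs$exposure_mediator)
  beta_med <- mediation_product(beta1, beta2)
  dec <- mediation_decompose(beta_all, beta_med)
  reverse_cleared <- vapply(
    legs[c("outcome_exposure", "outcome_mediator", "mediator_exposure")],
    function(l) l$insufficient || !isTRUE(l$result$significant), logical(1))
  forward_significant <- vapply(legs[forward],
                                function(l) isTRUE(l$result$significant), logical(1))
  out <- c(ids, list(
    evaluable = TRUE, failed_legs = character(0),
    beta_all = beta_all, beta1 = beta1, beta2 = beta2,
    beta_mediation = beta_med, beta_direct = dec$beta_direct,
    beta_mediation_ratio = dec$beta_mediation_ratio,
    valid_pathway = all(forward_significant) && all(reverse_cleared),
    assessments = legs))
  if (with_product_se)
    out$product_se <- mediation_product_se(beta1, primary_se(legs$exposure_mediator),
                                           beta2, primary_se(legs$mediator_outcome))
  structure(out, class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation_result: %s -> %s -> %s\n",
              x$exposure_id, x$mediator_id, x$outcome_id))
  if (!x$evaluable) {
    cat("  not evaluable; failing leg(s):", paste(x$failed_legs, collapse = ", "), "\n")
    return(invisible(x))
  }
  cat(sprintf("  beta_all = %.6g, beta1 = %.6g, beta2 = %.6g\n",
              x$beta_all, x$beta1, x$beta2))
  cat(sprintf("  beta_mediation = %.6g, beta_direct = %.6g, ratio = %.4f, valid_pathway = %s\n",
              x$beta_mediation, x$beta_direct, x$beta_mediation_ratio, x$valid_pathway))
  invisible(x)
}

#' Screen mediation pathways by the sign-concordance rule
#'
#' Retains evaluable pathways whose mediated proportion is positive
#' (mediated effect concordant in sign with the total effect) and, when
#' present, whose `valid_pathway` flag is `TRUE`; sorts by descending
#' proportion. Accepts a list of `mediation_result`s or a data frame with
#' `beta_all`, `beta_mediation`, `beta_mediation_ratio` columns (e.g. a
#' published mediation table used as a fixture).
#'
#' @param results List of `mediation_result`s or a data frame.
#' @param require_valid Require `valid_pathway` (default `TRUE`; ignored
#'   for data frames without the column).
#' @return A data frame sorted by descending `beta_mediation_ratio`.
#' @export
screen_mediation_pathways <- function(results, require_valid = TRUE) {
  if (is.data.frame(results)) {
    df <- results
    if (!"beta_mediation_ratio" %in% names(df))
      df$beta_mediation_ratio <- df$beta_mediation / df$beta_all
    keep <- df$beta_mediation_ratio > 0
    if (require_valid && "valid_pathway" %in% names(df))
      keep <- keep & df$valid_pathway
    out <- df[keep, , drop = FALSE]
  } else {
    rows <- lapply(results, function(r) {
      if (!inherits(r, "mediation_result") || !r$evaluable) return(NULL)
      data.frame(exposure_id = r$exposure_id, mediator_id = r$mediator_id,
                 outcome_id = r$outcome_id, beta_all = r$beta_all,
                 beta1 = r$beta1, beta2 = r$beta2,
                 beta_mediation = r$beta_mediation,
                 beta_direct = r$beta_direct,
                 beta_mediation_ratio = r$beta_mediation_ratio,
                 valid_pathway = r$valid_pathway, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) return(data.frame())
    keep <- out$beta_mediation_ratio > 0
    if (require_valid) keep <- keep & out$valid_pathway
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(-out$beta_mediation_ratio), , drop = FALSE]
  rownames(out) <- NULL
  out
}
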