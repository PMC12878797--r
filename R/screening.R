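# Batch screening of many exposures against one outcome: per-exposure
# pipeline, BH-FDR, effect classification, and tabular report files.

#' Benjamini-Hochberg step-up q-values
#'
#' Standard step-up adjustment: sort p ascending, `q_(i) = min_{j >= i}
#' m p_(j) / j` clipped at 1, returned in input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(is.na(pvals) | pvals < 0 | pvals > 1))
    stop_domain("p-values must lie in [0, 1]")
  m <- length(pvals)
  ord <- order(pvals)
  q_sorted <- pmin(1, rev(cummin(rev(m * pvals[ord] / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Screen a list of exposures against one outcome
#'
#' For each exposure: instrument selection, harmonization, Steiger
#' filtering, all applicable MR methods, and the sensitivity suite.
#' Exposures with insufficient instruments are logged in the `skipped`
#' attribute and excluded from the result rows. Bootstrap randomness is
#' derived per exposure from the run seed and the exposure id
#' ([derive_seed()]), so results do not depend on list order.
#'
#' @param exposures List of `summary_stats` objects.
#' @param outcome A `summary_stats` object.
#' @param ld An `ld_matrix`.
#' @param p_threshold,r2_threshold,window_kb,f_threshold,min_snps
#'   Instrument-selection settings (defaults 5e-6, 0.001, 10000, 10, 1).
#' @param steiger Apply the Steiger filter after harmonization
#'   (default `TRUE`).
#' @param n_boot,seed Bootstrap settings.
#' @param alpha Significance level for the primary flag (default 0.05).
#' @param significance `"raw"` (primary p < alpha, the default) or
#'   `"fdr"` (BH q-value < alpha) for the `significant` column; both
#'   columns are always reported.
#' @return A `screen_result` data frame (one row per analysable
#'   exposure) with `details` and `skipped` attributes.
#' @export
run_exposure_screen <- function(exposures, outcome, ld,
                                p_threshold = 5e-6, r2_threshold = 0.001,
                                window_kb = 10000, f_threshold = 10,
                                min_snps = 1, steiger = TRUE,
                                n_boot = 1000, seed = 1L, alpha = 0.05,
                                significance = c("raw", "fdr")) {
  significance <- match.arg(significance)
  stopifnot(is.list(exposures))
  rows <- list(); details <- list(); skipped <- list()
  for (exposure in exposures) {
    id <- attr(exposure, "trait_id")
    leg <- mr_leg(exposure, outcome, ld,
                  p_threshold = p_threshold, r2_threshold = r2_threshold,
                  window_kb = window_kb, f_threshold = f_threshold,
                  min_snps = min_snps, steiger = steiger,
                  n_boot = n_boot, seed = derive_seed(seed, id))
    if (leg$insufficient) {
      skipped[[id]] <- data.frame(
        exposure_id = id,
        reason = if (is.null(leg$h)) "insufficient_instruments"
                 else "insufficient_after_harmonisation",
        stringsAsFactors = FALSE)
      next
    }
    res <- leg$result
    sens <- sensitivity_report(leg$h)
    prim <- res$estimates[[res$primary]]
    rows[[id]] <- data.frame(
      exposure_id = id, outcome_id = attr(outcome, "trait_id"),
      method = prim$method, nsnp = prim$nsnp,
      beta = prim$beta, se = prim$se, pval = prim$pval,
      or = prim$or, ci_low = prim$ci_low, ci_high = prim$ci_high,
      q_pval = sens$q_pval,
      egger_intercept = sens$egger_intercept %||% NA_real_,
      egger_intercept_pval = sens$egger_intercept_pval %||% NA_real_,
      steiger_correct = if (is.null(sens$steiger)) NA
                        else sens$steiger$correct_causal_direction,
      steiger_pval = if (is.null(sens$steiger)) NA_real_
                     else sens$steiger$steiger_pval,
      stringsAsFactors = FALSE)
    details[[id]] <- list(result = res, sensitivity = sens, h = leg$h,
                          instruments = leg$instruments)
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(out))
    out <- data.frame(exposure_id = character(0), outcome_id = character(0),
                      method = character(0), nsnp = integer(0),
                      beta = numeric(0), se = numeric(0), pval = numeric(0),
                      or = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
                      q_pval = numeric(0), egger_intercept = numeric(0),
                      egger_intercept_pval = numeric(0),
                      steiger_correct = logical(0), steiger_pval = numeric(0),
                      stringsAsFactors = FALSE)
  # deterministic row order regardless of input order
  out <- out[order(out$exposure_id), , drop = FALSE]
  rownames(out) <- NULL
  out$qval <- bh_fdr(out$pval)
  out$significant <- if (significance == "raw") out$pval < alpha else out$qval < alpha
  out$direction <- ifelse(out$or < 1, "protective",
                          ifelse(out$or > 1, "risk", "null"))
  skipped_df <- if (length(skipped)) do.call(rbind, unname(skipped))
                else data.frame(exposure_id = character(0), reason = character(0),
                                stringsAsFactors = FALSE)
  rownames(skipped_df) <- NULL
  structure(out,
            details = details[out$exposure_id],
            skipped = skipped_df,
            class = c("screen_result", "data.frame"))
}

#' Classify significant screen hits by effect direction
#'
#' Partitions significant rows into protective (OR < 1) and
#' risk-enhancing (OR > 1); exact OR = 1 rows are counted separately.
#'
#' @param screen A `screen_result`.
#' @return List `n_significant`, `n_protective`, `n_risk`,
#'   `n_unclassified`, `n_total`.
#' @export
classify_effects <- function(screen) {
  sig <- screen[which(screen$significant), , drop = FALSE]
  list(n_significant = nrow(sig),
       n_protective = sum(sig$or < 1),
       n_risk = sum(sig$or > 1),
       n_unclassified = sum(sig$or == 1),
       n_total = nrow(screen))
}

#' Write the tabular screen report
#'
#' Emits the forest/scatter/single-SNP/funnel/leave-one-out tables and
#' the heterogeneity/pleiotropy/Steiger summaries as TSV files in
#' `outdir`, plus `skipped.tsv`. All orderings are deterministic; byte
#' content is reproducible for a fixed seed.
#'
#' @param screen A `screen_result` from [run_exposure_screen()].
#' @param outdir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(screen, outdir) {
  stopifnot(inherits(screen, "screen_result"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  details <- attr(screen, "details")
  wr <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  gather <- function(fun) {
    parts <- lapply(names(details), function(id) {
      df <- fun(details[[id]], id)
      if (is.null(df) || !nrow(df)) return(NULL)
      cbind(data.frame(exposure_id = id, stringsAsFactors = FALSE), df)
    })
    out <- do.call(rbind, parts)
    if (is.null(out)) data.frame(exposure_id = character(0)) else out
  }
  forest <- gather(function(dt, id) as.data.frame(dt$result))
  scatter <- gather(function(dt, id) {
    d <- retained(dt$h)
    data.frame(snp_id = d$snp_id, beta_exposure = d$beta_exposure,
               se_exposure = d$se_exposure, beta_outcome = d$beta_outcome,
               se_outcome = d$se_outcome, stringsAsFactors = FALSE)
  })
  fits <- gather(function(dt, id) {
    do.call(rbind, lapply(dt$result$estimates, function(e)
      data.frame(method = e$method, slope = e$beta,
                 intercept = e$extra$intercept %||% 0, stringsAsFactors = FALSE)))
  })
  single_snp <- gather(function(dt, id) {
    d <- retained(dt$h)
    do.call(rbind, lapply(seq_len(nrow(d)), function(j) {
      wr_j <- wald_ratio(d$beta_exposure[j], d$se_exposure[j],
                         d$beta_outcome[j], d$se_outcome[j])
      data.frame(snp_id = d$snp_id[j], beta = wr_j$beta, se = wr_j$se,
                 pval = wr_j$pval, or = wr_j$or, ci_low = wr_j$ci_low,
                 ci_high = wr_j$ci_high, stringsAsFactors = FALSE)
    }))
  })
  funnel <- gather(function(dt, id) dt$sensitivity$funnel)
  loo <- gather(function(dt, id) dt$sensitivity$loo)
  het <- data.frame(id.exposure = screen$exposure_id,
                    id.outcome = screen$outcome_id,
                    method = "Inverse variance weighted",
                    Q_pval = screen$q_pval, stringsAsFactors = FALSE)
  pleio <- data.frame(id.exposure = screen$exposure_id,
                      id.outcome = screen$outcome_id,
                      egger_intercept = screen$egger_intercept,
                      se = vapply(details[screen$exposure_id], function(dt)
                        dt$sensitivity$egger_intercept_se %||% NA_real_, numeric(1)),
                      pval = screen$egger_intercept_pval,
                      stringsAsFactors = FALSE)
  steiger <- data.frame(id.exposure = screen$exposure_id,
                        id.outcome = screen$outcome_id,
                        correct_causal_direction = screen$steiger_correct,
                        steiger_pval = screen$steiger_pval,
                        stringsAsFactors = FALSE)
  paths <- c(wr(forest, "forest.tsv"), wr(scatter, "scatter.tsv"),
             wr(fits, "fit_lines.tsv"), wr(single_snp, "single_snp.tsv"),
             wr(funnel, "funnel.tsv"), wr(loo, "loo.tsv"),
             wr(het, "heterogeneity.tsv"), wr(pleio, "pleiotropy.tsv"),
             wr(steiger, "steiger.tsv"),
             wr(attr(screen, "skipped"), "skipped.tsv"),
             wr(as.data.frame(screen), "screen.tsv"))
  invisible(paths)
}
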