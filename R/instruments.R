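# Instrument selection: F-statistics, greedy LD clumping, the combined
# p-filter -> clump -> F-filter pipeline, and the per-SNP Steiger filter.

#' Construct an LD matrix object
#'
#' Pairwise squared correlations between variants, with base-pair
#' positions (and optionally chromosomes) aligned to the variant order.
#'
#' @param snp_ids Character vector of variant identifiers.
#' @param r2 Square symmetric matrix of squared correlations in \[0, 1\]
#'   with unit diagonal.
#' @param positions Integer base-pair coordinates aligned to `snp_ids`
#'   (optional; clumping can take positions from the candidate table).
#' @param chrom Chromosome labels aligned to `snp_ids` (optional).
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(snp_ids, r2, positions = NULL, chrom = NULL) {
  r2 <- as.matrix(r2)
  stopifnot(length(snp_ids) == nrow(r2), nrow(r2) == ncol(r2))
  if (max(abs(r2 - t(r2))) > 1e-8) stop_domain("r2 matrix must be symmetric")
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) stop_domain("r2 values must lie in [0, 1]")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop_domain("r2 diagonal must be 1")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2,
                 positions = positions, chrom = chrom),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("ld_matrix: %d variants\n", length(x$snp_ids)))
  invisible(x)
}

#' Read an LD matrix from TSV
#'
#' Accepts either a square matrix layout (first column = snp_id, remaining
#' headers = snp ids) or a 3-column long layout (`snp_a`, `snp_b`, `r2`);
#' unlisted long-format pairs default to r2 = 0.
#'
#' @param path Path to the TSV file.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (identical(sort(names(tab)), sort(c("snp_a", "snp_b", "r2")))) {
    ids <- sort(unique(c(tab$snp_a, tab$snp_b)))
    m <- diag(1, length(ids)); dimnames(m) <- list(ids, ids)
    m[cbind(match(tab$snp_a, ids), match(tab$snp_b, ids))] <- tab$r2
    m[cbind(match(tab$snp_b, ids), match(tab$snp_a, ids))] <- tab$r2
    diag(m) <- 1
    return(ld_matrix(ids, m))
  }
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  stopifnot(identical(colnames(m), ids))
  ld_matrix(ids, m)
}

#' Write an LD matrix as square TSV
#'
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  out <- data.frame(snp_id = ld$snp_ids,
                    formatC(ld$r2, digits = 17, format = "g"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("snp_id", ld$snp_ids)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-variant F-statistic
#'
#' Instrument-strength measure. The default is the summary-data
#' approximation `(beta/se)^2`; with `n` supplied the exact form
#' `F = (n - 2) r2 / (1 - r2)` with `r2 = t^2 / (t^2 + n - 2)` is
#' available (the two coincide up to the `t` vs `F` degrees-of-freedom
#' convention; at GWAS sample sizes they are numerically indistinguishable).
#'
#' @param beta,se Per-variant effect and standard error (vectorized).
#' @param n Sample size, required for `method = "exact"`.
#' @param method `"approx"` (default) or `"exact"`.
#' @return Numeric vector of F-statistics.
#' @export
#' @examples
#' per_variant_f(0.05, 0.01) # 25
per_variant_f <- function(beta, se, n = NULL, method = c("approx", "exact")) {
  method <- match.arg(method)
  if (any(!is.finite(se) | se <= 0)) stop_domain("se must be > 0")
  t2 <- (beta / se)^2
  if (method == "approx") return(t2)
  if (is.null(n) || any(is.na(n)))
    stop_domain("sample size n required for the exact F-statistic")
  r2 <- t2 / (t2 + n - 2)
  (n - 2) * r2 / (1 - r2)
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unprocessed candidate with the smallest p-value as
#' an index variant and discards every other unprocessed candidate on the
#' same chromosome within `window_kb` kilobases whose squared correlation
#' with the index exceeds `r2_threshold`. Ties on p-value are broken by
#' ascending chromosome, position, then snp_id, making the result
#' independent of input row order.
#'
#' @param candidates A `summary_stats` object (or data frame with
#'   `snp_id`, `chrom`, `pos`, `pval`).
#' @param ld An `ld_matrix` covering every candidate.
#' @param r2_threshold Squared-correlation threshold in (0, 1\]
#'   (default 0.001).
#' @param window_kb Distance window in kilobases (default 10000).
#' @return List with `retained` (index snp_ids in selection order) and
#'   `selection_log` (data frame of `snp_id`, `action`, `reason`).
#' @export
ld_clump <- function(candidates, ld, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(ld, "ld_matrix"),
            r2_threshold > 0, r2_threshold <= 1, window_kb > 0)
  df <- as.data.frame(candidates)
  missing_ld <- setdiff(df$snp_id, ld$snp_ids)
  if (length(missing_ld))
    stop_domain("candidate(s) absent from LD matrix: ",
                paste(utils::head(missing_ld, 10L), collapse = ", "))
  # deterministic processing order: p, then chrom, pos, snp_id
  ord <- order(df$pval, df$chrom, df$pos, df$snp_id)
  df <- df[ord, , drop = FALSE]
  active <- rep(TRUE, nrow(df))
  retained <- character(0)
  log_rows <- list()
  for (i in seq_len(nrow(df))) {
    if (!active[i]) next
    idx <- df$snp_id[i]
    retained <- c(retained, idx)
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(snp_id = idx, action = "retain", reason = "index_variant")
    j <- which(active)
    j <- j[j != i]
    if (!length(j)) { active[i] <- FALSE; next }
    same_chr <- df$chrom[j] == df$chrom[i]
    in_window <- abs(df$pos[j] - df$pos[i]) <= window_kb * 1000
    r2 <- ld$r2[idx, df$snp_id[j]]
    clumped <- j[same_chr & in_window & r2 > r2_threshold]
    for (jj in clumped)
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(snp_id = df$snp_id[jj], action = "drop",
                   reason = sprintf("clumped_with_%s", idx))
    active[clumped] <- FALSE
    active[i] <- FALSE
  }
  list(retained = retained, selection_log = bind_log(log_rows))
}

#' Select genetic instruments for an exposure
#'
#' The pipeline: p-value filter, greedy LD clumping, then per-variant
#' F-statistic filter. Defaults follow the screening criteria used
#' throughout the package: `p < 5e-6`, clump at r2 0.001 within 10,000 kb,
#' `F > 10`, at least one variant (Wald-ratio fallback). A stricter
#' genome-wide threshold (5e-8) and a three-instrument minimum are
#' available through the arguments.
#'
#' @param exposure A `summary_stats` object.
#' @param ld An `ld_matrix` covering the p-passing candidates.
#' @param p_threshold Association p-value threshold (default `5e-6`).
#' @param r2_threshold,window_kb Clumping parameters (defaults 0.001 and
#'   10,000 kb).
#' @param f_threshold Minimum per-variant F (default 10; variants with
#'   `F < f_threshold` are excluded).
#' @param min_snps Minimum retained instruments for the set to be usable
#'   (default 1).
#' @return An `instrument_set`: `exposure_id`, `snp_ids`, `per_snp_f`,
#'   `mean_f`, `insufficient` flag and a full `selection_log`.
#' @export
select_instruments <- function(exposure, ld, p_threshold = 5e-6,
                               r2_threshold = 0.001, window_kb = 10000,
                               f_threshold = 10, min_snps = 1) {
  stopifnot(inherits(exposure, "summary_stats"),
            p_threshold > 0, p_threshold <= 1, f_threshold >= 0, min_snps >= 1)
  df <- as.data.frame(exposure)
  log_rows <- list()
  pass_p <- df$pval < p_threshold
  for (id in df$snp_id[!pass_p])
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(snp_id = id, action = "drop", reason = "p_threshold")
  cand <- df[pass_p, , drop = FALSE]
  if (nrow(cand)) {
    cl <- ld_clump(cand, ld, r2_threshold = r2_threshold, window_kb = window_kb)
    log_rows <- c(log_rows, list(cl$selection_log[cl$selection_log$action == "drop", ]))
    cand <- cand[match(cl$retained, cand$snp_id), , drop = FALSE]
  }
  keep_f <- logical(0)
  if (nrow(cand)) {
    f <- per_variant_f(cand$beta, cand$se)
    keep_f <- f >= f_threshold
    for (id in cand$snp_id[!keep_f])
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(snp_id = id, action = "drop", reason = "weak_instrument_f")
    cand <- cand[keep_f, , drop = FALSE]
    f <- f[keep_f]
  } else f <- numeric(0)
  for (id in cand$snp_id)
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(snp_id = id, action = "retain", reason = "instrument")
  sel_log <- bind_log(log_rows)
  structure(list(exposure_id = attr(exposure, "trait_id"),
                 snp_ids = cand$snp_id,
                 per_snp_f = stats::setNames(f, cand$snp_id),
                 mean_f = if (length(f)) mean(f) else NA_real_,
                 insufficient = length(f) < min_snps,
                 selection_log = sel_log),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set: %s, %d instruments (mean F = %.1f)%s\n",
              x$exposure_id, length(x$snp_ids), x$mean_f,
              if (x$insufficient) " [INSUFFICIENT]" else ""))
  invisible(x)
}

#' Steiger filter on a harmonized set
#'
#' Marks rows whose instruments explain more variance in the outcome than
#' in the exposure (`dropped_reason = "steiger_failed"`), using the
#' per-variant t-statistic transform `r2 = t^2 / (t^2 + n - 2)` for each
#' trait. Requires sample sizes for both traits.
#'
#' @param h A `harmonized_set` with `n_exposure`/`n_outcome` attributes
#'   (overridable through the arguments).
#' @param n_exposure,n_outcome Sample sizes; default from `h`.
#' @return The filtered `harmonized_set`.
#' @export
steiger_filter <- function(h, n_exposure = attr(h, "n_exposure"),
                           n_outcome = attr(h, "n_outcome")) {
  stopifnot(inherits(h, "harmonized_set"))
  if (is.null(n_exposure) || is.na(n_exposure) || is.null(n_outcome) || is.na(n_outcome))
    stop_domain("Steiger filtering requires sample sizes for both traits")
  keep <- is.na(h$dropped_reason)
  r2x <- snp_r2(h$beta_exposure, h$se_exposure, n_exposure)
  r2y <- snp_r2(h$beta_outcome, h$se_outcome, n_outcome)
  fail <- keep & r2y > r2x
  h$dropped_reason[fail] <- "steiger_failed"
  h
}

# per-variant variance explained from the t-statistic transform
snp_r2 <- function(beta, se, n) {
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}
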