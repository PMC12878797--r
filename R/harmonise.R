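# Allele harmonization of an exposure/outcome pair of summary-statistics
# tables onto the exposure's effect-allele frame.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic_pair <- function(a1, a2) COMPLEMENT[a1] == a2

new_harmonized_set <- function(rows, exposure_id, outcome_id,
                               n_exposure, n_outcome) {
  rownames(rows) <- NULL
  structure(rows,
            exposure_id = exposure_id, outcome_id = outcome_id,
            n_exposure = n_exposure, n_outcome = n_outcome,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("harmonized_set: %s -> %s; %d shared variants (%d retained, %d dropped)\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"),
              nrow(x), sum(is.na(x$dropped_reason)), sum(!is.na(x$dropped_reason))))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Retained rows of a harmonized set
#'
#' Rows without a `dropped_reason`; the subset every estimator consumes.
#' Dropped rows are kept in the object for audit.
#'
#' @param h A `harmonized_set`.
#' @return A data frame of retained rows.
#' @export
retained <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  as.data.frame(h)[is.na(h$dropped_reason), , drop = FALSE]
}

#' Harmonize exposure and outcome summary statistics
#'
#' Expresses both traits' effects relative to the exposure's effect allele
#' for every variant shared between the two tables. Outcome rows whose
#' alleles are swapped relative to the exposure have their beta negated
#' and EAF reflected (`flipped`); rows matching only after strand
#' complement (A<->T, C<->G) are complemented first. Palindromic variants
#' (A/T or G/C pairs) are resolved by EAF concordance when both
#' frequencies fall outside the ambiguity band, and dropped
#' (`dropped_reason = "palindromic_ambiguous"`) when either EAF lies in
#' `(0.5 - palindrome_maf_band, 0.5 + palindrome_maf_band)` or is missing.
#' Irreconcilable allele pairs get `dropped_reason = "allele_mismatch"`.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param palindrome_maf_band Half-width of the intermediate-frequency
#'   band around 0.5 inside which palindromic variants are considered
#'   strand-ambiguous. Default 0.08, i.e. drop when EAF is in
#'   (0.42, 0.58), mirroring common practice.
#' @return A `harmonized_set`: per-SNP rows
#'   (`snp_id`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_exposure`, `eaf_outcome`, `flipped`,
#'   `palindromic`, `dropped_reason`) with exposure/outcome ids and median
#'   sample sizes as attributes.
#' @export
harmonise <- function(exposure, outcome, palindrome_maf_band = 0.08) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"),
            palindrome_maf_band >= 0, palindrome_maf_band <= 0.5)
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (!length(shared)) stop_domain("no overlapping variants")
  ex <- as.data.frame(exposure)[match(shared, exposure$snp_id), ]
  ou <- as.data.frame(outcome)[match(shared, outcome$snp_id), ]

  k <- length(shared)
  bY <- ou$beta
  eafY <- ou$eaf
  flipped <- logical(k)
  dropped <- rep(NA_character_, k)
  palin <- is_palindromic_pair(ex$effect_allele, ex$other_allele)

  ea <- ou$effect_allele
  oa <- ou$other_allele
  for (i in seq_len(k)) {
    e1 <- ex$effect_allele[i]; e2 <- ex$other_allele[i]
    o1 <- ea[i]; o2 <- oa[i]
    if (palin[i]) {
      # alleles always "match" up to strand for palindromic pairs; the
      # literal orientation is applied first, EAF concordance then decides
      # whether the outcome sits on the opposite strand
      if (o1 == e1 && o2 == e2) {
        # as-is
      } else if (o1 == e2 && o2 == e1) {
        bY[i] <- -bY[i]; eafY[i] <- 1 - eafY[i]; flipped[i] <- TRUE
      } else {
        dropped[i] <- "allele_mismatch"; next
      }
      fx <- ex$eaf[i]; fy <- eafY[i]
      if (is.na(fx) || is.na(fy)) { dropped[i] <- "palindromic_ambiguous"; next }
      ambiguous <- function(f) min(f, 1 - f) > 0.5 - palindrome_maf_band
      if (ambiguous(fx) || ambiguous(fy)) { dropped[i] <- "palindromic_ambiguous"; next }
      if ((fx - 0.5) * (fy - 0.5) < 0) {
        # frequencies discordant: outcome labels are on the other strand
        bY[i] <- -bY[i]; eafY[i] <- 1 - eafY[i]; flipped[i] <- !flipped[i]
      }
    } else {
      if (o1 == e1 && o2 == e2) {
        # as-is
      } else if (o1 == e2 && o2 == e1) {
        bY[i] <- -bY[i]; eafY[i] <- 1 - eafY[i]; flipped[i] <- TRUE
      } else if (identical(unname(COMPLEMENT[o1]), e1) &&
                 identical(unname(COMPLEMENT[o2]), e2)) {
        # strand complement, same orientation
      } else if (identical(unname(COMPLEMENT[o1]), e2) &&
                 identical(unname(COMPLEMENT[o2]), e1)) {
        bY[i] <- -bY[i]; eafY[i] <- 1 - eafY[i]; flipped[i] <- TRUE
      } else {
        dropped[i] <- "allele_mismatch"
      }
    }
  }

  rows <- data.frame(
    snp_id = shared,
    beta_exposure = ex$beta, se_exposure = ex$se,
    beta_outcome = bY, se_outcome = ou$se,
    eaf_exposure = ex$eaf, eaf_outcome = eafY,
    pval_exposure = ex$pval, pval_outcome = ou$pval,
    flipped = flipped, palindromic = unname(palin),
    dropped_reason = dropped,
    stringsAsFactors = FALSE
  )
  new_harmonized_set(rows,
                     exposure_id = attr(exposure, "trait_id"),
                     outcome_id = attr(outcome, "trait_id"),
                     n_exposure = stats::median(ex$n, na.rm = TRUE),
                     n_outcome = stats::median(ou$n, na.rm = TRUE))
}

#' Build a harmonized set directly from effect vectors
#'
#' Convenience constructor for already-aligned effects (simulations,
#' worked examples, tests) that bypasses allele bookkeeping.
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Numeric
#'   vectors of equal length; SEs must be positive.
#' @param snp_id Variant identifiers (default `snp1..snpk`).
#' @param exposure_id,outcome_id Trait labels.
#' @param n_exposure,n_outcome Sample sizes (may be `NA`).
#' @return A `harmonized_set` with all rows retained.
#' @export
harmonized_set <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                           snp_id = paste0("snp", seq_along(beta_exposure)),
                           exposure_id = "exposure", outcome_id = "outcome",
                           n_exposure = NA_real_, n_outcome = NA_real_) {
  k <- length(beta_exposure)
  stopifnot(length(se_exposure) == k, length(beta_outcome) == k,
            length(se_outcome) == k, all(se_exposure > 0), all(se_outcome > 0))
  rows <- data.frame(
    snp_id = snp_id,
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    eaf_exposure = NA_real_, eaf_outcome = NA_real_,
    pval_exposure = pval_norm(beta_exposure, se_exposure),
    pval_outcome = pval_norm(beta_outcome, se_outcome),
    flipped = FALSE, palindromic = FALSE,
    dropped_reason = NA_character_,
    stringsAsFactors = FALSE
  )
  new_harmonized_set(rows, exposure_id, outcome_id, n_exposure, n_outcome)
}
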