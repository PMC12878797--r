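# GWAS summary-statistics container, validation and delimited-text I/O.
#
# The canonical on-disk format is a tab-separated table with header
#   snp_id chrom pos effect_allele other_allele eaf beta se pval n
# A "dialect" (named character vector, semantic name -> file header) maps
# nonstandard headers onto this frame at read time.

SS_COLUMNS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
SS_REQUIRED <- setdiff(SS_COLUMNS, c("eaf", "n"))

#' Construct a summary-statistics table
#'
#' Wraps a per-variant association data frame (one row per SNP) as a
#' `summary_stats` object carrying trait-level metadata. Columns follow the
#' canonical frame: `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`. `eaf` and `n` may be
#' `NA`; operations that need them fail loudly rather than imputing.
#'
#' @param records Data frame with the canonical columns (missing `eaf`/`n`
#'   columns are added as `NA`).
#' @param trait_id Character scalar identifying the trait (e.g. a GWAS
#'   Catalog accession).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param ancestry_label Free-text ancestry label.
#' @param validate Run [validate_summary_stats()] (default `TRUE`).
#' @return A `summary_stats` object (a data frame subclass).
#' @export
summary_stats <- function(records, trait_id, trait_type = c("continuous", "binary"),
                          ancestry_label = "EUR", validate = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is_string(trait_id), is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (opt in c("eaf", "n")) if (!opt %in% names(records)) records[[opt]] <- NA_real_
  missing_cols <- setdiff(SS_REQUIRED, names(records))
  if (length(missing_cols))
    stop_domain("missing required column(s): ", paste(missing_cols, collapse = ", "))
  records <- records[SS_COLUMNS]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (num in c("eaf", "beta", "se", "pval", "n"))
    records[[num]] <- as.numeric(records[[num]])
  rownames(records) <- NULL
  out <- structure(records,
                   trait_id = trait_id, trait_type = trait_type,
                   ancestry_label = ancestry_label,
                   class = c("summary_stats", "data.frame"))
  if (validate) validate_summary_stats(out)
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: %s (%s, %s), %d variants\n",
              attr(x, "trait_id"), attr(x, "trait_type"),
              attr(x, "ancestry_label"), nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Validate a summary-statistics table
#'
#' Enforces the per-variant invariants: single-base distinct alleles,
#' `se > 0`, `pval` in (0, 1], `eaf` in \[0, 1\] when present, unique
#' `snp_id`. Additionally warns (never edits) when a reported p-value
#' disagrees with the two-sided normal p implied by `beta/se` by more than
#' `zp_tol_log10` units in -log10 space.
#'
#' @param x A `summary_stats` object.
#' @param zp_tol_log10 Tolerance of the p-value consistency check, in
#'   -log10 units (default 1, i.e. a factor of 10).
#' @return `x`, invisibly.
#' @export
validate_summary_stats <- function(x, zp_tol_log10 = 1) {
  stopifnot(inherits(x, "summary_stats") || is.data.frame(x))
  dup <- unique(x$snp_id[duplicated(x$snp_id)])
  if (length(dup))
    stop_domain("duplicate snp_id: ", paste(utils::head(dup, 10L), collapse = ", "))
  bad_allele <- !(x$effect_allele %in% c("A", "C", "G", "T")) |
    !(x$other_allele %in% c("A", "C", "G", "T")) |
    x$effect_allele == x$other_allele
  if (any(bad_allele))
    stop_domain("invalid alleles (must be single distinct bases) for: ",
                paste(utils::head(x$snp_id[bad_allele], 10L), collapse = ", "))
  if (any(!is.finite(x$se) | x$se <= 0))
    stop_domain("se must be > 0 for: ",
                paste(utils::head(x$snp_id[!is.finite(x$se) | x$se <= 0], 10L), collapse = ", "))
  if (any(!is.finite(x$pval) | x$pval <= 0 | x$pval > 1))
    stop_domain("pval must lie in (0, 1]")
  eaf_bad <- !is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1)
  if (any(eaf_bad)) stop_domain("eaf outside [0, 1] for: ",
                                paste(utils::head(x$snp_id[eaf_bad], 10L), collapse = ", "))
  # p/z consistency: warn only, the reported p stays authoritative; very
  # significant variants (-log10 p > 30) are exempt, where normal-vs-t
  # tail differences exceed any sensible tolerance without signalling a
  # data problem
  p_implied <- pval_norm(x$beta, x$se)
  ok <- p_implied > 1e-30 & x$pval > 1e-30
  off <- ok & abs(log10(p_implied) - log10(x$pval)) > zp_tol_log10
  if (any(off))
    warning(sprintf("%d variant(s) have pval inconsistent with beta/se by > %g log10 units (e.g. %s)",
                    sum(off), zp_tol_log10, x$snp_id[which(off)[1L]]), call. = FALSE)
  invisible(x)
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- (or otherwise-) delimited table with a header row into a
#' [summary_stats()] object. Nonstandard headers are mapped through
#' `dialect`, a named character vector from canonical names
#' (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `n`) to the file's column names. `eaf` and `n`
#' are optional; all other columns are required.
#'
#' @param path Path to a delimited text file with a header.
#' @param trait_id,trait_type,ancestry_label Trait metadata; see
#'   [summary_stats()].
#' @param dialect Named character vector mapping canonical column names to
#'   file headers, or `NULL` when the file already uses canonical names.
#' @param sep Field separator (default tab).
#' @return A `summary_stats` object.
#' @export
read_summary_stats <- function(path, trait_id = basename(path),
                               trait_type = c("continuous", "binary"),
                               ancestry_label = "EUR", dialect = NULL, sep = "\t") {
  trait_type <- match.arg(trait_type)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!is.null(dialect)) {
    stopifnot(!is.null(names(dialect)))
    missing_src <- setdiff(unname(dialect), names(raw))
    if (length(missing_src))
      stop_domain("dialect maps to absent column(s): ",
                  paste(missing_src, collapse = ", "))
    for (canon in names(dialect)) names(raw)[names(raw) == dialect[[canon]]] <- canon
  }
  missing_cols <- setdiff(SS_REQUIRED, names(raw))
  if (length(missing_cols))
    stop_domain("missing required column(s): ", paste(missing_cols, collapse = ", "))
  # report rows failing numeric coercion with line numbers (header = line 1)
  for (num in intersect(c("pos", "eaf", "beta", "se", "pval", "n"), names(raw))) {
    coerced <- suppressWarnings(as.numeric(raw[[num]]))
    bad <- which(is.na(coerced) & !is.na(raw[[num]]) & raw[[num]] != "NA")
    if (length(bad))
      stop_domain(sprintf("column '%s' fails numeric coercion at file line(s): %s",
                          num, paste(utils::head(bad + 1L, 10L), collapse = ", ")))
    raw[[num]] <- coerced
  }
  summary_stats(raw, trait_id = trait_id, trait_type = trait_type,
                ancestry_label = ancestry_label)
}

#' Write GWAS summary statistics as canonical TSV
#'
#' Writes the canonical ten-column tab-separated layout. Floating-point
#' fields are rendered with 17 significant digits so a write/read
#' round-trip is lossless to representable precision.
#'
#' @param x A `summary_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_stats"))
  out <- as.data.frame(x)[SS_COLUMNS]
  for (num in c("eaf", "beta", "se", "pval", "n"))
    out[[num]] <- ifelse(is.na(out[[num]]), "NA",
                         formatC(out[[num]], digits = 17, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
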