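# Bundled regression fixtures: summary tables transcribed from a
# published metabolite -> inflammatory-factor -> oral-cancer MR screen.
# They serve as desk-check inputs for the mediation arithmetic, the
# pathway screening rule and the sensitivity-report ranges; the package
# does not (and cannot, offline) re-derive them from raw GWAS data.

#' Load the bundled reported screen tables
#'
#' Three small tab-separated tables shipped with the package, transcribed
#' from a published oral-cancer MR screen and used as fixtures:
#' * `"mediation"` - 15 mediation pathways (exposure, mediator, outcome,
#'   `beta_all`, `beta_mediation`, `beta_mediation_ratio`);
#' * `"heterogeneity"` - per-association Cochran's Q p-values;
#' * `"steiger"` - per-association Steiger directionality calls and
#'   p-values.
#'
#' A few printed mediation rows are internally inconsistent (the printed
#' ratio does not equal `beta_mediation / beta_all`, presumably from
#' rounding of `beta_mediation` at the typesetting stage); consumers
#' should recompute ratios from the beta columns where exact arithmetic
#' matters.
#'
#' @param which One of `"mediation"`, `"heterogeneity"`, `"steiger"`.
#' @return A data frame.
#' @export
reported_screen_table <- function(which = c("mediation", "heterogeneity", "steiger")) {
  which <- match.arg(which)
  file <- switch(which,
                 mediation = "reported_mediation_effects.tsv",
                 heterogeneity = "reported_heterogeneity.tsv",
                 steiger = "reported_steiger.tsv")
  path <- system.file("extdata", file, package = "mrpathway", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
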