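# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded bootstrap internals never
#' perturb the caller's random stream. With `seed = NULL` the expression
#' runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-task seed from a top-level seed and a string identifier
#'
#' Deterministic mixing rule used by the screening pipeline so that each
#' exposure's bootstrap stream is reproducible from one run-level seed,
#' independent of the order exposures are processed in.
#'
#' @param seed Integer top-level seed.
#' @param id Character identifier (e.g. an exposure accession).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(17, "GCST90199644")
derive_seed <- function(seed, id) {
  stopifnot(length(id) == 1L, is.character(id))
  h <- 0
  for (k in utf8ToInt(id)) h <- (h * 131 + k) %% 2147483647
  as.integer((h + as.numeric(seed) %% 2147483647) %% 2147483647)
}

# two-sided normal p-value from an estimate and its SE
pval_norm <- function(beta, se) {
  ifelse(se > 0, 2 * stats::pnorm(-abs(beta / se)), ifelse(beta == 0, 1, 0))
}

stop_domain <- function(...) stop(..., call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# rbind a list of selection-log data frames, tolerating the empty case
bind_log <- function(rows) {
  if (!length(rows))
    return(data.frame(snp_id = character(0), action = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
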