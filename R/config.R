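#' Pipeline configuration
#'
#' Collects every tunable threshold of the precursor and target pipelines in
#' one list, with defaults matching the published protocol this package
#' implements. Any subset can be overridden.
#'
#' @param ... Named overrides of the defaults below.
#' @return A named list of class `mircane_config`:
#' \describe{
#'   \item{max_edits}{scan edit tolerance (3)}
#'   \item{seed_len}{nominal scan word size (7)}
#'   \item{flank}{precursor window flank in nt (300)}
#'   \item{min_loop}{minimum hairpin loop (3)}
#'   \item{fold_weights}{pair weights of the built-in folding model,
#'     `c(GC = -3, AU = -2, GU = -1)` kcal/mol}
#'   \item{mfei_min}{MFEI acceptance bound, strict `>` (0.65)}
#'   \item{gc_range}{inclusive G+C bounds in percent (`c(30, 70)`)}
#'   \item{duplex_mismatch_range}{allowed mature/star mismatches,
#'     inclusive (`c(1, 6)`); the lower bound is exposed because perfect
#'     duplexes are biologically plausible even though the published
#'     criteria reject them}
#'   \item{max_consec_mm}{maximum consecutive duplex mismatches (2)}
#'   \item{min_closing_pairs}{base pairs the stem must continue beyond the
#'     mature/star duplex (2); see the methods vignette for why this
#'     reading of criterion 8 was chosen}
#'   \item{min_stemloop}{minimum trimmed stem-loop length in nt (60)}
#'   \item{star_overhang}{extension of the star span in nt; 0 keeps the
#'     star exactly the span of duplex partners, 2 applies the canonical
#'     Dicer 2-nt 3' overhang rule}
#'   \item{precursor_identity}{collapse threshold for precursor loci in
#'     percent, strict `>` (95)}
#'   \item{target_threshold}{maximum target complementarity score (3.5)}
#'   \item{target_identity}{collapse threshold for targets in percent,
#'     non-strict `>=` (95)}
#'   \item{block_caps}{per-block mismatch caps of the target pre-filter
#'     (`c(2, 0, 3)`)}
#'   \item{gu_is_block_match}{whether G:U counts as a match in the block
#'     pre-filter (FALSE; it is only rewarded by the 0.5 score later)}
#'   \item{max_bulges}{maximum bulged nucleotides in a target duplex (2)}
#' }
#' @export
mircane_config <- function(...) {
  cfg <- list(
    max_edits = 3L,
    seed_len = 7L,
    flank = 300L,
    min_loop = 3L,
    fold_weights = c(GC = -3, AU = -2, GU = -1),
    mfei_min = 0.65,
    gc_range = c(30, 70),
    duplex_mismatch_range = c(1L, 6L),
    max_consec_mm = 2L,
    min_closing_pairs = 2L,
    min_stemloop = 60L,
    star_overhang = 0L,
    precursor_identity = 95,
    target_threshold = 3.5,
    target_identity = 95,
    block_caps = c(2L, 0L, 3L),
    gu_is_block_match = FALSE,
    max_bulges = 2L
  )
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0 || is.null(names(over)) || any(names(over) == "")) {
      abort(paste0("unknown config field(s): ",
                   paste(bad, collapse = ", ")))
    }
    cfg[names(over)] <- over
  }
  structure(cfg, class = "mircane_config")
}

#' @export
print.mircane_config <- function(x, ...) {
  cat("<mircane_config>\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", paste(format(x[[nm]]), collapse = " "), "\n",
        sep = "")
  }
  invisible(x)
}

# Short stable digest of the resolved configuration, embedded in reports.
config_hash <- function(config) {
  txt <- paste(names(config),
               vapply(config, function(v) paste(format(v), collapse = ","),
                      character(1)),
               sep = "=", collapse = ";")
  # small FNV-1a style rolling hash; stability matters, not cryptography
  h <- 119406923
  for (ch in utf8ToInt(txt)) {
    h <- bitwXor(h, ch)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}
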