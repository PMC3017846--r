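#' The bundled sugarcane miRNA precursor catalog
#'
#' A small catalog of 19 published sugarcane miRNA precursors (14 families)
#' shipped with the package: for each precursor its family, sequence source
#' and accession, gene name, mature sequence, precursor arm, mismatches to
#' the closest plant homolog (NM), trimmed precursor length (LP, nt) and
#' MFEI under thermodynamic folding. One precursor (`SsMIR319`) was
#' annotated by homology despite failing structural validation, so its LP
#' and MFEI are `NA`. These sequences are the default drivers for the
#' homology scan and the default embeds of the synthetic generator.
#'
#' @return A tibble with columns `family`, `source`, `accession`, `gene`,
#'   `mature_sequence`, `arm`, `nm`, `lp`, `mfei`, `conserved_in_rice`.
#' @export
mircane_catalog <- function() {
  path <- system.file("extdata", "sugarcane_precursors.tsv",
                      package = "mircane")
  tibble::as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                               na.strings = "NA"))
}

#' Path to the bundled mature miRNA FASTA
#'
#' FASTA of the 19 mature sequences of [mircane_catalog()], with `family=`
#' and `arm=` metadata in the headers, ready for [read_mature_fasta()].
#'
#' @return A file path.
#' @export
mircane_mature_path <- function() {
  system.file("extdata", "sugarcane_mature.fasta", package = "mircane")
}

#' Summary statistics of a precursor report table
#'
#' Summarises a catalog or report tibble the way precursor surveys are
#' reported: number of precursors, mean and sample standard deviation of
#' MFEI over entries where it is defined, range of precursor lengths, and
#' the 5' uracil bias of the mature sequences (mature miRNAs predominantly
#' start with U, a hallmark of AGO1 loading).
#'
#' @param x A tibble with columns `mfei` and `mature_sequence` (and
#'   optionally `lp`), e.g. [mircane_catalog()].
#' @return A one-row tibble: `n`, `n_mfei`, `mfei_mean`, `mfei_sd`,
#'   `lp_min`, `lp_max`, `first_u`, `first_u_fraction`.
#' @examples
#' summarize_precursors(mircane_catalog())
#' @export
summarize_precursors <- function(x) {
  stopifnot(is.data.frame(x), "mfei" %in% names(x),
            "mature_sequence" %in% names(x))
  mf <- x$mfei[!is.na(x$mfei)]
  first <- substr(x$mature_sequence, 1, 1)
  lp <- if ("lp" %in% names(x)) x$lp[!is.na(x$lp)] else numeric(0)
  tibble(
    n = nrow(x),
    n_mfei = length(mf),
    mfei_mean = mean(mf),
    mfei_sd = sd(mf),
    lp_min = if (length(lp) > 0) min(lp) else NA_real_,
    lp_max = if (length(lp) > 0) max(lp) else NA_real_,
    first_u = sum(first == "U"),
    first_u_fraction = mean(first == "U")
  )
}
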