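#' Read a FASTA file into a sequence tibble
#'
#' Loads nucleotide sequences and normalises them to the RNA alphabet:
#' residues are upper-cased, `T` becomes `U`, and IUPAC ambiguity codes other
#' than `A`/`C`/`G`/`U` are collapsed to `N` (`N` counts towards length but
#' never matches and never pairs downstream). Whether the record was written
#' as DNA or RNA is kept in `source_alphabet`.
#'
#' @param path Path to a FASTA file. Multi-line sequences and CRLF line
#'   endings are tolerated.
#' @return A tibble with one row per record and columns `id` (first
#'   whitespace-delimited word of the header), `description` (remainder of
#'   the header, `""` if absent), `residues` (RNA string) and
#'   `source_alphabet` (`"DNA"` if the raw record contained `T`, else
#'   `"RNA"`). Record order is preserved.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x some est", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort(paste0("no records in FASTA file: ", path))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) {
    abort("FASTA record with empty id")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  raw <- as.character(set)
  raw <- gsub("[\r ]", "", raw)
  norm <- normalize_rna(raw, ids)
  tibble(
    id = unname(ids),
    description = unname(desc),
    residues = norm$residues,
    source_alphabet = norm$source_alphabet
  )
}

# Upper-case, validate against IUPAC nucleotide codes, T->U, ambiguity->N.
normalize_rna <- function(x, ids = NULL) {
  up <- str_to_upper(x)
  bad <- regexpr("[^ACGTUNRYSWKMBDHV]", up)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(paste0(
      "invalid character '", substr(up[i], bad[i], bad[i]), "' at position ",
      bad[i], " in record ",
      if (is.null(ids)) i else ids[i]
    ))
  }
  if (any(nchar(up) == 0)) {
    i <- which(nchar(up) == 0)[1]
    abort(paste0(
      "empty sequence in record ", if (is.null(ids)) i else ids[i]
    ))
  }
  alpha <- ifelse(str_detect(up, "T"), "DNA", "RNA")
  res <- chartr("T", "U", up)
  res <- gsub("[RYSWKMBDHV]", "N", res)
  list(residues = unname(res), source_alphabet = unname(alpha))
}

#' Write a sequence tibble to FASTA
#'
#' Sequences are wrapped at 60 columns. The header is `id` followed by
#' `description` when non-empty.
#'
#' @param seqs Tibble with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else
    rep("", nrow(seqs))
  headers <- ifelse(is.na(desc) | desc == "", seqs$id,
                    paste(seqs$id, desc))
  set <- Biostrings::BStringSet(setNames(seqs$residues, headers))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' G+C content of sequences
#'
#' `N` counts towards the length but not towards G+C, so ambiguous positions
#' dilute the percentage.
#'
#' @param residues Character vector of RNA strings.
#' @return Numeric vector of percentages in `[0, 100]`, unrounded.
#' @examples
#' gc_percent(c("GCGC", "AUAU", "GCAU"))
#' @export
gc_percent <- function(residues) {
  stopifnot(is.character(residues))
  if (any(nchar(residues) == 0)) {
    abort("gc_percent: empty sequence")
  }
  gc <- str_length(gsub("[^GC]", "", residues))
  100 * gc / str_length(residues)
}

#' Reverse complement of RNA sequences
#'
#' `A`/`U` and `G`/`C` are swapped, `N` maps to `N`, and the sequence is
#' reversed. Applying the function twice returns the input.
#'
#' @param residues Character vector of RNA strings.
#' @return Character vector of reverse-complemented RNA strings.
#' @examples
#' reverse_complement("AUGC")
#' @export
reverse_complement <- function(residues) {
  stopifnot(is.character(residues))
  comp <- chartr("ACGUN", "UGCAN", residues)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Split an RNA string into a character vector of single bases.
seq_chars <- function(residues) {
  strsplit(residues, "", fixed = TRUE)[[1]]
}

# Watson-Crick partner of each base (N -> N).
wc_partner <- function(chars) {
  chartr("ACGUN", "UGCAN", chars)
}
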