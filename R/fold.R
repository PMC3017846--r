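#' Fold an RNA sequence with the built-in base-pair-weighted model
#'
#' Computes the nested secondary structure minimising the model energy
#' `E = sum of pair weights`, with weights (kcal/mol) of -3 for G:C, -2 for
#' A:U and -1 for G:U by default, by dynamic programming over all
#' pseudoknot-free structures whose hairpin loops span at least `min_loop`
#' unpaired bases. This is a pairing-count model, not a nearest-neighbour
#' thermodynamic model: its energies differ from mfold/RNAfold, so MFEI
#' thresholds calibrated on thermodynamic folders are approximate here (see
#' the methods vignette); externally computed structures can be supplied via
#' [parse_vienna()] or [parse_ct()] when fidelity to a thermodynamic model
#' matters. Ties are broken deterministically: at equal energy the leftmost
#' position is paired, with the smallest partner index.
#'
#' @param residues A single RNA string (length >= `min_loop + 2`).
#' @param min_loop Minimum hairpin loop length in nt (default 3, the steric
#'   minimum).
#' @param weights Named numeric vector of pair weights `c(GC=, AU=, GU=)`.
#' @return A `mircane_fold` object: list with `residues`, `pairing` (integer
#'   vector of 1-based partners, 0 = unpaired), `dot_bracket`, `mfe_kcal`
#'   (model energy, <= 0) and `source = "builtin"`.
#' @examples
#' fold_rna("GGGGAAAACCCC")
#' @export
fold_rna <- function(residues, min_loop = 3,
                     weights = c(GC = -3, AU = -2, GU = -1)) {
  stopifnot(is.character(residues), length(residues) == 1)
  n <- nchar(residues)
  if (n < min_loop + 2) {
    abort(paste0("sequence too short to fold (need >= ", min_loop + 2,
                 " nt, got ", n, ")"))
  }
  res <- .fold_kernel(residues, as.integer(min_loop),
                      weights[["GC"]], weights[["AU"]], weights[["GU"]])
  new_fold(residues, res$pairing, res$energy, "builtin")
}

new_fold <- function(residues, pairing, mfe_kcal, source) {
  structure(
    list(
      residues = residues,
      pairing = as.integer(pairing),
      dot_bracket = pairing_to_dotbracket(pairing),
      mfe_kcal = mfe_kcal,
      source = source
    ),
    class = "mircane_fold"
  )
}

#' @export
print.mircane_fold <- function(x, ...) {
  cat("<mircane_fold> ", nchar(x$residues), " nt, ",
      sum(x$pairing > 0) / 2, " pairs, energy ",
      if (is.na(x$mfe_kcal)) "undefined" else
        paste0(format(x$mfe_kcal, nsmall = 1), " kcal/mol"),
      " [", x$source, "]\n", sep = "")
  if (nchar(x$residues) <= 120) {
    cat(x$residues, "\n", x$dot_bracket, "\n", sep = "")
  }
  invisible(x)
}

pairing_to_dotbracket <- function(pairing) {
  db <- rep(".", length(pairing))
  i <- seq_along(pairing)
  db[pairing > i & pairing > 0] <- "("
  db[pairing < i & pairing > 0] <- ")"
  paste(db, collapse = "")
}

dotbracket_to_pairing <- function(db, line = NA) {
  chars <- seq_chars(db)
  if (any(!chars %in% c("(", ")", "."))) {
    bad <- setdiff(unique(chars), c("(", ")", "."))
    abort(paste0("unsupported structure notation '",
                 paste(bad, collapse = ""), "'",
                 if (!is.na(line)) paste0(" at line ", line) else ""))
  }
  pairing <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) {
        abort(paste0("unbalanced brackets",
                     if (!is.na(line)) paste0(" at line ", line) else ""))
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairing[i] <- j
      pairing[j] <- i
    }
  }
  if (length(stack) > 0) {
    abort(paste0("unbalanced brackets",
                 if (!is.na(line)) paste0(" at line ", line) else ""))
  }
  pairing
}

#' Parse a Vienna dot-bracket file
#'
#' Expects records of the form header line (optional, starting with `>`),
#' sequence line, then a dot-bracket line with an optional trailing energy
#' annotation such as `(-12.30)`. Only the first record is returned; when
#' several structures are present the first is kept (and said so), matching
#' the convention of taking the optimal structure from a folding run.
#'
#' @param path Path to a Vienna-format file.
#' @return A `mircane_fold` with `source = "vienna_file"`; `mfe_kcal` is `NA`
#'   (flagged with a message) when the file carries no energy.
#' @export
parse_vienna <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty Vienna file: ", path))
  i <- if (startsWith(lines[1], ">")) 2 else 1
  if (length(lines) < i + 1) {
    abort(paste0("truncated Vienna file: ", path))
  }
  residues <- normalize_rna(trimws(lines[i]))$residues
  struct_line <- trimws(lines[i + 1])
  if (length(lines) > i + 1 + if (startsWith(lines[1], ">")) 0 else 0) {
    n_extra <- length(lines) - (i + 1)
    if (n_extra > 0) {
      inform(paste0("Vienna file has ", n_extra,
                    " extra line(s); keeping the first structure"))
    }
  }
  energy <- NA_real_
  m <- regexpr("\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", struct_line)
  if (m > 0) {
    energy <- as.numeric(gsub("[()\\s]", "",
                              regmatches(struct_line, m)))
    struct_line <- trimws(substr(struct_line, 1, m - 1))
  }
  if (nchar(struct_line) != nchar(residues)) {
    abort(paste0("structure length (", nchar(struct_line),
                 ") does not match sequence length (", nchar(residues),
                 ") at line ", i + 1))
  }
  pairing <- dotbracket_to_pairing(struct_line, line = i + 1)
  if (is.na(energy)) {
    inform("Vienna file carries no energy; mfe_kcal left undefined")
  }
  new_fold(residues, pairing, energy, "vienna_file")
}

#' Write a fold to a Vienna dot-bracket file
#'
#' @param fold A `mircane_fold`.
#' @param path Output path.
#' @param id Header id (default `"structure"`).
#' @return `path`, invisibly.
#' @export
write_vienna <- function(fold, path, id = "structure") {
  stopifnot(inherits(fold, "mircane_fold"))
  energy <- if (is.na(fold$mfe_kcal)) "" else
    paste0(" (", format(round(fold$mfe_kcal, 2), nsmall = 2), ")")
  writeLines(c(paste0(">", id), fold$residues,
               paste0(fold$dot_bracket, energy)), path)
  invisible(path)
}

#' Parse a CT (connect) format secondary structure file
#'
#' Standard 6-column connect format: index, base, previous, next, partner,
#' natural numbering. The header line's first field gives the sequence
#' length and may be followed by an energy annotation (`dG = -12.3` or
#' `ENERGY = -12.3`); when several structures are concatenated only the
#' first is read.
#'
#' @param path Path to a CT file.
#' @return A `mircane_fold` with `source = "ct_file"`.
#' @export
parse_ct <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) abort(paste0("truncated CT file: ", path))
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(n) || n < 1) {
    abort("CT header does not start with a sequence length (line 1)")
  }
  energy <- NA_real_
  em <- regexpr("=\\s*(-?[0-9.]+)", lines[1])
  if (em > 0) {
    energy <- as.numeric(sub("=\\s*", "", regmatches(lines[1], em)))
  }
  if (length(lines) < n + 1) {
    abort(paste0("CT file ends before row ", n + 1))
  }
  bases <- character(n)
  pairing <- integer(n)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(lines[k + 1]), "\\s+")[[1]]
    if (length(f) < 5) {
      abort(paste0("malformed CT row at line ", k + 1))
    }
    idx <- as.integer(f[1])
    if (is.na(idx) || idx != k) {
      abort(paste0("CT row index mismatch at line ", k + 1))
    }
    bases[k] <- f[2]
    pairing[k] <- as.integer(f[5])
  }
  if (any(pairing < 0 | pairing > n)) {
    bad <- which(pairing < 0 | pairing > n)[1]
    abort(paste0("CT partner out of range at line ", bad + 1))
  }
  for (k in seq_len(n)) {
    j <- pairing[k]
    if (j > 0 && pairing[j] != k) {
      abort(paste0("CT pairing asymmetry: row ", k, " pairs ", j,
                   " but row ", j, " pairs ", pairing[j],
                   " (line ", k + 1, ")"))
    }
  }
  # reject pseudoknots: pairing must be well-nested
  stack <- integer(0)
  for (k in seq_len(n)) {
    j <- pairing[k]
    if (j > k) {
      stack <- c(stack, j)
    } else if (j > 0 && j < k) {
      if (length(stack) == 0 || stack[length(stack)] != k) {
        abort(paste0("CT structure contains a pseudoknot (line ", k + 1, ")"))
      }
      stack <- stack[-length(stack)]
    }
  }
  residues <- normalize_rna(paste(bases, collapse = ""))$residues
  if (is.na(energy)) {
    inform("CT file carries no energy; mfe_kcal left undefined")
  }
  new_fold(residues, pairing, energy, "ct_file")
}

#' Adjusted minimal free energy (AMFE)
#'
#' Energy per 100 nt: `AMFE = (|mfe_kcal| / length) * 100`, reported as a
#' positive number.
#'
#' @param mfe_kcal Minimal free energy in kcal/mol (<= 0).
#' @param length Sequence length in nt (>= 1).
#' @return AMFE as a positive number.
#' @export
amfe <- function(mfe_kcal, length) {
  stopifnot(length >= 1)
  if (any(mfe_kcal > 0, na.rm = TRUE)) {
    abort("amfe: mfe_kcal must be <= 0")
  }
  abs(mfe_kcal) / length * 100
}

#' Minimal free energy index (MFEI)
#'
#' `MFEI = AMFE / GC%`: normalises the folding energy by both sequence
#' length and G+C content, and discriminates miRNA precursors (typically
#' MFEI > 0.65-0.85 under thermodynamic folding) from other non-coding RNAs
#' and mRNAs. Reported as a positive number.
#'
#' @inheritParams amfe
#' @param gc_percent G+C content in `(0, 100]`.
#' @return MFEI as a positive number.
#' @examples
#' mfei(-47, 100, 50)
#' @export
mfei <- function(mfe_kcal, length, gc_percent) {
  if (any(gc_percent <= 0, na.rm = TRUE)) {
    abort("mfei is undefined for GC content of 0")
  }
  amfe(mfe_kcal, length) / gc_percent
}
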