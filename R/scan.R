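#' Read a mature miRNA catalog from FASTA
#'
#' Mature miRNA queries drive the homology scan. The FASTA description may
#' carry per-family metadata as `key=value` tokens; `arm=5p` or `arm=3p`
#' records on which precursor arm the mature sequence sits in the species the
#' query comes from (used by hairpin criterion 3). Absent metadata defaults
#' to `unknown`, which makes that criterion pass automatically.
#'
#' @param path Path to a FASTA file of mature miRNAs (19-24 nt each).
#' @return A tibble with columns `family` (record id), `residues` and
#'   `expected_arm` (`"5p"`, `"3p"` or `"unknown"`).
#' @export
read_mature_fasta <- function(path) {
  recs <- read_fasta(path)
  arm <- str_match_field(recs$description, "arm")
  arm[is.na(arm) | !arm %in% c("5p", "3p")] <- "unknown"
  out <- tibble(
    family = recs$id,
    residues = recs$residues,
    expected_arm = arm
  )
  validate_mature(out)
  out
}

str_match_field <- function(x, key) {
  m <- regmatches(x, regexpr(paste0(key, "=\\S+"), x))
  out <- rep(NA_character_, length(x))
  hit <- regexpr(paste0(key, "=\\S+"), x)
  ok <- hit > 0
  out[ok] <- sub(paste0("^", key, "="), "",
                 regmatches(x, hit))
  out
}

validate_mature <- function(queries) {
  stopifnot(is.data.frame(queries),
            all(c("family", "residues") %in% names(queries)))
  len <- nchar(queries$residues)
  if (any(len < 19 | len > 24)) {
    bad <- queries$family[len < 19 | len > 24]
    abort(paste0("mature sequences must be 19-24 nt: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(queries)
}

#' Scan a sequence database for mature miRNA matches
#'
#' Finds every locus, on both strands, where a mature miRNA query aligns to a
#' database substring with at most `max_edits` unit-cost edits (substitutions
#' plus single-nucleotide indels; a 2-nt gap costs 2). The scan is exhaustive
#' - a full semi-global dynamic programme is run against every record, so
#' results are identical to brute-force evaluation of every offset - and
#' `seed_len` (the word size a seeded search would use) is retained for
#' interface compatibility and validated but does not restrict the search.
#' Overlapping hits of the same query and strand are merged, keeping the hit
#' with the lowest edit total (ties: leftmost).
#'
#' @param db Sequence tibble from [read_fasta()].
#' @param queries Mature catalog from [read_mature_fasta()], or any tibble
#'   with `family` and `residues` columns (and optionally `expected_arm`).
#' @param max_edits Maximum total edits allowed (default 3).
#' @param seed_len Nominal word size (default 7); must not exceed the
#'   shortest query.
#' @return A tibble of hits: `db_id`, `strand` (`"+"`/`"-"`), `start`, `end`
#'   (1-based inclusive, always on the + strand of the database record),
#'   `family`, `substitutions`, `gaps`, `edit_total`.
#' @export
scan_mirna <- function(db, queries, max_edits = 3, seed_len = 7) {
  stopifnot(is.data.frame(db), nrow(db) > 0)
  if (!is.data.frame(queries) || nrow(queries) == 0) {
    abort("scan_mirna: empty mature catalog")
  }
  validate_mature(queries)
  if (seed_len > min(nchar(queries$residues))) {
    abort("seed_len exceeds the shortest query length")
  }
  if (max_edits < 0) abort("max_edits must be >= 0")

  rows <- list()
  for (r in seq_len(nrow(db))) {
    plus <- db$residues[r]
    minus <- reverse_complement(plus)
    len <- nchar(plus)
    homopolymer_warning(db$id[r], plus)
    for (q in seq_len(nrow(queries))) {
      for (strand in c("+", "-")) {
        subject <- if (strand == "+") plus else minus
        res <- .scan_kernel(subject, queries$residues[q], as.integer(max_edits))
        hits <- tibble::as_tibble(res$hits)
        if (nrow(hits) == 0) next
        hits <- merge_scan_hits(hits)
        if (strand == "-") {
          s <- len - hits$end + 1L
          e <- len - hits$start + 1L
          hits$start <- s
          hits$end <- e
        }
        hits$db_id <- db$id[r]
        hits$strand <- strand
        hits$family <- queries$family[q]
        rows[[length(rows) + 1]] <- hits
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      db_id = character(), strand = character(), start = integer(),
      end = integer(), family = character(), substitutions = integer(),
      gaps = integer(), edit_total = integer()
    ))
  }
  bind_rows(rows) |>
    select("db_id", "strand", "start", "end", "family",
           "substitutions", "gaps", "edit_total") |>
    arrange(.data$db_id, .data$family, .data$strand, .data$start)
}

# Merge overlapping candidate hits (same query/strand), keeping the lowest
# edit total; ties broken towards the leftmost (then shortest) hit.
merge_scan_hits <- function(hits) {
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  grp <- integer(nrow(hits))
  g <- 0L
  hi <- -Inf
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] > hi) g <- g + 1L
    grp[i] <- g
    hi <- max(hi, hits$end[i])
  }
  hits$.grp <- grp
  hits |>
    group_by(.data$.grp) |>
    arrange(.data$edit_total, .data$start, .data$end, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".grp")
}

# The scan applies no low-complexity masking; flag homopolymer-heavy records
# instead so spurious hit pile-ups can be traced.
homopolymer_warning <- function(id, residues) {
  runs <- rle(seq_chars(residues))
  frac <- sum(runs$lengths[runs$lengths >= 10]) / nchar(residues)
  if (frac > 0.5) {
    inform(paste0("record ", id, " is >50% homopolymer runs; ",
                  "expect spurious scan hits"))
  }
  invisible(NULL)
}

#' Extract candidate precursor windows around scan hits
#'
#' Cuts a window of `flank` nucleotides on either side of each mature-miRNA
#' hit (clamped to the record; with the default 300-nt flank a full-length
#' window spans about 620 nt). Minus-strand hits are reverse-complemented so
#' that the mature sequence always reads 5'-3' left-to-right in the window.
#'
#' @param db Sequence tibble the hits refer to.
#' @param hits Hit tibble from [scan_mirna()].
#' @param flank Flank length in nt on each side (default 300).
#' @return A tibble of windows: `window_id`, `db_id`, `strand`, `family`,
#'   `window_start`, `window_end` (1-based inclusive, + strand coordinates),
#'   `residues` (strand-resolved), `mature_offset` (1-based position of the
#'   mature within `residues`) and `mature_len`.
#' @export
extract_windows <- function(db, hits, flank = 300) {
  stopifnot(is.data.frame(hits))
  idx <- match(hits$db_id, db$id)
  if (anyNA(idx)) {
    abort(paste0("hits refer to unknown db record(s): ",
                 paste(unique(hits$db_id[is.na(idx)]), collapse = ", ")))
  }
  out <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    rec <- db[idx[i], ]
    len <- nchar(rec$residues)
    if (hits$start[i] < 1 || hits$end[i] > len) {
      abort(paste0("hit coordinates outside record ", rec$id))
    }
    ws <- max(1L, hits$start[i] - flank)
    we <- min(len, hits$end[i] + flank)
    res <- str_sub(rec$residues, ws, we)
    if (hits$strand[i] == "+") {
      off <- hits$start[i] - ws + 1L
    } else {
      res <- reverse_complement(res)
      off <- we - hits$end[i] + 1L
    }
    out[[i]] <- tibble(
      window_id = paste0(rec$id, ":", ws, "-", we, ":", hits$strand[i],
                         ":", hits$family[i]),
      db_id = rec$id,
      strand = hits$strand[i],
      family = hits$family[i],
      window_start = ws,
      window_end = we,
      residues = res,
      mature_offset = off,
      mature_len = hits$end[i] - hits$start[i] + 1L
    )
  }
  bind_rows(out)
}

#' Drop candidate windows matching an exclusion database
#'
#' A local stand-in for screening candidates against collections of known
#' non-miRNA RNAs (tRNA, rRNA, snoRNA and similar hairpin mimics): any window
#' whose mature-spanning region hits the exclusion database under
#' [scan_mirna()] semantics is removed, and each removal is reported with the
#' matching exclusion id.
#'
#' @param windows Window tibble from [extract_windows()].
#' @param exclusion_db Sequence tibble of non-miRNA RNAs; an empty or `NULL`
#'   database is a no-op.
#' @param max_edits Edit tolerance for the exclusion match (default 3).
#' @return The filtered window tibble.
#' @export
exclusion_screen <- function(windows, exclusion_db, max_edits = 3) {
  if (is.null(exclusion_db) || nrow(exclusion_db) == 0 ||
      nrow(windows) == 0) {
    return(windows)
  }
  keep <- rep(TRUE, nrow(windows))
  for (i in seq_len(nrow(windows))) {
    mature <- str_sub(windows$residues[i], windows$mature_offset[i],
                      windows$mature_offset[i] + windows$mature_len[i] - 1L)
    for (r in seq_len(nrow(exclusion_db))) {
      for (subject in c(exclusion_db$residues[r],
                        reverse_complement(exclusion_db$residues[r]))) {
        res <- .scan_kernel(subject, mature, as.integer(max_edits))
        if (min(c(res$end_edits, Inf)) <= max_edits) {
          keep[i] <- FALSE
          inform(paste0("window ", windows$window_id[i],
                        " removed: mature region matches exclusion entry ",
                        exclusion_db$id[r]))
          break
        }
      }
      if (!keep[i]) break
    }
  }
  windows[keep, , drop = FALSE]
}
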