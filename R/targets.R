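#' Block pre-filter for miRNA target sites
#'
#' The ungapped pre-filter of the target predictor: the miRNA is read 5'-3'
#' and divided into three blocks - positions 1-8 (block 1), 9-11 (block 2)
#' and 12-end (block 3; nominally 10 nt for a 21-mer, with shorter or longer
#' miRNAs absorbing the difference in block 3). The site is compared
#' antiparallel at equal length and a position counts as a mismatch when the
#' pairing is not Watson-Crick; by default a G:U wobble counts as a mismatch
#' here (it is only rewarded by the 0.5 point in the scored alignment).
#' Block 2 spans positions 9-11, which cover the canonical cleavage site
#' opposite the tenth miRNA nucleotide - hence its zero-mismatch cap.
#'
#' @param mirna Mature miRNA string, 5'-3', 19-24 nt.
#' @param site Candidate site on the message, 5'-3', same length as `mirna`.
#' @param caps Integer vector of per-block mismatch caps (default
#'   `c(2, 0, 3)`).
#' @param gu_is_match If `TRUE`, G:U wobbles count as matches in the filter.
#' @return A list with `pass` (logical) and `mismatches` (integer triple).
#' @export
block_filter <- function(mirna, site, caps = c(2L, 0L, 3L),
                         gu_is_match = FALSE) {
  m <- nchar(mirna)
  if (m < 19 || m > 24) abort("block_filter: miRNA must be 19-24 nt")
  if (nchar(site) != m) {
    abort("block_filter: site length must equal miRNA length")
  }
  q <- seq_chars(mirna)
  s <- rev(seq_chars(site))  # antiparallel: miRNA 5' end pairs site 3' end
  mm <- !is_wc_pair(q, s)
  if (gu_is_match) mm <- mm & !is_gu_pair(q, s)
  counts <- c(
    sum(mm[1:8]),
    sum(mm[9:11]),
    sum(mm[12:m])
  )
  list(pass = all(counts <= caps), mismatches = as.integer(counts))
}

is_wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

is_gu_pair <- function(a, b) {
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

duplex_pair_cost <- function(a, b) {
  ifelse(is_wc_pair(a, b), 0, ifelse(is_gu_pair(a, b), 0.5, 1))
}

#' Score a miRNA/target duplex by bulge-aware alignment
#'
#' Finds the minimum-score antiparallel alignment between a miRNA and a
#' candidate site region under the published scoring algebra: Watson-Crick
#' pair 0, G:U wobble pair 0.5, non-G:U mismatch 1, each bulged nucleotide
#' (on either strand) 1.5. The search is a dynamic programme over all
#' alignments using at most `max_bulges` bulged nucleotides in total, with a
#' deterministic tie-break (fewer bulges, then leftmost placement). Note the
#' 0.5 penalty applies to the G:U wobble *pair*, which is distinct from the
#' 1.5 bulged-nucleotide penalty.
#'
#' @param mirna Mature miRNA string, 5'-3'.
#' @param site Site region on the message, 5'-3'; its length may differ from
#'   the miRNA's by at most `max_bulges`.
#' @param max_bulges Maximum total bulged nucleotides (default 2; two
#'   bulges alone already cost 3.0, so more can never pass the 3.5 cutoff
#'   together with any other defect).
#' @return A `mircane_duplex` object: list with `mirna`, `site`, `columns`
#'   (tibble of aligned columns along the miRNA 5'-3': `mirna_base`,
#'   `site_base`, `type` in `wc`/`gu`/`mismatch`/`bulge_mirna`/
#'   `bulge_target`), counts `n_gu`, `n_mismatch`, `n_bulge`, score
#'   components `score_gu`, `score_mismatch`, `score_bulge` and
#'   `score_total`.
#' @examples
#' align_duplex("UGACAGAAGAGAGUGAGCAC", reverse_complement("UGACAGAAGAGAGUGAGCAC"))
#' @export
align_duplex <- function(mirna, site, max_bulges = 2) {
  m <- nchar(mirna)
  t_len <- nchar(site)
  if (abs(t_len - m) > max_bulges) {
    abort(paste0("length difference (", abs(t_len - m),
                 ") exceeds max_bulges (", max_bulges, ")"))
  }
  q <- seq_chars(mirna)
  s <- rev(seq_chars(site))
  G <- as.integer(max_bulges)

  INF <- Inf
  F <- array(INF, dim = c(m + 1, t_len + 1, G + 1))
  F[1, 1, 1] <- 0
  for (i in 0:m) {
    for (j in 0:t_len) {
      for (g in 0:G) {
        v <- F[i + 1, j + 1, g + 1]
        if (!is.finite(v)) next
        if (i < m && j < t_len) {
          cand <- v + duplex_pair_cost(q[i + 1], s[j + 1])
          if (cand < F[i + 2, j + 2, g + 1]) F[i + 2, j + 2, g + 1] <- cand
        }
        if (i < m && g < G) {
          cand <- v + 1.5
          if (cand < F[i + 2, j + 1, g + 2]) F[i + 2, j + 1, g + 2] <- cand
        }
        if (j < t_len && g < G) {
          cand <- v + 1.5
          if (cand < F[i + 1, j + 2, g + 2]) F[i + 1, j + 2, g + 2] <- cand
        }
      }
    }
  }
  finals <- F[m + 1, t_len + 1, ]
  best_g <- which.min(finals) - 1L  # which.min takes the first (fewest bulges)
  best <- finals[best_g + 1]
  if (!is.finite(best)) {
    abort("no alignment within the bulge budget")
  }

  # traceback, preferring paired columns (pushes bulges leftward)
  i <- m; j <- t_len; g <- best_g
  cols <- list()
  while (i > 0 || j > 0) {
    v <- F[i + 1, j + 1, g + 1]
    if (i > 0 && j > 0 &&
        is.finite(F[i, j, g + 1]) &&
        v == F[i, j, g + 1] + duplex_pair_cost(q[i], s[j])) {
      type <- if (is_wc_pair(q[i], s[j])) "wc" else
        if (is_gu_pair(q[i], s[j])) "gu" else "mismatch"
      cols[[length(cols) + 1]] <- list(mirna_base = q[i], site_base = s[j],
                                       type = type)
      i <- i - 1; j <- j - 1
    } else if (i > 0 && g > 0 && is.finite(F[i, j + 1, g]) &&
               v == F[i, j + 1, g] + 1.5) {
      cols[[length(cols) + 1]] <- list(mirna_base = q[i], site_base = "-",
                                       type = "bulge_mirna")
      i <- i - 1; g <- g - 1
    } else {
      cols[[length(cols) + 1]] <- list(mirna_base = "-", site_base = s[j],
                                       type = "bulge_target")
      j <- j - 1; g <- g - 1
    }
  }
  columns <- bind_rows(lapply(rev(cols), tibble::as_tibble))

  n_gu <- sum(columns$type == "gu")
  n_mm <- sum(columns$type == "mismatch")
  n_bulge <- sum(columns$type %in% c("bulge_mirna", "bulge_target"))
  structure(
    list(
      mirna = mirna, site = site, columns = columns,
      n_gu = n_gu, n_mismatch = n_mm, n_bulge = n_bulge,
      score_gu = 0.5 * n_gu, score_mismatch = 1 * n_mm,
      score_bulge = 1.5 * n_bulge,
      score_total = 0.5 * n_gu + 1 * n_mm + 1.5 * n_bulge
    ),
    class = "mircane_duplex"
  )
}

#' @export
print.mircane_duplex <- function(x, ...) {
  cat("<mircane_duplex> score ", x$score_total, " (", x$n_gu, " G:U, ",
      x$n_mismatch, " mismatch, ", x$n_bulge, " bulged)\n", sep = "")
  bars <- c(wc = "|", gu = "o", mismatch = " ", bulge_mirna = " ",
            bulge_target = " ")
  cat("miRNA 5' ", paste(x$columns$mirna_base, collapse = ""), " 3'\n",
      "         ", paste(bars[x$columns$type], collapse = ""), "\n",
      "mRNA  3' ", paste(x$columns$site_base, collapse = ""), " 5'\n",
      sep = "")
  invisible(x)
}

#' Predict miRNA target sites in transcripts
#'
#' Slides each mature miRNA over every same-length window of each transcript
#' (sense strand; messages are directional), applies the block pre-filter,
#' and for passing windows scores bulge-aware alignments against site
#' regions shifted and resized by up to `max_bulges` nt, keeping the
#' best-scoring duplex per locus. Hits scoring at most
#' `config$target_threshold` are retained, near-duplicate hits at one locus
#' are merged, and transcripts sharing at least `config$target_identity`
#' percent global identity are collapsed into one reported gene target per
#' family (the cluster representative).
#'
#' @param mirnas Mature catalog tibble (`family`, `residues`).
#' @param transcripts Sequence tibble of candidate messages.
#' @param config A [mircane_config()].
#' @return A tibble sorted by family, target and site position: `family`,
#'   `target_id`, `site_start`, `site_end` (1-based inclusive),
#'   `block_mm1`-`block_mm3`, `n_gu`, `n_mismatch`, `n_bulge`, `score`,
#'   `n_collapsed` (transcripts represented by the hit).
#' @export
scan_targets <- function(mirnas, transcripts, config = mircane_config()) {
  stopifnot(is.data.frame(mirnas), is.data.frame(transcripts))
  hits <- list()
  for (qi in seq_len(nrow(mirnas))) {
    mirna <- mirnas$residues[qi]
    fam <- mirnas$family[qi]
    m <- nchar(mirna)
    for (ti in seq_len(nrow(transcripts))) {
      tx <- transcripts$residues[ti]
      L <- nchar(tx)
      if (L < m) next
      tch <- seq_chars(tx)
      W <- L - m + 1L
      mm <- matrix(FALSE, nrow = m, ncol = W)
      qch <- seq_chars(mirna)
      for (i in seq_len(m)) {
        part <- tch[(seq_len(W)) + (m - i)]
        bad <- !is_wc_pair(qch[i], part)
        if (config$gu_is_block_match) {
          bad <- bad & !is_gu_pair(qch[i], part)
        }
        mm[i, ] <- bad
      }
      b1 <- colSums(mm[1:8, , drop = FALSE])
      b2 <- colSums(mm[9:11, , drop = FALSE])
      b3 <- colSums(mm[12:m, , drop = FALSE])
      pass <- b1 <= config$block_caps[1] & b2 <= config$block_caps[2] &
        b3 <= config$block_caps[3]
      for (w in which(pass)) {
        best <- best_site_alignment(mirna, tx, w, config$max_bulges)
        if (is.null(best)) next
        hits[[length(hits) + 1]] <- tibble(
          family = fam,
          target_id = transcripts$id[ti],
          site_start = best$start,
          site_end = best$end,
          block_mm1 = as.integer(b1[w]),
          block_mm2 = as.integer(b2[w]),
          block_mm3 = as.integer(b3[w]),
          n_gu = best$duplex$n_gu,
          n_mismatch = best$duplex$n_mismatch,
          n_bulge = best$duplex$n_bulge,
          score = best$duplex$score_total
        )
      }
    }
  }
  empty <- tibble(
    family = character(), target_id = character(), site_start = integer(),
    site_end = integer(), block_mm1 = integer(), block_mm2 = integer(),
    block_mm3 = integer(), n_gu = integer(), n_mismatch = integer(),
    n_bulge = integer(), score = numeric(), n_collapsed = integer()
  )
  if (length(hits) == 0) return(empty)
  hits <- bind_rows(hits) |>
    filter(.data$score <= config$target_threshold) |>
    merge_target_hits() |>
    collapse_targets(transcripts, config)
  if (nrow(hits) == 0) return(empty)
  arrange(hits, .data$family, .data$target_id, .data$site_start)
}

# Best-scoring duplex near an ungapped window: tries site regions whose
# start shifts and length differs from the miRNA by up to max_bulges nt.
best_site_alignment <- function(mirna, tx, w, max_bulges) {
  m <- nchar(mirna)
  L <- nchar(tx)
  best <- NULL
  for (delta in -max_bulges:max_bulges) {
    for (shift in -max_bulges:max_bulges) {
      s <- w + shift
      e <- s + m + delta - 1L
      if (s < 1 || e > L || e < s) next
      region <- str_sub(tx, s, e)
      d <- align_duplex(mirna, region, max_bulges = max_bulges)
      if (is.null(best) || d$score_total < best$duplex$score_total ||
          (d$score_total == best$duplex$score_total &&
           abs(delta) + abs(shift) <
             abs(best$delta) + abs(best$shift))) {
        best <- list(start = s, end = e, duplex = d,
                     delta = delta, shift = shift)
      }
    }
  }
  best
}

# Adjacent passing windows describe the same locus: merge hits with
# overlapping site intervals (same family and transcript), keeping the
# lowest score, ties leftmost.
merge_target_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    group_by(.data$family, .data$target_id) |>
    arrange(.data$site_start, .data$site_end, .by_group = TRUE) |>
    mutate(.grp = cumsum(.data$site_start >
                           dplyr::lag(cummax(.data$site_end),
                                      default = 0L))) |>
    group_by(.data$family, .data$target_id, .data$.grp) |>
    arrange(.data$score, .data$site_start, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".grp")
}

# One reported gene target per >= identity-threshold transcript cluster.
collapse_targets <- function(hits, transcripts, config) {
  if (nrow(hits) == 0) return(hits)
  out <- list()
  for (fam in unique(hits$family)) {
    fh <- hits[hits$family == fam, , drop = FALSE]
    seqs <- transcripts[transcripts$id %in% unique(fh$target_id), ,
                        drop = FALSE]
    cl <- cluster_sequences(seqs, threshold = config$target_identity,
                            strict = FALSE)
    fh$n_collapsed <- NA_integer_
    keep <- fh$target_id %in% cl$representative
    fh <- fh[keep, , drop = FALSE]
    sizes <- setNames(cl$n_members, cl$representative)
    fh$n_collapsed <- as.integer(sizes[fh$target_id])
    out[[length(out) + 1]] <- fh
  }
  bind_rows(out)
}
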