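#' @name synthetic
#' @title Synthetic sequence databases with known ground truth
#' @description
#' The generator builds EST-like databases in which every true precursor,
#' decoy and target site is constructed, so recovery can be checked exactly.
#' Constructed precursors use restricted alphabets for their non-functional
#' parts: poly-A flanks, a poly-C/poly-G closing stem, a poly-N terminal
#' loop (ambiguity bases never pair, like a low-quality EST stretch), and a
#' fixed 2-bp C:G adapter between the duplex and the loop.
#' Under a base-pair-maximising folding model a flank or loop base whose
#' complement occurs anywhere reachable can substitute into the stem at
#' equal energy, so these alphabets are chosen such that no flank or loop
#' base can pair with any reachable base: the designed hairpin is then the
#' unique optimal structure and the engineered duplex statistics are
#' exactly what the validator sees. Real ESTs are messier; the methods
#' vignette discusses what this idealisation does and does not test.
NULL

rand_chars <- function(n, alphabet) {
  if (n <= 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# bases that neither Watson-Crick nor wobble pair with any base in `chars`
nonpairing_bases <- function(chars) {
  partners <- unique(unlist(lapply(chars, function(b) {
    switch(b, A = "U", U = c("A", "G"), G = c("C", "U"), C = "G",
           character(0))
  })))
  setdiff(c("A", "C", "G", "U"), partners)
}

bases_pair <- function(a, b) {
  is_wc_pair(a, b) | is_gu_pair(a, b)
}

# Design the engineered star mismatches: positions within the mature and a
# substitute base per position. Under a pairing-maximising fold a designed
# mismatch stays a clean symmetric mismatch only if no equal-or-better
# alternative pairing exists one register off. Working through the pair
# weights (G:C 3, A:U 2, G:U 1), such an alternative exists exactly when
#   (i)  the substitute base pairs the mature position itself (any pair
#        type: the column would simply pair), or
#   (ii) the substitute is the Watson-Crick complement of a neighbouring
#        mature base (it could replace that neighbour's designed partner
#        at equal weight), or
#   (iii) the mature base equals a neighbouring mature base (it could
#        slide onto the neighbour's star partner at equal weight);
# wobble-weight alternatives are strictly worse and never chosen. A
# position is eligible when a substitute passing (i)+(ii) exists and (iii)
# holds for neither neighbour. Positions are kept >= 2 apart; a run of
# run_len additionally requires the bases flanking the run not to pair
# each other (they could otherwise close a mini-hairpin across the
# unpaired run, which spans >= the minimum loop).
design_star_mismatches <- function(mature_chars, n_mm, run_len,
                                   rotate = 0L, relax = 0L) {
  L <- length(mature_chars)
  if (n_mm == 0) return(list(pos = integer(0), sub = character(0)))
  cand <- 3:(L - 4)

  # relax widens the eligible set by shrinking the neighbourhood whose
  # complements the substitute must avoid (2, 1, 0 positions); relaxed
  # designs rely on the caller's fold verification to weed out failures
  substitute_for <- function(s, e) {
    guard <- max(0L, 2L - relax)
    nbr <- mature_chars[max(1, s - guard):min(L, e + guard)]
    bad <- unique(c(
      unlist(lapply(mature_chars[s:e], function(b) {
        switch(b, A = "U", U = c("A", "G"), G = c("C", "U"), C = "G")
      })),
      if (guard > 0) wc_partner(nbr)
    ))
    setdiff(c("A", "C", "G", "U"), bad)
  }
  slide_safe <- function(p) {
    mature_chars[p] != mature_chars[p + 1] &&
      mature_chars[p] != mature_chars[p - 1]
  }

  pos <- integer(0)
  sub <- character(0)
  if (run_len > 1) {
    starts <- cand[cand + run_len - 1 <= max(cand)]
    feasible <- starts[vapply(starts, function(s) {
      e <- s + run_len - 1
      length(substitute_for(s, e)) > 0 &&
        !bases_pair(mature_chars[s - 1], mature_chars[e + 1]) &&
        mature_chars[s] != mature_chars[s - 1] &&
        mature_chars[e] != mature_chars[e + 1]
    }, logical(1))]
    if (length(feasible) == 0) {
      abort("no mature window admits the requested mismatch run")
    }
    s <- feasible[(rotate %% length(feasible)) + 1]
    e <- s + run_len - 1
    pos <- s:e
    sub <- rep(substitute_for(s, e)[1], run_len)
  }

  n_single <- n_mm - length(pos)
  # spread singles over eligible positions, centre-out, >= 2 apart;
  # `rotate` shifts the starting point so callers can retry alternatives
  elig <- cand[vapply(cand, function(p) {
    length(substitute_for(p, p)) > 0 && slide_safe(p)
  }, logical(1))]
  elig <- elig[order(abs(elig - mean(cand)))]
  if (length(elig) > 0 && rotate > 0) {
    k <- rotate %% length(elig)
    elig <- c(elig[-seq_len(k)], elig[seq_len(k)])
  }
  for (i in seq_len(n_single)) {
    ok <- elig[!elig %in% c(pos, pos - 1L, pos + 1L)]
    if (length(ok) == 0) {
      abort("cannot place that many rigidly-foldable mismatches")
    }
    p <- ok[1]
    pos <- c(pos, p)
    sub <- c(sub, substitute_for(p, p)[1])
  }
  o <- order(pos)
  list(pos = pos[o], sub = sub[o])
}

#' Construct a synthetic miRNA precursor with known duplex statistics
#'
#' Assembles `5' flank + closing stem + mature arm + adapter + loop +
#' adapter' + star arm + closing stem' + 3' flank` with the mature on the
#' requested arm and the star carrying exactly `mismatches` engineered
#' substitutions (isolated by default; a `run_len > 2` run violates the
#' consecutive-mismatch criterion on purpose). Substituted star bases are
#' chosen so that they cannot pair - Watson-Crick or wobble - with any
#' mature base of their mismatch run; together with the restricted
#' flank/stem/loop alphabets (see [synthetic]) this pins the fold to the
#' designed structure.
#'
#' @param mature Mature miRNA string (19-24 nt).
#' @param mismatches Number of engineered duplex mismatches.
#' @param arm `"5p"` or `"3p"`: arm carrying the mature sequence.
#' @param loop_len Terminal loop length (>= 3; default 24, large enough to
#'   keep the trimmed G+C content of the GC/AU-extreme catalog matures
#'   within the 30-70\% acceptance band).
#' @param flanks Integer pair: 5' and 3' flank lengths.
#' @param stem_ext Closing-stem extension in bp beyond the duplex.
#' @param run_len Length of the (single) mismatch run; 1 keeps all
#'   mismatches isolated.
#' @param star_bulge If `TRUE`, one extra nucleotide is inserted into the
#'   star arm, shifting the duplex register (violates the no-break-in-star
#'   criterion).
#' @param id Record id.
#' @return A list with `record` (one-row sequence tibble), `window`
#'   (one-row window tibble usable directly with [check_hairpin()]) and
#'   `truth` (one-row tibble of expected outcomes).
#' @export
make_precursor <- function(mature, mismatches = 3, arm = c("5p", "3p"),
                           loop_len = 24, flanks = c(50, 50), stem_ext = 14,
                           run_len = 1, star_bulge = FALSE,
                           id = "synthetic_precursor") {
  arm <- match.arg(arm)
  if (loop_len < 3) abort("loop_len must be >= 3")
  if (run_len > 1 && mismatches < run_len) {
    abort("mismatches must be >= run_len")
  }
  mch <- seq_chars(mature)
  L <- length(mch)
  if (mismatches > L) abort("more mismatches than mature positions")

  bulge_at <- if (star_bulge) find_au_window(mch) else 0L

  # The eligibility rules below make one-off rearrangements of the designed
  # structure energetically unattractive, but equal-energy rearrangement
  # chains through several positions can survive them, so each candidate
  # design is folded and verified against the designed pairing map;
  # alternative placements are tried until one folds exactly as designed.
  built <- NULL
  last_err <- NULL
  for (relax in 0:2) {
    for (rotate in 0:7) {
      design <- tryCatch(
        design_star_mismatches(mch, mismatches, run_len,
                               rotate = rotate, relax = relax),
        error = function(e) {
          last_err <<- conditionMessage(e)
          NULL
        }
      )
      if (is.null(design)) break  # capacity at this level: relax further
      cand <- assemble_precursor(mch, design, arm, loop_len, flanks,
                                 stem_ext, bulge_at)
      fold <- fold_rna(cand$residues, min_loop = 3)
      if (identical(fold$pairing, cand$designed_pairing)) {
        built <- cand
        break
      }
    }
    if (!is.null(built)) break
  }
  if (is.null(built)) {
    abort(paste0("could not realise a rigidly-folding precursor for ",
                 mature, " with ", mismatches, " mismatches",
                 if (!is.null(last_err)) paste0(" (", last_err, ")")))
  }
  pos <- built$design$pos
  residues <- built$residues
  offset <- built$offset
  hairpin <- built$hairpin
  designed_energy <- -3 * (stem_ext + 2) -
    sum(ifelse(mch[setdiff(seq_len(L), pos)] %in% c("G", "C"), 3, 2))

  trimmed_len <- nchar(hairpin)
  trimmed_gc <- gc_percent(hairpin)
  expected_mfei <- mfei(designed_energy, trimmed_len, trimmed_gc)
  expected_failed <- character(0)
  if (mismatches < 1 || mismatches > 6) expected_failed <- c(expected_failed, "c4")
  if (star_bulge) expected_failed <- c(expected_failed, "c5")
  if (expected_mfei <= 0.65 || trimmed_gc < 30 || trimmed_gc > 70) {
    expected_failed <- c(expected_failed, "c6")
  }
  if (run_len > 2) expected_failed <- c(expected_failed, "c7")
  if (stem_ext < 2) expected_failed <- c(expected_failed, "c8")
  if (trimmed_len < 60) expected_failed <- c(expected_failed, "c9")

  record <- tibble(id = id, description = "synthetic precursor",
                   residues = residues, source_alphabet = "RNA")
  window <- tibble(
    window_id = id, db_id = id, strand = "+", family = NA_character_,
    window_start = 1L, window_end = nchar(residues),
    residues = residues, mature_offset = offset, mature_len = L
  )
  truth <- tibble(
    id = id, category = "precursor_embed", arm = arm,
    mismatches = mismatches, run_len = run_len, star_bulge = star_bulge,
    expected_verdict = if (length(expected_failed) == 0) "accept" else "reject",
    expected_failed = paste(expected_failed, collapse = ",")
  )
  list(record = record, window = window, truth = truth)
}

# Assemble one candidate precursor window and its designed pairing map
# (1-based partner vector, 0 = unpaired) for verification against the fold.
assemble_precursor <- function(mch, design, arm, loop_len, flanks,
                               stem_ext, bulge_at) {
  L <- length(mch)
  star <- seq_chars(reverse_complement(paste(mch, collapse = "")))
  for (k in seq_along(design$pos)) {
    star[L - design$pos[k] + 1] <- design$sub[k]
  }
  k_b <- 0L
  if (bulge_at > 0) {
    k_b <- L - bulge_at + 1L  # insert after the partner of that position
    star <- append(star, "C", after = k_b)
  }
  Ls <- length(star)
  star_str <- paste(star, collapse = "")
  mature_str <- paste(mch, collapse = "")

  stem5 <- strrep("C", stem_ext)
  stem3 <- strrep("G", stem_ext)
  loop <- strrep("N", loop_len)
  F5 <- flanks[1]

  if (arm == "5p") {
    hairpin <- paste0(stem5, mature_str, "CC", loop, "GG", star_str, stem3)
    mature_at <- F5 + stem_ext
    star_at <- F5 + stem_ext + L + 2L + loop_len + 2L
  } else {
    hairpin <- paste0(stem5, star_str, "CC", loop, "GG", mature_str, stem3)
    star_at <- F5 + stem_ext
    mature_at <- F5 + stem_ext + Ls + 2L + loop_len + 2L
  }
  residues <- paste0(strrep("A", F5), hairpin, strrep("A", flanks[2]))
  n <- nchar(residues)

  pairing <- integer(n)
  link <- function(i, j) {
    pairing[i] <<- j
    pairing[j] <<- i
  }
  stem3_at <- F5 + nchar(hairpin) - stem_ext
  for (i in seq_len(stem_ext)) {
    link(F5 + i, stem3_at + stem_ext + 1L - i)
  }
  # adapter: two C:G pairs bracketing the loop
  cc_at <- min(mature_at, star_at) + (if (arm == "5p") L else Ls)
  gg_at <- cc_at + 2L + loop_len
  link(cc_at + 1L, gg_at + 2L)
  link(cc_at + 2L, gg_at + 1L)
  for (p in setdiff(seq_len(L), design$pos)) {
    j <- L - p + 1L
    if (k_b > 0 && j > k_b) j <- j + 1L
    link(mature_at + p, star_at + j)
  }
  list(residues = residues, hairpin = hairpin,
       offset = as.integer(mature_at + 1L),
       designed_pairing = as.integer(pairing),
       design = design)
}

# a mature position whose +/-2 neighbourhood is A/U only (so an inserted C
# cannot pair anything nearby)
find_au_window <- function(mch) {
  L <- length(mch)
  for (p in 5:(L - 5)) {
    if (all(mch[(p - 2):(p + 2)] %in% c("A", "U"))) return(p)
  }
  abort("mature has no A/U-rich window for a star bulge")
}

#' Construct a candidate failing exactly one hairpin criterion
#'
#' Builds, for each of the nine validation criteria, a candidate window
#' engineered to fail that criterion and no other (criteria presupposing a
#' one-arm duplex are vacuous when the duplex itself is the defect). Used
#' for knockout testing of [check_hairpin()].
#'
#' @param criterion One of `"c1"` ... `"c9"`.
#' @return A list with `window`, `query` (one-row mature tibble or `NULL`)
#'   and `expected_failed` (the criterion name).
#' @export
make_knockout <- function(criterion = paste0("c", 1:9)) {
  criterion <- match.arg(criterion)
  out <- switch(criterion,
    c1 = knockout_no_duplex(),
    c2 = knockout_spans_loop(),
    c3 = {
      p <- make_precursor("UGACAGAAGAGAGUGAGCAC", mismatches = 3,
                          arm = "5p", id = "ko_c3")
      list(window = p$window,
           query = tibble(family = "ko", residues = "UGACAGAAGAGAGUGAGCAC",
                          expected_arm = "3p"))
    },
    c4 = {
      p <- make_precursor("UGACAGAAGAGAGUGAGCAC", mismatches = 0,
                          arm = "5p", id = "ko_c4")
      list(window = p$window, query = NULL)
    },
    c5 = {
      # AU-rich interior admits the bulged C
      p <- make_precursor("GCGAUAUAAUAUAUCGCAUGC", mismatches = 1,
                          arm = "5p", star_bulge = TRUE, id = "ko_c5")
      list(window = p$window, query = NULL)
    },
    c6 = {
      # GC-only mature and a tight loop push trimmed G+C past 70%
      p <- make_precursor("GCGCGCGCGCGCGCGCGCGCG", mismatches = 3,
                          arm = "5p", loop_len = 6, id = "ko_c6")
      list(window = p$window, query = NULL)
    },
    c7 = {
      # G-flanked AAA run: boundaries cannot pair across the run
      p <- make_precursor("GCUGCGAAAGGUGCAUGCAUG", mismatches = 3,
                          arm = "5p", run_len = 3, id = "ko_c7")
      list(window = p$window, query = NULL)
    },
    c8 = {
      # mature starts G so the unprotected duplex fringe resists the
      # poly-A flank (A pairs neither G nor its complement C)
      p <- make_precursor("GCACAGAAGAGAGUGAGCAC", mismatches = 2,
                          arm = "5p", loop_len = 20, stem_ext = 0,
                          id = "ko_c8")
      list(window = p$window, query = NULL)
    },
    c9 = {
      p <- make_precursor("UGACAGAAGAGAGUGAGCAC", mismatches = 2,
                          arm = "5p", loop_len = 3, stem_ext = 2,
                          id = "ko_c9")
      list(window = p$window, query = NULL)
    }
  )
  out$expected_failed <- criterion
  out
}

# c1: mature in an unpairable context, plus an unrelated strong hairpin so
# every whole-window statistic still passes
knockout_no_duplex <- function() {
  hairpin <- paste0(strrep("G", 18), "AAAA", strrep("C", 18))
  mature <- substr(strrep("AAAAAC", 4), 1, 21)  # A/C only: cannot pair here
  residues <- paste0(hairpin, rand_chars(20, c("A", "C")), mature,
                     rand_chars(20, c("A", "C")))
  window <- tibble(
    window_id = "ko_c1", db_id = "ko_c1", strand = "+",
    family = NA_character_, window_start = 1L,
    window_end = nchar(residues), residues = residues,
    mature_offset = nchar(hairpin) + 20L + 1L, mature_len = 21L
  )
  list(window = window, query = NULL)
}

# c2: the mature sequence is itself a short hairpin centred on the terminal
# loop, embedded so the whole window still passes the composition criteria
knockout_spans_loop <- function() {
  mature <- paste0("GCAGCAGCA", "AAA", "UGCUGCUGC")  # self-complementary
  residues <- paste0(strrep("A", 30), strrep("C", 22), mature,
                     strrep("G", 22), strrep("A", 30))
  window <- tibble(
    window_id = "ko_c2", db_id = "ko_c2", strand = "+",
    family = NA_character_, window_start = 1L,
    window_end = nchar(residues), residues = residues,
    mature_offset = 30L + 22L + 1L, mature_len = nchar(mature)
  )
  list(window = window, query = NULL)
}

#' Generate decoy sequences
#'
#' Negative controls for the precursor pipeline: `random` uniform sequences,
#' `low_gc`/`high_gc` compositionally extreme sequences (fail the G+C
#' bounds), `short_hairpin` perfect hairpins far below the minimum stem-loop
#' length, and `mite` MITE-like perfect terminal inverted repeats (a perfect
#' duplex, rejected by the >= 1 mismatch rule when it ever reaches
#' validation). None contains a mature-miRNA homolog, so under a real
#' catalog decoys are normally rejected at the scan stage already.
#'
#' @param n Number of decoys.
#' @param length_range Uniform bounds on decoy length.
#' @param types Character vector of categories to draw from.
#' @return A list with `records` (sequence tibble) and `truth` (category and
#'   expected-reason tibble).
#' @export
make_decoys <- function(n, length_range = c(200, 500),
                        types = c("random", "low_gc", "high_gc",
                                  "short_hairpin", "mite")) {
  recs <- vector("list", n)
  cats <- character(n)
  for (i in seq_len(n)) {
    type <- types[((i - 1) %% length(types)) + 1]
    len <- sample(length_range[1]:length_range[2], 1)
    res <- switch(type,
      random = rand_chars(len, c("A", "C", "G", "U")),
      low_gc = rand_chars(len, c("A", "U", "A", "U", "G")),
      high_gc = rand_chars(len, c("G", "C", "G", "C", "A")),
      short_hairpin = {
        arm <- rand_chars(15, c("A", "C", "G", "U"))
        paste0(rand_chars(80, c("A", "C", "G", "U")), arm, "AAAA",
               reverse_complement(arm),
               rand_chars(80, c("A", "C", "G", "U")))
      },
      mite = {
        tir <- rand_chars(30, c("A", "C", "G", "U"))
        paste0(tir, rand_chars(max(10, len - 60), c("A", "C", "G", "U")),
               reverse_complement(tir))
      }
    )
    cats[i] <- type
    recs[[i]] <- tibble(
      id = sprintf("decoy_%03d_%s", i, type),
      description = paste("synthetic decoy:", type),
      residues = res, source_alphabet = "RNA"
    )
  }
  records <- bind_rows(recs)
  truth <- tibble(
    id = records$id, category = cats,
    expected_verdict = "reject",
    expected_failed = dplyr::case_match(cats,
      "low_gc" ~ "c6", "high_gc" ~ "c6", "short_hairpin" ~ "c9",
      "mite" ~ "c4", .default = ""
    )
  )
  list(records = records, truth = truth)
}

#' Generate a full synthetic EST database with embedded precursors
#'
#' Embeds constructed precursors for the given mature catalog among decoys,
#' with a sidecar truth table, so the whole precursor pipeline can be
#' checked for exact recovery (every embedded precursor found, no decoy
#' accepted).
#'
#' @param queries Mature catalog tibble (`family`, `residues`,
#'   `expected_arm`); arms default to `5p` when unknown.
#' @param n_embeds Number of embedded true precursors; families are
#'   recycled when `n_embeds` exceeds the catalog size.
#' @param n_decoys Number of decoys (see [make_decoys()]).
#' @param mismatches Engineered duplex mismatches per embed (default 3; must
#'   be <= the scan edit tolerance for the star arm not to out-scan the
#'   mature, and >= 1 for validity).
#' @param seed Integer seed; the same seed reproduces the database exactly.
#' @return A list with `db` (sequence tibble, embeds shuffled among decoys)
#'   and `truth` (tibble with one row per record).
#' @export
synth_precursor_db <- function(queries, n_embeds = 20, n_decoys = 200,
                               mismatches = 3, seed = 1) {
  set.seed(seed)
  fams <- rep(seq_len(nrow(queries)), length.out = n_embeds)
  recs <- vector("list", n_embeds)
  truths <- vector("list", n_embeds)
  for (i in seq_len(n_embeds)) {
    q <- queries[fams[i], ]
    arm <- if (!is.null(q$expected_arm) && q$expected_arm %in% c("5p", "3p"))
      q$expected_arm else "5p"
    p <- make_precursor(
      q$residues, mismatches = mismatches, arm = arm,
      id = sprintf("embed_%03d_%s", i, q$family)
    )
    p$record$description <- paste("synthetic EST with", q$family,
                                  "precursor")
    p$truth$family <- q$family
    recs[[i]] <- p$record
    truths[[i]] <- p$truth
  }
  dec <- make_decoys(n_decoys)
  db <- bind_rows(bind_rows(recs), dec$records)
  db <- db[sample(nrow(db)), ]
  truth <- bind_rows(
    bind_rows(truths) |> select("id", "category", "expected_verdict",
                                "expected_failed", "family"),
    dec$truth |> mutate(family = NA_character_)
  )
  list(db = db, truth = truth)
}

#' Construct a target site with a known complementarity score
#'
#' Engineers a site whose best bulge-aware duplex with the given miRNA has
#' exactly the requested defects, hence score
#' `0.5*n_gu + 1*n_mm + 1.5*n_bulge`, and embeds it in a random host
#' transcript. G:U wobbles and mismatches are placed at spaced positions in
#' blocks 1 and 3 (block 2 stays perfect); bulged nucleotides are inserted
#' near the site end pairing the miRNA 3' tail, where the ungapped
#' pre-filter register is disturbed the least.
#'
#' @param mature Mature miRNA string.
#' @param n_gu Number of G:U wobble pairs.
#' @param n_mm Number of non-G:U mismatches.
#' @param n_bulge Number of bulged nucleotides (0-2), inserted on the target
#'   strand.
#' @param host_len Host transcript length.
#' @param id Record id.
#' @return A list with `record` (host transcript tibble) and `truth`
#'   (site coordinates, expected score, whether the block pre-filter is
#'   expected to pass, and `expected_accepted`).
#' @export
make_target_site <- function(mature, n_gu = 0, n_mm = 0, n_bulge = 0,
                             host_len = 300, id = "synthetic_target") {
  mch <- seq_chars(mature)
  L <- length(mch)
  if (n_bulge > 2) abort("at most 2 bulged nucleotides are supported")
  slots_b1 <- c(3L, 6L)
  slots_b3 <- c(13L, 16L, 19L)
  # bulged nucleotides misalign the miRNA 3' tail in the ungapped
  # pre-filter register: 1 + n_bulge positions for an insertion this deep
  disturb <- if (n_bulge > 0) 1L + n_bulge else 0L
  site <- seq_chars(reverse_complement(mature))  # site[k] pairs mature[L-k+1]

  place <- function(slots, kind) {
    # returns the chosen miRNA position, or NA when no slot fits
    for (p in slots) {
      if (kind == "gu" && !mch[p] %in% c("G", "U")) next
      return(p)
    }
    NA_integer_
  }

  defects <- c(rep("gu", n_gu), rep("mm", n_mm))
  used <- integer(0)
  placed_b1 <- 0L
  placed_b3 <- 0L
  for (kind in defects) {
    avail_b1 <- setdiff(slots_b1, used)
    avail_b3 <- setdiff(slots_b3, used)
    p <- if (placed_b1 < 2L) place(avail_b1, kind) else NA_integer_
    if (is.na(p)) p <- place(avail_b3, kind)
    if (is.na(p)) {
      abort(paste0("cannot place a ", kind,
                   " defect: no compatible position left outside block 2"))
    }
    used <- c(used, p)
    if (p %in% slots_b1) placed_b1 <- placed_b1 + 1L else
      placed_b3 <- placed_b3 + 1L
    k <- L - p + 1L
    if (kind == "gu") {
      site[k] <- if (mch[p] == "G") "U" else "G"
    } else {
      allowed <- nonpairing_bases(mch[p])
      site[k] <- allowed[1]
    }
  }
  if (n_bulge > 0) {
    # the inserted base must not pair any miRNA tail base it could face;
    # inserting 1 + n_bulge positions in makes trimming the bulge off the
    # site end cost at least as much as the bulge penalty itself
    ins <- nonpairing_bases(mch[(L - 3L):L])
    if (length(ins) == 0) {
      abort(paste0("cannot bulge against this miRNA: every base pairs ",
                   "one of its four 3'-terminal nucleotides"))
    }
    # the bulge must not be able to migrate off the site end: at least one
    # step of the migration path must face a non-pairing tail dinucleotide
    k <- 1L + n_bulge
    steps <- (L - k + 1L):(L - 1L)
    blocked <- any(!bases_pair(wc_partner(mch[steps]), mch[steps + 1L]))
    if (!blocked) {
      abort(paste0("cannot bulge against this miRNA: its 3'-tail repeats ",
                   "let a bulged site nucleotide realign off the end"))
    }
    site <- append(site, rep(ins[1], n_bulge), after = k)
  }
  site <- paste(site, collapse = "")

  expected_score <- 0.5 * n_gu + 1 * n_mm + 1.5 * n_bulge
  block_pass <- placed_b1 <= 2L && (placed_b3 + disturb) <= 3L

  pos <- sample(seq_len(host_len - nchar(site) + 1), 1)
  host <- paste0(
    rand_chars(pos - 1, c("A", "C", "G", "U")), site,
    rand_chars(host_len - pos + 1 - nchar(site), c("A", "C", "G", "U"))
  )
  record <- tibble(id = id, description = "synthetic transcript",
                   residues = host, source_alphabet = "RNA")
  truth <- tibble(
    id = id, site_start = pos, site_end = pos + nchar(site) - 1L,
    n_gu = n_gu, n_mm = n_mm, n_bulge = n_bulge,
    expected_score = expected_score,
    expected_block_pass = block_pass,
    expected_accepted = block_pass && expected_score <= 3.5
  )
  list(record = record, truth = truth)
}

#' Write a synthetic database and its truth table to disk
#'
#' @param synth A list with `db` (or `records`) and `truth`, as returned by
#'   [synth_precursor_db()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly. Writes `database.fasta` and
#'   `truth.tsv`.
#' @export
save_synth <- function(synth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  db <- synth$db %||% synth$records
  write_fasta(db, file.path(dir, "database.fasta"))
  write.table(synth$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
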