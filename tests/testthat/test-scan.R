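make_db <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = names(seqs), description = "", residues = unname(seqs),
                 source_alphabet = "RNA")
}

one_query <- function(residues, family = "q1", arm = "unknown") {
  tibble::tibble(family = family, residues = residues, expected_arm = arm)
}

mutate_at_positions <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- setdiff(c("A", "C", "G", "U"), chars[p])[1]
  }
  paste(chars, collapse = "")
}

test_that("a verbatim embedded query is found once, exactly", {
  set.seed(1)
  q <- random_rna(21)
  host <- paste0(random_rna(240), q, random_rna(239))
  hits <- scan_mirna(make_db(h = host), one_query(q))
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$start, 241L)
  expect_equal(plus$end, 261L)
  expect_equal(plus$substitutions, 0L)
  expect_equal(plus$gaps, 0L)
})

test_that("hits are found up to the edit budget and not beyond", {
  set.seed(2)
  q <- random_rna(21)
  with2 <- mutate_at_positions(q, c(5, 15))
  with4 <- mutate_at_positions(q, c(3, 8, 13, 18))
  host2 <- paste0(random_rna(100), with2, random_rna(100))
  host4 <- paste0(random_rna(100), with4, random_rna(100))
  h2 <- scan_mirna(make_db(a = host2), one_query(q), max_edits = 3)
  expect_true(any(h2$strand == "+" & h2$edit_total == 2))
  h4 <- scan_mirna(make_db(a = host4), one_query(q), max_edits = 3)
  expect_false(any(h4$strand == "+" & h4$start > 90 & h4$start < 110))
  # the oracle agrees that 4 substitutions exceed the budget
  expect_gte(min(oracle_scan_end_edits(host4, q)[95:130]), 4)
})

test_that("minus-strand hits are reported in plus-strand coordinates", {
  set.seed(3)
  q <- random_rna(21)
  host <- paste0(random_rna(50), revcomp_chr(q), random_rna(30))
  hits <- scan_mirna(make_db(m = host), one_query(q))
  minus <- hits[hits$strand == "-", ]
  expect_equal(nrow(minus), 1)
  expect_equal(minus$start, 51L)
  expect_equal(minus$end, 71L)
  expect_equal(substr(host, minus$start, minus$end), revcomp_chr(q))
})

test_that("scan matches the exhaustive edit-distance oracle", {
  set.seed(4)
  for (rep in 1:12) {
    n <- sample(300:800, 1)
    db_seq <- random_rna(n)
    q <- random_rna(21)
    if (rep %% 3 == 0) {
      at <- sample(50:(n - 80), 1)
      db_seq <- paste0(substr(db_seq, 1, at),
                       mutate_at_positions(q, sample(21, rep %% 4)),
                       substr(db_seq, at + 22, n))
    }
    for (subject in c(db_seq, revcomp_chr(db_seq))) {
      kern <- mircane:::.scan_kernel(subject, q, 3L)
      expect_equal(kern$end_edits, oracle_scan_end_edits(subject, q))
    }
  }
})

test_that("embedded catalog matures are all recovered at zero edits", {
  set.seed(5)
  mat <- read_mature_fasta(mircane_mature_path())
  pick <- mat[sample(nrow(mat), 6), ]
  hosts <- lapply(seq_len(nrow(pick)), function(i) {
    paste0(random_rna(150), pick$residues[i], random_rna(150))
  })
  db <- tibble::tibble(id = paste0("h", seq_len(nrow(pick))),
                       description = "", residues = unlist(hosts),
                       source_alphabet = "RNA")
  hits <- scan_mirna(db, pick, max_edits = 0)
  hits <- hits[hits$edit_total == 0, ]
  own <- hits[hits$db_id == paste0("h", match(hits$family, pick$family)), ]
  expect_equal(nrow(own), nrow(pick))          # every embed recovered
  expect_equal(anyDuplicated(own$db_id), 0L)   # exactly one locus each
})

test_that("overlapping candidate hits merge to the lowest edit total", {
  # a query whose 1-edit neighbourhood creates several end positions
  q <- "ACGUACGUACGUACGUACGUA"
  host <- paste0(strrep("C", 60), q, strrep("C", 60))
  hits <- scan_mirna(make_db(h = host), one_query(q), max_edits = 2)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$edit_total, 0L)
})

test_that("extract_windows clamps, resolves strand and tracks the mature", {
  set.seed(6)
  q <- random_rna(21)
  rec <- paste0(random_rna(300), q, random_rna(300))
  db <- make_db(r = rec)
  hits <- scan_mirna(db, one_query(q), max_edits = 0)
  plus <- hits[hits$strand == "+" & hits$edit_total == 0, ]
  w <- extract_windows(db, plus, flank = 300)
  expect_equal(w$window_start, 1L)
  expect_equal(w$window_end, 621L)
  expect_equal(w$mature_offset, 301L)
  expect_equal(substr(w$residues, 301, 321), q)

  w10 <- extract_windows(db, dplyr::mutate(plus, start = 11L, end = 31L),
                         flank = 300)
  expect_equal(w10$window_start, 1L)   # clamped at the record start
  expect_equal(w10$mature_offset, 11L)

  minus <- plus
  minus$strand <- "-"
  wm <- extract_windows(db, minus, flank = 50)
  expect_equal(wm$residues,
               revcomp_chr(substr(rec, plus$start - 50, plus$end + 50)))
  expect_equal(substr(wm$residues, wm$mature_offset,
                      wm$mature_offset + 20), revcomp_chr(q))
})

test_that("exclusion_screen removes matching windows and nothing else", {
  set.seed(7)
  q <- random_rna(21)
  rec <- paste0(random_rna(100), q, random_rna(100))
  db <- make_db(r = rec)
  hits <- scan_mirna(db, one_query(q), max_edits = 0)
  w <- extract_windows(db, hits[hits$strand == "+", ], flank = 50)

  expect_identical(exclusion_screen(w, NULL), w)
  expect_identical(exclusion_screen(w, db[0, ]), w)

  excl_exact <- make_db(trna1 = paste0(random_rna(20), q, random_rna(20)))
  expect_equal(suppressMessages(nrow(exclusion_screen(w, excl_exact))), 0)

  far <- mutate_at_positions(q, c(2, 6, 10, 14))  # 4 edits away
  excl_far <- make_db(trna2 = paste0(random_rna(20), far, random_rna(20)))
  expect_equal(nrow(exclusion_screen(w, excl_far, max_edits = 3)), 1)
})

test_that("scan validates its inputs", {
  q <- one_query("ACGUACGUACGUACGUACGUA")
  expect_error(scan_mirna(make_db(a = "ACGU")[0, ], q), "nrow")
  expect_error(scan_mirna(make_db(a = "ACGU"), q[0, ]), "empty")
  expect_error(scan_mirna(make_db(a = "ACGU"), q, seed_len = 25),
               "seed_len")
  expect_error(one_query("ACGU") |> scan_mirna(db = make_db(a = "ACGU")),
               "19-24")
})
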