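mat_cat <- read_mature_fasta(mircane_mature_path())
mir156 <- mat_cat$residues[mat_cat$family == "SsMIR156b-c"]

test_that("block_filter applies the 2/0/3 caps along the miRNA", {
  site <- reverse_complement(mir156)
  bf <- block_filter(mir156, site)
  expect_true(bf$pass)
  expect_equal(bf$mismatches, c(0L, 0L, 0L))

  # one mismatch opposite miRNA position 10 (block 2 allows zero)
  chars <- strsplit(site, "")[[1]]
  m <- nchar(mir156)
  k <- m - 10 + 1
  chars[k] <- setdiff(c("A", "C", "G", "U"),
                      c(chars[k], "G", "U"))[1]
  bf2 <- block_filter(mir156, paste(chars, collapse = ""))
  expect_false(bf2$pass)
  expect_equal(bf2$mismatches[2], 1L)

  # boundary load: 2 in block 1, 3 in block 3 still passes
  chars <- strsplit(site, "")[[1]]
  qc <- strsplit(mir156, "")[[1]]
  for (p in c(1, 2, 12, 13, 14)) {
    k <- m - p + 1
    chars[k] <- setdiff(c("A", "C", "G", "U"),
                        c(chartr("ACGU", "UGCA", qc[p]),
                          if (qc[p] == "G") "U", if (qc[p] == "U") "G"))[1]
  }
  bf3 <- block_filter(mir156, paste(chars, collapse = ""))
  expect_true(bf3$pass)
  expect_equal(bf3$mismatches, c(2L, 0L, 3L))
})

test_that("G:U counts as a block mismatch unless configured otherwise", {
  mirna <- "GGACAGAAGAGAGUGAGCACG"  # G at position 1
  site <- reverse_complement(mirna)
  chars <- strsplit(site, "")[[1]]
  chars[nchar(mirna)] <- "U"  # G:C becomes G:U opposite position 1
  site_gu <- paste(chars, collapse = "")
  expect_equal(block_filter(mirna, site_gu)$mismatches[1], 1L)
  expect_equal(block_filter(mirna, site_gu,
                            gu_is_match = TRUE)$mismatches[1], 0L)
})

test_that("align_duplex scores follow the 0.5/1/1.5 algebra", {
  d0 <- align_duplex(mir156, reverse_complement(mir156))
  expect_equal(d0$score_total, 0)
  expect_equal(d0$n_gu + d0$n_mismatch + d0$n_bulge, 0)

  set.seed(41)
  ts <- make_target_site(mir156, n_gu = 1, n_mm = 0, n_bulge = 0)
  site <- substr(ts$record$residues, ts$truth$site_start,
                 ts$truth$site_end)
  d1 <- align_duplex(mir156, site)
  expect_equal(d1$score_total, 0.5)
  expect_equal(d1$n_gu, 1)

  ts35 <- make_target_site(mir156, n_gu = 2, n_mm = 1, n_bulge = 1)
  site35 <- substr(ts35$record$residues, ts35$truth$site_start,
                   ts35$truth$site_end)
  d35 <- align_duplex(mir156, site35)
  expect_equal(d35$score_total, 3.5)
  expect_equal(oracle_duplex_score(mir156, site35), 3.5)

  expect_error(align_duplex(mir156, substr(site35, 1, 10)), "max_bulges")
})

test_that("align_duplex equals exhaustive enumeration on random duplexes", {
  set.seed(42)
  for (i in 1:40) {
    m <- sample(19:24, 1)
    mirna <- random_rna(m)
    delta <- sample(-2:2, 1)
    # half the cases scan a perturbed near-complement, half pure noise
    site <- if (i %% 2 == 0) random_rna(m + delta) else {
      s <- strsplit(reverse_complement(mirna), "")[[1]]
      for (p in sample(m, 3)) s[p] <- sample(c("A", "C", "G", "U"), 1)
      s <- if (delta > 0) append(s, sample(c("A", "C", "G", "U"), delta),
                                 after = sample(m, 1)) else
        if (delta < 0) s[-sample(m, -delta)] else s
      paste(s, collapse = "")
    }
    d <- align_duplex(mirna, site)
    expect_equal(d$score_total, oracle_duplex_score(mirna, site),
                 info = paste(mirna, site))
    expect_equal(d$score_total,
                 0.5 * d$n_gu + 1 * d$n_mismatch + 1.5 * d$n_bulge)
    # columns reconstruct both strands
    expect_equal(paste(d$columns$mirna_base[d$columns$mirna_base != "-"],
                       collapse = ""), mirna)
    expect_equal(paste(rev(d$columns$site_base[d$columns$site_base != "-"]),
                       collapse = ""), site)
  }
})

test_that("scan_targets accepts planted sites iff score and blocks allow", {
  set.seed(43)
  cases <- list(c(0, 0, 0), c(2, 1, 0), c(2, 1, 1), c(0, 4, 0), c(1, 2, 1))
  for (cs in cases) {
    ts <- make_target_site(mir156, cs[1], cs[2], cs[3], host_len = 250)
    hits <- scan_targets(mat_cat[mat_cat$family == "SsMIR156b-c", ],
                         ts$record)
    expect_equal(nrow(hits) > 0, ts$truth$expected_accepted,
                 info = paste(cs, collapse = "/"))
    if (nrow(hits) > 0) {
      expect_equal(hits$score[1], ts$truth$expected_score)
      expect_lte(abs(hits$site_start[1] - ts$truth$site_start), 2)
    }
  }
})

test_that("a zero threshold keeps only perfect complements", {
  set.seed(44)
  perfect <- make_target_site(mir156, 0, 0, 0)
  near <- make_target_site(mir156, 1, 0, 0, id = "near")
  cfg <- mircane_config(target_threshold = 0)
  hits <- scan_targets(mat_cat[mat_cat$family == "SsMIR156b-c", ],
                       dplyr::bind_rows(perfect$record, near$record),
                       config = cfg)
  expect_equal(hits$target_id, "synthetic_target")
  expect_equal(hits$score, 0)
})

test_that("near-identical transcripts collapse to one reported target", {
  set.seed(45)
  ts <- make_target_site(mir156, 0, 0, 0, id = "tx1")
  tx2 <- ts$record
  tx2$id <- "tx0"  # same sequence, different id
  hits <- scan_targets(mat_cat[mat_cat$family == "SsMIR156b-c", ],
                       dplyr::bind_rows(ts$record, tx2))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$n_collapsed, 2L)
  expect_equal(hits$target_id, "tx0")  # equal length: smallest id wins
})

test_that("every catalog mature finds its exact synthetic complement", {
  set.seed(46)
  tx <- tibble::tibble(
    id = paste0("tx_", mat_cat$family),
    residues = vapply(mat_cat$residues, function(m) {
      paste0(random_rna(60), reverse_complement(m), random_rna(60))
    }, character(1)),
    description = "", source_alphabet = "RNA"
  )
  hits <- scan_targets(mat_cat, tx)
  own <- hits[hits$target_id == paste0("tx_", hits$family) &
                hits$score == 0, ]
  expect_equal(sort(unique(own$family)), sort(mat_cat$family))
})
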