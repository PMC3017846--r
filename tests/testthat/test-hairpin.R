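# perfect hairpin: 20-bp inverted repeat joined by a short loop
perfect_hairpin <- function(arm_seq = "GCAGUCAGUCAGUCAGUCAG", loop = "NNNNNN") {
  paste0(arm_seq, loop, reverse_complement(arm_seq))
}

test_that("locate_star summarises a perfect duplex", {
  s <- perfect_hairpin()
  f <- fold_rna(s)
  ds <- locate_star(f, 1, 20)
  expect_equal(ds$paired_count, 20)
  expect_equal(ds$mismatch_count, 0)
  expect_equal(ds$max_consec_mm, 0)
  expect_true(ds$star_contiguous)
  expect_equal(ds$mature_arm, "5p")
  expect_equal(ds$star_start, 27)
  expect_equal(ds$star_end, 46)

  ds3 <- locate_star(f, 27, 20)
  expect_equal(ds3$mature_arm, "3p")
})

test_that("engineered mismatches are counted from the pairing map", {
  set.seed(21)
  p <- make_precursor("UGACAGAAGAGAGUGAGCAC", mismatches = 3, arm = "5p")
  f <- fold_rna(p$window$residues)
  ds <- locate_star(f, p$window$mature_offset, p$window$mature_len)
  expect_equal(ds$mismatch_count, 3)
  expect_equal(ds$paired_count, 17)
  expect_lte(ds$max_consec_mm, 2)
  expect_true(ds$star_contiguous)
  expect_equal(ds$paired_count + ds$mismatch_count, p$window$mature_len)
})

test_that("a mature spanning the terminal loop is flagged", {
  ko <- make_knockout("c2")
  f <- fold_rna(ko$window$residues)
  ds <- locate_star(f, ko$window$mature_offset, ko$window$mature_len)
  expect_equal(ds$mature_arm, "spans_loop")
  rep <- check_hairpin(ko$window, f)
  expect_false(rep$c2)
  expect_equal(rep$failed_criteria, "c2")
})

test_that("a construction passing all nine criteria is accepted", {
  set.seed(22)
  p <- make_precursor("UGACAGAAGAGAGUGAGCAC", mismatches = 3, arm = "5p")
  f <- fold_rna(p$window$residues)
  rep <- check_hairpin(p$window, f)
  expect_equal(rep$verdict, "accept")
  expect_true(all(unlist(rep[paste0("c", 1:9)])))
  expect_gt(rep$mfei, 0.65)
  expect_true(rep$gc_percent >= 30 && rep$gc_percent <= 70)
  expect_gte(rep$trimmed_len, 60)
})

test_that("a perfect duplex fails only the >=1 mismatch rule", {
  set.seed(23)
  p <- make_precursor("UGACAGAAGAGAGUGAGCAC", mismatches = 0, arm = "5p")
  rep <- check_hairpin(p$window, fold_rna(p$window$residues))
  expect_equal(rep$failed_criteria, "c4")
})

test_that("short stem-loops fail the 60-nt minimum alone", {
  set.seed(24)
  p <- make_precursor("UGACAGAAGAGAGUGAGCAC", mismatches = 2, arm = "5p",
                      loop_len = 3, stem_ext = 2)
  rep <- check_hairpin(p$window, fold_rna(p$window$residues))
  expect_lt(rep$trimmed_len, 60)
  expect_equal(rep$failed_criteria, "c9")
})

test_that("the expected-arm criterion uses catalog metadata", {
  set.seed(25)
  p <- make_precursor("UGACAGAAGAGAGUGAGCAC", mismatches = 3, arm = "5p")
  f <- fold_rna(p$window$residues)
  ok <- check_hairpin(p$window, f,
                      query = tibble::tibble(family = "x",
                                             expected_arm = "5p"))
  expect_equal(ok$verdict, "accept")
  bad <- check_hairpin(p$window, f,
                       query = tibble::tibble(family = "x",
                                              expected_arm = "3p"))
  expect_equal(bad$failed_criteria, "c3")
})

test_that("relaxing thresholds never flips accept to reject", {
  set.seed(26)
  relaxed <- mircane_config(
    mfei_min = 0.3, gc_range = c(10, 90),
    duplex_mismatch_range = c(0L, 10L), max_consec_mm = 5L,
    min_closing_pairs = 0L, min_stemloop = 30L
  )
  cases <- list(
    make_precursor("UGACAGAAGAGAGUGAGCAC", mismatches = 3, arm = "5p"),
    make_precursor("UGACAGAAGAGAGUGAGCAC", mismatches = 0, arm = "5p"),
    make_precursor("UUUGGAUUGAAGGGAGCUCUG", mismatches = 2, arm = "3p"),
    make_precursor("UGACAGAAGAGAGUGAGCAC", mismatches = 2, arm = "5p",
                   loop_len = 3, stem_ext = 2)
  )
  for (p in cases) {
    f <- fold_rna(p$window$residues)
    strict <- check_hairpin(p$window, f)$verdict
    loose <- check_hairpin(p$window, f, config = relaxed)$verdict
    if (strict == "accept") expect_equal(loose, "accept")
  }
})

test_that("trimmed stem-loop statistics match hand computation", {
  # fixed construction: 4-bp closing stem, 8-bp duplex, loop of 5
  arm <- "GCGAUCGA"
  s <- paste0("AAAAA", "CCCC", arm, "CC", "NNNNN", "GG",
              reverse_complement(arm), "GGGG", "AAAAA")
  f <- fold_rna(s)
  w <- tibble::tibble(window_id = "t", db_id = "t", family = NA_character_,
                      residues = s, mature_offset = 10L, mature_len = 8L)
  rep <- check_hairpin(w, f)
  hairpin_len <- 4 + 8 + 2 + 5 + 2 + 8 + 4
  expect_equal(rep$trimmed_len, hairpin_len)
  expect_equal(rep$trimmed_start, 6L)
  hairpin <- substr(s, 6, 6 + hairpin_len - 1)
  expect_equal(rep$gc_percent, gc_percent(hairpin))
  # energy: 4 stem C:G + 2 adapter C:G + duplex (5 GC + 3 AU)
  expect_equal(rep$mfe_kcal, -(6 * 3 + 5 * 3 + 3 * 2))
  expect_equal(rep$amfe, amfe(rep$mfe_kcal, hairpin_len))
  expect_equal(rep$mfei, mfei(rep$mfe_kcal, hairpin_len, rep$gc_percent))
})
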