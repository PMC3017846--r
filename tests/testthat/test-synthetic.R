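test_that("constructed precursors fold exactly as designed", {
  set.seed(51)
  mat <- read_mature_fasta(mircane_mature_path())
  for (i in sample(nrow(mat), 6)) {
    arm <- mat$expected_arm[i]
    p <- make_precursor(mat$residues[i], mismatches = 3, arm = arm)
    rep <- check_hairpin(p$window, fold_rna(p$window$residues))
    expect_equal(rep$verdict, p$truth$expected_verdict, info = mat$family[i])
    expect_equal(rep$mismatch_count, 3, info = mat$family[i])
    expect_equal(rep$mature_arm, arm, info = mat$family[i])
  }
})

test_that("truth records predict check() outcomes for defective builds", {
  set.seed(52)
  builds <- list(
    make_precursor("UGACAGAAGAGAGUGAGCAC", mismatches = 0, arm = "5p"),
    make_precursor("GACGACGACGACGACGACGAC", mismatches = 7, arm = "5p"),
    make_precursor("GCGAUAUAAUAUAUCGCAUGC", mismatches = 1, arm = "5p",
                   star_bulge = TRUE),
    make_precursor("GCUGCGAAAGGUGCAUGCAUG", mismatches = 3, arm = "5p",
                   run_len = 3),
    make_precursor("UGACAGAAGAGAGUGAGCAC", mismatches = 2, arm = "5p",
                   loop_len = 3, stem_ext = 2)
  )
  for (p in builds) {
    rep <- check_hairpin(p$window, fold_rna(p$window$residues))
    expect_equal(rep$verdict, p$truth$expected_verdict)
    expect_equal(rep$failed_criteria, p$truth$expected_failed)
  }
})

test_that("each hairpin criterion has an exact single-criterion knockout", {
  set.seed(53)
  for (crit in paste0("c", 1:9)) {
    ko <- make_knockout(crit)
    rep <- check_hairpin(ko$window, fold_rna(ko$window$residues), ko$query)
    expect_equal(rep$verdict, "reject", info = crit)
    expect_equal(rep$failed_criteria, crit, info = crit)
  }
})

test_that("infeasible constructions fail fast with an explanation", {
  expect_error(make_precursor("UGACAGAAGAGAGUGAGCAC", loop_len = 2),
               "loop_len")
  expect_error(
    make_precursor("UUUGGAUUGAAGGGAGCUCUG", mismatches = 6, arm = "3p"),
    "rigidly"
  )
  # miR437's UU tail lets a bulge realign off the site end
  expect_error(
    make_target_site("AAAGUUAGAGAAGUUUGACUU", n_bulge = 1),
    "realign|migrate"
  )
  expect_error(
    make_target_site("UGACAGAAGAGAGUGAGCAC", n_gu = 5),
    "block 2"
  )
})

test_that("decoy generation is reproducible and categorised", {
  set.seed(60)
  d1 <- make_decoys(20)
  set.seed(60)
  d2 <- make_decoys(20)
  expect_identical(d1, d2)
  expect_equal(nrow(d1$records), 20)
  expect_setequal(unique(d1$truth$category),
                  c("random", "low_gc", "high_gc", "short_hairpin", "mite"))
  expect_true(all(d1$truth$expected_verdict == "reject"))
  # MITE decoys end in a perfect terminal inverted repeat
  mite <- d1$records$residues[d1$truth$category == "mite"][1]
  n <- nchar(mite)
  expect_equal(substr(mite, 1, 30),
               reverse_complement(substr(mite, n - 29, n)))
})

test_that("the synthetic database is byte-identical under a fixed seed", {
  mat <- read_mature_fasta(mircane_mature_path())
  s1 <- synth_precursor_db(mat, n_embeds = 4, n_decoys = 10, seed = 99)
  s2 <- synth_precursor_db(mat, n_embeds = 4, n_decoys = 10, seed = 99)
  expect_identical(s1, s2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  save_synth(s1, d1)
  save_synth(s2, d2)
  expect_identical(readLines(file.path(d1, "database.fasta")),
                   readLines(file.path(d2, "database.fasta")))
  expect_identical(readLines(file.path(d1, "truth.tsv")),
                   readLines(file.path(d2, "truth.tsv")))
})
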