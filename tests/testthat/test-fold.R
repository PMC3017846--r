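test_that("fold_rna reproduces hand-checkable structures", {
  f <- fold_rna("GGGGAAAACCCC")
  expect_equal(f$dot_bracket, "((((....))))")
  expect_equal(f$mfe_kcal, -12)
  expect_equal(sum(f$pairing > 0) / 2, 4)

  f0 <- fold_rna("AAAAAAA")
  expect_equal(f0$mfe_kcal, 0)
  expect_equal(f0$dot_bracket, ".......")

  expect_error(fold_rna("ACG"), "too short")
})

test_that("fold_rna equals brute-force enumeration on random sequences", {
  set.seed(11)
  for (i in 1:40) {
    s <- random_rna(sample(10:26, 1))
    f <- fold_rna(s)
    expect_equal(f$mfe_kcal, oracle_fold_energy(s), info = s)
  }
})

test_that("folding is deterministic and energy is sequence-intrinsic", {
  set.seed(12)
  s <- random_rna(40)
  f1 <- fold_rna(s)
  f2 <- fold_rna(s)
  expect_identical(f1$pairing, f2$pairing)
  expect_identical(f1$mfe_kcal, f2$mfe_kcal)
})

test_that("fold structures satisfy the structural invariants", {
  set.seed(13)
  for (i in 1:20) {
    s <- random_rna(sample(15:60, 1))
    f <- fold_rna(s)
    p <- f$pairing
    idx <- which(p > 0)
    expect_identical(p[p[idx]], idx)            # involution
    expect_true(all(abs(p[idx] - idx) >= 4))    # min_loop = 3
    chars <- strsplit(s, "")[[1]]
    pairs <- paste0(pmin(chars[idx], chars[p[idx]]),
                    pmax(chars[idx], chars[p[idx]]))
    expect_true(all(pairs %in% c("CG", "AU", "GU")))
    expect_equal(nchar(f$dot_bracket), nchar(s))
  }
})

test_that("Vienna files parse, round-trip, and carry energies", {
  v <- withr::local_tempfile(fileext = ".vienna")
  writeLines(c("GGGAAACCC", "(((...))) (-7.4)"), v)
  f <- parse_vienna(v)
  expect_equal(sum(f$pairing > 0) / 2, 3)
  expect_equal(f$mfe_kcal, -7.4)
  expect_equal(f$source, "vienna_file")

  out <- withr::local_tempfile(fileext = ".vienna")
  write_vienna(f, out, id = "s1")
  f2 <- parse_vienna(out)
  expect_equal(f2$pairing, f$pairing)
  expect_equal(f2$mfe_kcal, f$mfe_kcal)

  writeLines(c("GGGAAACCC", "(((...)))"), v)
  expect_message(parse_vienna(v), "no energy")

  writeLines(c("GGGAAACCC", "(((...))"), v)
  expect_error(parse_vienna(v), "length")
  writeLines(c("GGGAAACCC", "((....)))"), v)
  expect_error(parse_vienna(v), "unbalanced")
  writeLines(c("GGGAAACCC", "[[[...]]]"), v)
  expect_error(parse_vienna(v), "unsupported")
})

test_that("CT files parse and asymmetry is rejected with a line number", {
  ct <- withr::local_tempfile(fileext = ".ct")
  rows <- c(
    "9 dG = -7.4 hairpin",
    "1 G 0 2 9 1", "2 G 1 3 8 2", "3 G 2 4 7 3",
    "4 A 3 5 0 4", "5 A 4 6 0 5", "6 A 5 7 0 6",
    "7 C 6 8 3 7", "8 C 7 9 2 8", "9 C 8 0 1 9"
  )
  writeLines(rows, ct)
  f <- parse_ct(ct)
  expect_equal(f$residues, "GGGAAACCC")
  expect_equal(f$mfe_kcal, -7.4)
  expect_equal(f$dot_bracket, "(((...)))")

  rows[8] <- "7 C 6 8 2 7"  # claims 7-2 but row 2 pairs 8
  writeLines(rows, ct)
  expect_error(parse_ct(ct), "asymmetry.*line \\d+")
})

test_that("AMFE and MFEI follow their defining formulas", {
  expect_equal(amfe(-47, 100), 47)
  expect_equal(mfei(-47, 100, 50), 0.94)
  expect_equal(mfei(-30, 100, 30), 1)
  expect_equal(amfe(0, 50), 0)
  expect_equal(mfei(0, 50, 40), 0)
  expect_error(amfe(5, 100), "<= 0")
  expect_error(mfei(-10, 100, 0), "undefined")
})
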