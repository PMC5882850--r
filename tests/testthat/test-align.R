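test_that("identity alignments score the matrix diagonal with no gaps", {
  m <- substitution_matrix()
  al <- global_align("ACDE", "ACDE", m)
  expect_equal(al$score, 24) # 4 + 9 + 6 + 5 on the BLOSUM62 diagonal
  expect_identical(al$aligned_a, "ACDE")
  expect_identical(al$aligned_b, "ACDE")
  for (s in 1:10) {
    x <- random_protein(sample(5:40, 1), seed = 100 + s)
    al <- global_align(x, x, m)
    expect_equal(al$score, sum(diag(m)[strsplit(x, "")[[1]]]))
    expect_false(grepl("-", al$aligned_a, fixed = TRUE))
  }
})

test_that("emitted alignments recover the inputs and rescore identically", {
  m <- substitution_matrix()
  for (s in 1:20) {
    a <- random_protein(sample(1:60, 1), seed = 200 + s)
    b <- random_protein(sample(1:60, 1), seed = 300 + s)
    al <- global_align(a, b, m)
    expect_identical(gsub("-", "", al$aligned_a, fixed = TRUE), a)
    expect_identical(gsub("-", "", al$aligned_b, fixed = TRUE), b)
    expect_equal(score_alignment(al$aligned_a, al$aligned_b, m), al$score)
  }
})

test_that("DP score equals exhaustive brute force on small pairs", {
  m4 <- test_matrix_4()
  withr::with_seed(7, {
    for (rep in 1:60) {
      la <- sample(1:6, 1)
      lb <- sample(1:6, 1)
      a <- paste(sample(rownames(m4), la, replace = TRUE), collapse = "")
      b <- paste(sample(rownames(m4), lb, replace = TRUE), collapse = "")
      open <- sample(2:8, 1)
      ext <- sample(1:3, 1)
      dp <- global_align(a, b, m4, open, ext)$score
      expect_equal(dp, brute_force_align(a, b, m4, open, ext),
                   info = paste(a, b, open, ext))
    }
  })
  # the small published-style example: one residue against four
  m <- substitution_matrix()
  al <- global_align("A", "AAAA", m, 10, 1)
  expect_equal(al$score, brute_force_align("A", "AAAA", m, 10, 1))
})

test_that("alignment score is symmetric in its arguments", {
  m <- substitution_matrix()
  for (s in 1:40) {
    a <- random_protein(sample(1:30, 1), seed = 400 + s)
    b <- random_protein(sample(1:30, 1), seed = 500 + s)
    expect_equal(global_align(a, b, m)$score, global_align(b, a, m)$score)
  }
})

test_that("an isolated insertion costs exactly the affine gap penalty", {
  m <- substitution_matrix()
  x <- "ACDEFGHIKLMNPQRSTVWY"
  for (L in c(1, 3, 5)) {
    y <- paste0(substr(x, 1, 10), strrep("W", 0), # no-op, keep x structure
                paste(rep("P", L), collapse = ""), substr(x, 11, 20))
    base <- global_align(x, x, m)$score
    with_ins <- global_align(x, y, m, 10, 1)$score
    expect_equal(with_ins, base - (10 + (L - 1) * 1))
  }
})

test_that("empty input is rejected", {
  expect_error(global_align("", "ACD"), class = "optoxr_precondition_error")
  expect_error(star_msa("ACD", character(0)), class = "optoxr_precondition_error")
})

test_that("star MSA of identical sequences has no gap columns", {
  ref <- random_protein(50, seed = 9)
  msa <- star_msa(ref, rep(ref, 5))
  expect_equal(nrow(msa$rows), 6L)
  expect_true(all(msa$rows$aligned == ref))
})

test_that("star MSA with one partner equals the pairwise alignment", {
  m <- substitution_matrix()
  a <- random_protein(40, seed = 11)
  b <- random_protein(35, seed = 12)
  al <- global_align(a, b, m)
  msa <- star_msa(a, b, m)
  expect_identical(msa$rows$aligned[1], al$aligned_a)
  expect_identical(msa$rows$aligned[2], al$aligned_b)
})

test_that("indel-free families align gaplessly and map one-to-one", {
  truth <- make_7tm(7)
  fam <- make_family(truth, n = 6, sub_rate = 0.05, seed = 7)
  msa <- star_msa(truth$protein, fam)
  expect_true(all(nchar(msa$rows$aligned) == nchar(truth$protein)))
  expect_false(any(grepl("-", msa$rows$aligned, fixed = TRUE)))
  for (pos in c(0L, 10L, nchar(truth$protein) - 1L)) {
    expect_identical(map_position(msa, 2L, pos), pos)
  }
})

test_that("map_position handles reference gaps and bounds", {
  # hand-built case: partner has an N-terminal extension, so the reference
  # row starts with gap columns
  ref <- "CDEFGHIKLM"
  other <- paste0("WWWW", ref)
  msa <- star_msa(ref, other)
  expect_true(startsWith(msa$rows$aligned[1], "-"))
  # the partner's position 4 is the reference's position 0
  expect_identical(map_position(msa, 2L, 4L), 0L)
  # partner positions inside the extension sit in reference-gap columns
  expect_true(is.na(map_position(msa, 2L, 0L)))
  expect_error(map_position(msa, 5L, 0L), class = "optoxr_bounds_error")
  expect_error(map_position(msa, 2L, 99L), class = "optoxr_bounds_error")
})
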