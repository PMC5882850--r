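test_that("primer properties follow the Wallace and GC rules", {
  p <- primer_properties("AAAA")
  expect_equal(p$length, 4L)
  expect_equal(p$gc, 0)
  expect_equal(p$tm, 8) # 2*(A+T)
  p <- primer_properties("GGGG")
  expect_equal(p$gc, 1)
  expect_equal(p$tm, 16)
  # the qPCR assay's forward primer: 20-mer, 11 G+C by direct tally
  fwd <- "TGACAACGAGTACACCACGG"
  tally <- sum(strsplit(fwd, "")[[1]] %in% c("G", "C"))
  expect_equal(tally, 11L)
  p <- primer_properties(fwd)
  expect_equal(p$length, 20L)
  expect_equal(p$gc, 11 / 20)
  expect_equal(p$tm, 64.9 + 41 * (11 - 16.4) / 20)
})

test_that("in-silico PCR finds the single constructed product", {
  tp <- make_pcr_template()
  hits <- in_silico_pcr(tp$template, tp$fwd, tp$rev)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$product_length, nchar(tp$fwd) + 160L + nchar(tp$rev))
  expect_equal(hits$start, 100L)
  # deleting the reverse site kills the product
  expect_equal(nrow(in_silico_pcr(tp$no_rev, tp$fwd, tp$rev)), 0L)
})

test_that("in-silico PCR is strand symmetric", {
  tp <- make_pcr_template()
  fwd_hits <- in_silico_pcr(tp$template, tp$fwd, tp$rev)
  rc_hits <- in_silico_pcr(revcomp(tp$template), tp$fwd, tp$rev)
  expect_equal(nrow(rc_hits), 1L)
  expect_equal(rc_hits$product_length, fwd_hits$product_length)
  # coordinates mirror across the template
  expect_equal(rc_hits$start, nchar(tp$template) - fwd_hits$end)
})

test_that("mismatch tolerance respects the exact 3' anchor", {
  tp <- make_pcr_template()
  # one mismatch in the forward primer's 5' half is tolerated...
  fwd_mut <- tp$fwd
  substr(fwd_mut, 2, 2) <- if (substr(fwd_mut, 2, 2) == "A") "C" else "A"
  expect_equal(nrow(in_silico_pcr(tp$template, fwd_mut, tp$rev)), 1L)
  # ...but any 3'-terminal mismatch aborts the match
  fwd_3p <- tp$fwd
  substr(fwd_3p, 20, 20) <- "A" # was G
  expect_equal(nrow(in_silico_pcr(tp$template, fwd_3p, tp$rev)), 0L)
  # and more than max_mismatch kills it
  fwd_many <- tp$fwd
  substr(fwd_many, 1, 3) <- "CCC"
  expect_equal(nrow(in_silico_pcr(tp$template, fwd_many, tp$rev,
                                  max_mismatch = 2)), 0L)
})

test_that("zero-mismatch mode agrees with a naive quadratic scan", {
  for (s in 1:12) {
    tp <- make_pcr_template(seed = 700 + s, inter = sample(50:400, 1))
    got <- in_silico_pcr(tp$template, tp$fwd, tp$rev, max_mismatch = 0)
    want <- naive_pcr_scan(tp$template, tp$fwd, tp$rev, 2000)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("designed junction pairs amplify the chimera and not the parents", {
  for (seed in c(3, 8)) {
    scen <- make_parent_chimera_set(seed)
    j <- chimera_junctions(scen$design)
    il3_junction <- 3L * j$junction[j$right_label == "IL3"]
    parents <- c(backbone = scen$backbone_cds, target = scen$target_cds)
    pair <- design_junction_primers(scen$chimera_cds, il3_junction, parents)
    expect_identical(pair$specificity, "specific")
    chim <- in_silico_pcr(scen$chimera_cds, pair$forward, pair$reverse)
    expect_gte(nrow(chim), 1L)
    for (p in parents) {
      expect_equal(nrow(in_silico_pcr(p, pair$forward, pair$reverse)), 0L)
    }
    # the amplicon strictly contains the junction
    expect_lt(chim$start[1], il3_junction)
    expect_gt(chim$end[1], il3_junction)
  }
})

test_that("degenerate junctions and missing parents are handled", {
  scen <- make_parent_chimera_set(3)
  expect_error(design_junction_primers(scen$chimera_cds, 0L, character(0)),
               class = "optoxr_precondition_error")
  j <- chimera_junctions(scen$design)
  pair <- design_junction_primers(scen$chimera_cds, 3L * j$junction[1],
                                  character(0))
  expect_identical(pair$specificity, "unscreened")
})

test_that("primer pairs export as three-column tab text", {
  scen <- make_parent_chimera_set(3)
  j <- chimera_junctions(scen$design)
  pair <- design_junction_primers(scen$chimera_cds, 3L * j$junction[1],
                                  character(0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_primers(pair, path, "jx")
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_identical(back$forward, pair$forward)
  expect_identical(back$reverse, pair$reverse)
})
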