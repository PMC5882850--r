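test_that("codon table fractions sum to one per amino acid", {
  tab <- codon_usage()
  sums <- tapply(tab$fraction, tab$aa, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(AA_ALPHABET %in% tab$aa))
})

test_that("back-translation round-trips in both modes", {
  tab <- codon_usage()
  expect_identical(back_translate("M", tab), "ATG")
  expect_identical(back_translate("W", tab), "TGG")
  expect_identical(back_translate("M", tab, "sampled", seed = 5), "ATG")
  p <- random_protein(120, seed = 2)
  det <- back_translate(p, tab)
  expect_identical(as.character(translate_dna(det)), p)
  for (s in 1:10) {
    q <- random_protein(80, seed = 600 + s)
    expect_identical(as.character(translate_dna(back_translate(q, tab))), q)
    expect_identical(
      as.character(translate_dna(back_translate(q, tab, "sampled", seed = s))), q
    )
  }
  # sampled mode is seed-deterministic
  expect_identical(back_translate(p, tab, "sampled", 3),
                   back_translate(p, tab, "sampled", 3))
})

test_that("restriction scanning finds sites on both strands", {
  hits <- scan_sites("AAGGTACCAA", restriction_enzymes("KpnI"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 2L)
  # the fusion linker carries a NotI core at its first base
  hits <- scan_sites("GCGGCCGCC", restriction_enzymes("NotI"))
  expect_equal(hits$position, 0L)
  # a non-palindromic pattern is found via its reverse complement too
  asym <- tibble::tibble(name = "Asym", site = "GGGGAT")
  hits <- scan_sites(paste0("AA", revcomp("GGGGAT"), "AA"), asym)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$strand, "-")
  # screened-by-construction random sequence is clean
  x <- withr::with_seed(4, {
    repeat {
      cand <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                    collapse = "")
      if (!grepl("GGTACC", cand) && !grepl("GGATCC", cand)) break
    }
    cand
  })
  expect_equal(nrow(scan_sites(x)), 0L)
})

test_that("site removal recodes synonymously until clean", {
  tab <- codon_usage()
  out <- remove_sites("ATGGGTACCTAA", 0L, restriction_enzymes("KpnI"), tab)
  expect_equal(nrow(scan_sites(out, restriction_enzymes("KpnI"))), 0L)
  expect_identical(as.character(translate_dna(out)),
                   as.character(translate_dna("ATGGGTACCTAA")))
  # zero hits: fixed point
  clean <- "ATGAAACTG"
  expect_identical(remove_sites(clean, 0L, restriction_enzymes("KpnI"), tab), clean)
  # protected regions are exempt
  orf_linker <- paste0("ATGAAA", "GCGGCCGCC", "CTG")
  kept <- remove_sites(orf_linker, 0L, restriction_enzymes("NotI"), tab,
                       protected = list(c(6L, 15L)))
  expect_identical(kept, orf_linker)
})

test_that("planted sites are removed with translation preserved", {
  tab <- codon_usage()
  enz <- restriction_enzymes(c("KpnI", "BamHI"))
  for (s in 1:15) {
    orf <- plant_sites_orf(seed = s, n_sites = sample(1:5, 1))
    before <- as.character(translate_dna(orf))
    out <- remove_sites(orf, 0L, enz, tab)
    expect_equal(nrow(scan_sites(out, enz)), 0L)
    expect_identical(as.character(translate_dna(out)), before)
  }
})

test_that("direct fusion deletes the reporter start and keeps one frame", {
  reporter <- paste0("ATGGTG", back_translate(random_protein(30, seed = 8)))
  frag <- fuse_reporter("ATGAAA", reporter)
  seq <- paste(frag$seq, collapse = "")
  expect_true(startsWith(seq, paste0("ATGAAA", "GCGGCCGCC", "GTG")))
  tr <- translate_dna(seq)
  expect_true(attr(tr, "stopped"))
  expect_identical(
    as.character(tr),
    paste0("MK", "AAA", "V", random_protein(30, seed = 8))
  )
  expect_error(fuse_reporter("ATGAAA", reporter, linker = "GCGG"),
               class = "optoxr_frame_error")
  expect_error(fuse_reporter("ATGAAA", paste0("CCC", reporter)),
               class = "optoxr_input_error")
})

test_that("terminal stops are stripped before fusion with a notice", {
  reporter <- make_reporter(21)
  expect_message(frag <- fuse_reporter("ATGAAATAA", reporter), "stop codon")
  expect_identical(frag$seq[frag$role == "orf"], "ATGAAA")
})

test_that("the bicistronic style keeps the reporter initiator", {
  t2a <- back_translate(random_protein(18, seed = 13))
  reporter <- make_reporter(22)
  frag <- fuse_reporter("ATGAAA", reporter, style = "t2a_bicistronic", t2a = t2a)
  expect_identical(frag$role, c("orf", "t2a", "reporter", "stop"))
  expect_true(startsWith(frag$seq[frag$role == "reporter"], "ATG"))
  expect_error(fuse_reporter("ATGAAA", reporter, style = "t2a_bicistronic"),
               class = "optoxr_input_error")
})

test_that("cassettes are flanked by the cloning sites and audit the insert", {
  scen <- make_parent_chimera_set(2)
  tab <- codon_usage()
  cds <- remove_sites(scen$chimera_cds, 0L,
                      restriction_enzymes(c("KpnI", "BamHI")), tab)
  frag <- suppressMessages(fuse_reporter(cds, make_reporter(23)))
  cass <- build_cassette("hSyn", frag)
  full <- attr(cass, "seq")
  expect_true(startsWith(full, "GGTACC"))
  expect_true(endsWith(full, "GGATCC"))
  # frame invariant: chimera + Ala-Ala-Ala linker + reporter-minus-Met
  cds_part <- paste(cass$seq[cass$role %in% c("orf", "linker", "reporter", "stop")],
                    collapse = "")
  tr <- translate_dna(cds_part)
  n_rep_aa <- (nchar(make_reporter(23)) - 6) / 3 # minus ATG and stop
  expect_equal(nchar(tr), nchar(chimera_protein(scen$design)) + 3 + n_rep_aa)
  # an insert with an internal cloning site is refused, naming the position
  dirty <- fuse_reporter("ATGGGTACCAAA", make_reporter(24))
  expect_error(build_cassette("hSyn", dirty), class = "optoxr_cassette_error")
})

test_that("cassette GenBank round-trip preserves the element table", {
  scen <- make_parent_chimera_set(2)
  tab <- codon_usage()
  cds <- remove_sites(scen$chimera_cds, 0L,
                      restriction_enzymes(c("KpnI", "BamHI")), tab)
  frag <- suppressMessages(fuse_reporter(cds, make_reporter(23)))
  cass <- build_cassette("hSyn", frag)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(cassette_record(cass), path)
  back <- read_genbank(path)
  expect_identical(back$seq, attr(cass, "seq"))
  expect_identical(back$features$label, cass$name)
  expect_equal(back$features$start, cass$start)
  expect_equal(back$features$end, cass$end)
})

test_that("identical inputs give byte-identical cassettes", {
  scen1 <- make_parent_chimera_set(14)
  scen2 <- make_parent_chimera_set(14)
  expect_identical(scen1$chimera_cds, scen2$chimera_cds)
  f1 <- suppressMessages(fuse_reporter(scen1$chimera_cds, make_reporter(3)))
  f2 <- suppressMessages(fuse_reporter(scen2$chimera_cds, make_reporter(3)))
  expect_identical(paste(f1$seq, collapse = ""), paste(f2$seq, collapse = ""))
})
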