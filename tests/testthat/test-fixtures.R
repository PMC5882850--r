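test_that("generators are pure functions of seed and arguments", {
  expect_identical(make_7tm(3), make_7tm(3))
  t1 <- make_7tm(3)
  expect_identical(make_family(t1, 6, 0.05, seed = 7),
                   make_family(t1, 6, 0.05, seed = 7))
  expect_identical(make_qpcr_table(5), make_qpcr_table(5))
  s1 <- make_parent_chimera_set(9)
  s2 <- make_parent_chimera_set(9)
  expect_identical(s1$chimera_cds, s2$chimera_cds)
  expect_identical(chimera_protein(s1$design), chimera_protein(s2$design))
})

test_that("generated truths satisfy the topology invariants", {
  for (s in c(1, 13, 77)) {
    truth <- make_7tm(s)
    expect_silent(validate_topology_map(truth$map))
    expect_equal(sum(grepl("^TM", truth$map$label)), 7L)
    expect_equal(sum(grepl("^IL", truth$map$label)), 3L)
    expect_equal(sum(grepl("^EL", truth$map$label)), 3L)
    # segment alphabets respect the generator contract
    for (k in seq_len(15)) {
      seg <- substr(truth$protein, truth$map$start[k] + 1, truth$map$end[k])
      chars <- unique(strsplit(seg, "")[[1]])
      if (grepl("^TM", truth$map$label[k])) {
        expect_true(all(chars %in% c("A", "I", "L", "V", "F", "M", "W", "C")))
      } else {
        expect_true(all(chars %in% c("D", "E", "K", "R", "S", "T", "N", "Q",
                                     "G", "P", "H", "Y")))
      }
    }
    # every generated helix clears the calling threshold with margin:
    # each within-helix window (width up to 19) averages at least 2.0
    kd <- kyte_doolittle()
    tm <- truth$map[grepl("^TM", truth$map$label), ]
    for (k in seq_len(7)) {
      v <- kd[strsplit(substr(truth$protein, tm$start[k] + 1, tm$end[k]),
                       "")[[1]]]
      w <- min(19L, length(v))
      wins <- vapply(seq_len(length(v) - w + 1L), function(i) {
        mean(v[i:(i + w - 1L)])
      }, numeric(1))
      expect_gte(min(wins), 2.0)
    }
  }
  expect_error(make_7tm(1, tm_len_range = c(10, 20)),
               class = "optoxr_parameter_error")
})

test_that("family substitution counts match the binomial model", {
  truth <- make_7tm(7)
  n <- nchar(truth$protein)
  fam <- make_family(truth, n = 20, sub_rate = 0.05, seed = 7)
  count_subs <- function(h) {
    sum(strsplit(h, "")[[1]] != strsplit(truth$protein, "")[[1]])
  }
  total <- sum(vapply(fam, count_subs, numeric(1)))
  bounds <- stats::qbinom(c(0.005, 0.995), size = 20L * n, prob = 0.05)
  expect_gte(total, bounds[1])
  expect_lte(total, bounds[2])
  # rate 0 gives exact copies
  expect_true(all(make_family(truth, 3, 0, seed = 1) == truth$protein))
  expect_error(make_family(truth, 3, 0.5, seed = 1),
               class = "optoxr_parameter_error")
})

test_that("class-preserving families still call seven helices", {
  truth <- make_7tm(7)
  fam <- make_family(truth, n = 4, sub_rate = 0.05, seed = 7)
  for (h in fam) {
    tm <- call_tm_segments(hydropathy_profile(h))
    expect_equal(nrow(tm), 7L)
  }
})

test_that("scenario CDSs are mutually consistent with the design", {
  scen <- make_parent_chimera_set(5)
  expect_identical(as.character(translate_dna(scen$chimera_cds)),
                   chimera_protein(scen$design))
  expect_identical(as.character(translate_dna(scen$backbone_cds)),
                   scen$backbone$protein)
  # deterministic codon choice: backbone-sourced codons agree between
  # chimera CDS and backbone CDS over the Nt..TM1 stretch
  tm1_end_aa <- scen$backbone$map$end[scen$backbone$map$label == "TM1"]
  expect_identical(substr(scen$chimera_cds, 1, 3 * tm1_end_aa),
                   substr(scen$backbone_cds, 1, 3 * tm1_end_aa))
})

test_that("simulated scenario directories carry all advertised files", {
  dir <- withr::local_tempdir()
  simulate_scenario(21, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "proteins.fasta", "backbone.fasta", "target.fasta", "family.fasta",
    "backbone_truth.bed", "target_truth.bed", "cds.fasta",
    "reporter_synthetic.fasta", "qpcr.csv", "manifest.json"
  )))))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 21L)
  cds <- read_fasta(file.path(dir, "cds.fasta"), "dna")
  expect_equal(nrow(cds), 3L)
})
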