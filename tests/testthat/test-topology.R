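test_that("hydropathy profile averages the KD scale over centred windows", {
  p30 <- strrep("I", 30)
  prof <- hydropathy_profile(p30, 9)
  expect_equal(prof$hydropathy[15], 4.5) # KD(Ile)
  prof_r <- hydropathy_profile(strrep("R", 30), 9)
  expect_equal(prof_r$hydropathy[15], -4.5) # KD(Arg)
  # alternating I/R: a 9-window holds 5 of the centre residue and 4 of the
  # other, so the interior mean is +-0.5 depending on the centre
  alt <- paste(rep(c("I", "R"), 15), collapse = "")
  prof_a <- hydropathy_profile(alt, 9)
  expect_equal(prof_a$hydropathy[15], (5 * 4.5 + 4 * -4.5) / 9)
  expect_equal(prof_a$hydropathy[16], (5 * -4.5 + 4 * 4.5) / 9)
  # truncated edge windows average only the residues present
  expect_equal(prof$hydropathy[1], 4.5)
  expect_equal(length(prof$hydropathy), 30L)
  expect_error(hydropathy_profile(p30, 8), class = "optoxr_parameter_error")
  expect_error(hydropathy_profile(p30, 33), class = "optoxr_parameter_error")
})

test_that("TM calling finds forced blocks and nothing in hydrophilic chains", {
  none <- call_tm_segments(hydropathy_profile(strrep("R", 200)))
  expect_equal(nrow(none), 0L)
  one <- paste0(strrep("R", 40), strrep("I", 21), strrep("R", 40))
  tm <- call_tm_segments(hydropathy_profile(one))
  expect_equal(nrow(tm), 1L)
  expect_equal(tm$start, 40L)
  expect_equal(tm$end, 61L)
})

test_that("TM boundaries are recovered within two residues on fixtures", {
  n_ok <- 0L; n_all <- 0L; all7 <- TRUE
  for (s in 1:20) {
    truth <- make_7tm(1000 + s)
    tm <- call_tm_segments(hydropathy_profile(truth$protein))
    if (nrow(tm) != 7) { all7 <- FALSE; next }
    tm_truth <- truth$map[grepl("^TM", truth$map$label), ]
    errs <- c(abs(tm$start - tm_truth$start), abs(tm$end - tm_truth$end))
    n_ok <- n_ok + sum(errs <= 2)
    n_all <- n_all + length(errs)
  }
  expect_true(all7)
  expect_gte(n_ok / n_all, 0.95)
})

test_that("partition labels alternate by orientation and cover the protein", {
  truth <- make_7tm(3)
  tm <- truth$map[grepl("^TM", truth$map$label), c("start", "end")]
  map_out <- partition_7tm(truth$protein, tm, "extracellular")
  expect_identical(map_out$label[3], "IL1")
  map_in <- partition_7tm(truth$protein, tm, "intracellular")
  expect_identical(map_in$label[3], "EL1")
  # completeness: segment substrings concatenate back to the protein
  pieces <- vapply(seq_len(15), function(k) {
    substr(truth$protein, map_out$start[k] + 1, map_out$end[k])
  }, character(1))
  expect_identical(paste(pieces, collapse = ""), truth$protein)
  expect_error(partition_7tm(truth$protein, tm[1:5, ]),
               class = "optoxr_topology_error")
})

test_that("full topology call matches generator truth labels", {
  truth <- make_7tm(3)
  called <- call_topology(truth$protein, id = "fixture")
  expect_identical(called$label, truth$map$label)
  expect_true(all(abs(called$start - truth$map$start) <= 2))
  expect_true(all(abs(called$end - truth$map$end) <= 2))
})

test_that("raising the threshold never increases the candidate count", {
  for (s in 1:20) {
    truth <- make_7tm(2000 + s)
    prof <- hydropathy_profile(truth$protein)
    counts <- vapply(c(1.0, 1.3, 1.6, 2.0, 2.4, 2.8), function(th) {
      nrow(call_tm_segments(prof, threshold = th))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0), info = paste("seed", 2000 + s))
  }
})

test_that("consensus of identical maps is the input map", {
  truth <- make_7tm(5)
  fam <- rep(truth$protein, 4)
  msa <- star_msa(truth$protein, fam)
  maps <- replicate(4, truth$map, simplify = FALSE)
  cons <- consensus_topology(truth$map, maps, msa)
  expect_equal(as.data.frame(cons), as.data.frame(truth$map))
})

test_that("the median shrugs off a single shifted homolog boundary", {
  truth <- make_7tm(5)
  msa <- star_msa(truth$protein, rep(truth$protein, 5))
  shifted <- truth$map
  shifted$start[4] <- shifted$start[4] + 6L # TM2 start outlier
  shifted$end[3] <- shifted$end[3] + 6L
  maps <- c(replicate(4, truth$map, simplify = FALSE), list(shifted))
  cons <- consensus_topology(truth$map, maps, msa)
  expect_equal(as.data.frame(cons), as.data.frame(truth$map))
})

test_that("consensus over jittered families lands within one residue", {
  withr::with_seed(11, {
    truth <- make_7tm(11)
    n_len <- attr(truth$map, "length")
    fam <- rep(truth$protein, 6)
    msa <- star_msa(truth$protein, fam)
    maps <- lapply(1:6, function(h) {
      jit <- truth$map
      internal <- 2:15
      jitter <- sample(-2:2, 14, replace = TRUE)
      starts <- pmin(pmax(jit$start[internal] + jitter, 0L), n_len)
      jit$start[internal] <- as.integer(starts)
      jit$end[1:14] <- as.integer(starts)
      validate_topology_map(jit)
      jit
    })
    cons <- consensus_topology(truth$map, maps, msa)
    expect_true(all(abs(cons$start - truth$map$start) <= 1))
  })
})

test_that("topology BED round-trip preserves the map", {
  truth <- make_7tm(8)
  path <- withr::local_tempfile(fileext = ".bed")
  write_topology(truth$map, path)
  back <- read_topology(path)
  expect_equal(as.data.frame(back), as.data.frame(truth$map))
})
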