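# Independent oracles and small generators used across the suite.
# Deliberately naive implementations: they must not share code paths with
# the package.

# score an explicit gapped alignment with affine costs (independent scan)
oracle_score <- function(ca, cb, mat, open, ext) {
  score <- 0
  prev <- "M"
  for (k in seq_along(ca)) {
    if (ca[k] == "-") {
      score <- score - if (prev == "A") ext else open
      prev <- "A"
    } else if (cb[k] == "-") {
      score <- score - if (prev == "B") ext else open
      prev <- "B"
    } else {
      score <- score + mat[ca[k], cb[k]]
      prev <- "M"
    }
  }
  score
}

# exhaustive enumeration of all global alignments; returns the best score
brute_force_align <- function(a, b, mat, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, score, prev) {
    if (i > length(ca) && j > length(cb)) {
      if (score > best) best <<- score
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      recurse(i + 1L, j + 1L, score + mat[ca[i], cb[j]], "M")
    }
    if (i <= length(ca)) {
      recurse(i + 1L, j, score - if (prev == "A") ext else open, "A")
    }
    if (j <= length(cb)) {
      recurse(i, j + 1L, score - if (prev == "B") ext else open, "B")
    }
  }
  recurse(1L, 1L, 0, "M")
  best
}

# simple symmetric test matrix over a 4-letter alphabet
test_matrix_4 <- function(match = 3, mismatch = -2) {
  letters4 <- c("A", "C", "D", "E")
  m <- matrix(mismatch, 4, 4, dimnames = list(letters4, letters4))
  diag(m) <- match
  m
}

random_protein <- function(n, seed) {
  withr::with_seed(seed, {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
          collapse = "")
  })
}

random_dna <- function(n, seed) {
  withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  })
}

# naive quadratic in-silico PCR at zero mismatches: substring scans on both
# strands, independent of Biostrings
naive_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

naive_pcr_scan <- function(template, fwd, rev, max_product) {
  find_all <- function(pat, s) {
    k <- nchar(pat)
    hits <- integer(0)
    if (k > nchar(s)) return(hits)
    for (i in 0:(nchar(s) - k)) {
      if (substr(s, i + 1, i + k) == pat) hits <- c(hits, i)
    }
    hits
  }
  products <- list()
  orientations <- list(c(fwd, rev), c(rev, fwd))
  for (o in orientations) {
    fs <- find_all(o[1], template)
    rs <- find_all(naive_revcomp(o[2]), template)
    for (f in fs) {
      for (r in rs) {
        e <- r + nchar(o[2])
        len <- e - f
        if (len >= nchar(o[1]) + nchar(o[2]) && len <= max_product) {
          products[[length(products) + 1L]] <- c(f, e)
        }
      }
    }
  }
  if (length(products) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  df <- unique(do.call(rbind, products))
  df <- df[order(df[, 1], df[, 2]), , drop = FALSE]
  data.frame(start = df[, 1], end = df[, 2])
}

# random whole-codon ORF with no stop, with n_sites restriction sites planted
# at codon-aligned-free random positions; rejection keeps the ORF stop-free
plant_sites_orf <- function(seed, n_codons = 100, n_sites = 3,
                            sites = c("GGTACC", "GGATCC")) {
  withr::with_seed(seed, {
    repeat {
      prot <- paste(sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*"),
                           n_codons, replace = TRUE), collapse = "")
      orf <- optoxr::back_translate(prot, optoxr::codon_usage())
      pos <- sample(0:(nchar(orf) - 7), n_sites)
      for (p in pos) {
        s <- sample(sites, 1)
        substr(orf, p + 1, p + 6) <- s
      }
      tr <- optoxr::translate_dna(orf)
      if (!attr(tr, "stopped")) {
        return(orf)
      }
    }
  })
}

# synthetic amplifiable template: random flanks around planted binding
# sites for the chimera-assay primer pair
make_pcr_template <- function(seed = 9, inter = 160) {
  fwd <- "TGACAACGAGTACACCACGG"
  rev <- "GCTTCGTCGCAATGAGTTCC"
  withr::with_seed(seed, {
    left <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
    mid <- paste(sample(c("A", "C", "G", "T"), inter, replace = TRUE), collapse = "")
    right <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
    list(
      template = paste0(left, fwd, mid, optoxr::revcomp(rev), right),
      no_rev = paste0(left, fwd, mid, right),
      fwd = fwd, rev = rev
    )
  })
}
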