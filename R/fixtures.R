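# Seeded synthetic-data generators. Every generator is a pure function of
# its arguments: repeated calls are byte-identical. Derived seeds come from
# one documented splitting rule so a single top-level seed reproduces a
# whole scenario.

HYDROPHOBIC_AA <- c("A", "I", "L", "V", "F", "M", "W", "C")
HYDROPHILIC_AA <- c("D", "E", "K", "R", "S", "T", "N", "Q", "G", "P", "H", "Y")

#' Derive a sub-generator seed
#'
#' Splitting rule for seeded scenarios: `(seed * 7919 + k) mod (2^31 - 1)`.
#' Documented so one top-level seed reproduces every sub-generator.
#'
#' @param seed Top-level integer seed.
#' @param k Stream index.
#' @return Derived integer seed, always below 2^31.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + k) %% 2147483647)
}

#' Generate a synthetic 7TM protein with known topology
#'
#' Transmembrane helices are drawn from a hydrophobic alphabet
#' (`A I L V F M W C`), loops and termini from a hydrophilic alphabet
#' (`D E K R S T N Q G P H Y`). Each helix is redrawn until every
#' within-helix hydropathy window averages at least `tm_margin` (default
#' 2.0), so generated helices clear the default calling threshold of 1.6
#' with margin — the margin is enforced by construction and asserted by
#' tests, not assumed. Stands in for real opsin/GPCR sequences, whose
#' composition statistics it does not attempt to mimic.
#'
#' @param seed Integer seed.
#' @param tm_len_range Length-2 range of TM lengths, within `[15, 30]`
#'   (default `c(18, 25)`).
#' @param loop_len_range Length-2 range of loop lengths (default `c(8, 40)`).
#' @param nt_len,ct_len N-/C-terminus lengths (defaults 25 and 50).
#' @param tm_margin Minimum mean hydropathy of any window (width up to 19)
#'   inside a generated helix (default 2.0).
#' @param id Sequence id.
#' @return A list of class `synthetic_7tm`: `protein` (string), `map`
#'   (`topology_map` ground truth), `params`.
#' @export
make_7tm <- function(seed, tm_len_range = c(18L, 25L),
                     loop_len_range = c(8L, 40L),
                     nt_len = 25L, ct_len = 50L, tm_margin = 2.0,
                     id = paste0("syn7tm_", seed)) {
  if (any(tm_len_range < 15) || any(tm_len_range > 30) ||
      any(loop_len_range < 1) || nt_len < 1 || ct_len < 1) {
    abort("length ranges out of bounds (TM lengths must lie in [15, 30])",
      class = "optoxr_parameter_error"
    )
  }
  withr::with_seed(seed, {
    tm_lens <- sample(tm_len_range[1]:tm_len_range[2], 7, replace = TRUE)
    loop_lens <- sample(loop_len_range[1]:loop_len_range[2], 6, replace = TRUE)
    seg_lens <- integer(15)
    seg_lens[1] <- nt_len
    seg_lens[15] <- ct_len
    seg_lens[2 * (1:7)] <- tm_lens
    seg_lens[2 * (1:6) + 1] <- loop_lens
    kd <- kyte_doolittle()
    draw_tm <- function(len) {
      w <- min(19L, len)
      repeat {
        res <- sample(HYDROPHOBIC_AA, len, replace = TRUE)
        v <- kd[res]
        cs <- c(0, cumsum(v))
        window_means <- (cs[(w + 1):(len + 1)] - cs[1:(len - w + 1)]) / w
        if (min(window_means) >= tm_margin) {
          return(paste(res, collapse = ""))
        }
      }
    }
    seqs <- vapply(seq_len(15), function(k) {
      if (k %% 2 == 0) {
        draw_tm(seg_lens[k])
      } else {
        paste(sample(HYDROPHILIC_AA, seg_lens[k], replace = TRUE), collapse = "")
      }
    }, character(1))
    ends <- cumsum(seg_lens)
    starts <- ends - seg_lens
    map <- new_topology_map(
      tibble(label = SEGMENT_ORDER, start = as.integer(starts),
             end = as.integer(ends)),
      seq_id = id, length = sum(seg_lens), orientation = "extracellular"
    )
    structure(
      list(
        protein = paste(seqs, collapse = ""), map = map,
        params = list(seed = seed, tm_len_range = tm_len_range,
                      loop_len_range = loop_len_range,
                      nt_len = nt_len, ct_len = ct_len)
      ),
      class = "synthetic_7tm"
    )
  })
}

#' Generate a homolog family by point substitution
#'
#' Applies i.i.d. per-site substitutions at rate `sub_rate` (no indels, so
#' homolog coordinates map one-to-one onto the reference). With
#' `class_preserving = TRUE` substitutions stay within the segment's
#' hydrophobic/hydrophilic alphabet, preserving the hydropathy contrast.
#'
#' @param truth A [make_7tm()] result.
#' @param n Number of homologs.
#' @param sub_rate Per-site substitution rate, in `[0, 0.2]`.
#' @param seed Integer seed.
#' @param class_preserving Keep substitutions within the segment class
#'   alphabet (default TRUE).
#' @return Named character vector of `n` homolog protein strings.
#' @export
make_family <- function(truth, n = 6L, sub_rate = 0.05, seed = 1L,
                        class_preserving = TRUE) {
  stopifnot(inherits(truth, "synthetic_7tm"))
  if (sub_rate < 0 || sub_rate > 0.2 || n < 1) {
    abort("sub_rate must lie in [0, 0.2] and n must be >= 1",
      class = "optoxr_parameter_error"
    )
  }
  chars <- strsplit(truth$protein, "")[[1]]
  map <- truth$map
  seg_of <- rep(seq_len(15), map$end - map$start)
  is_tm <- grepl("^TM", map$label)[seg_of]
  withr::with_seed(seed, {
    fam <- vapply(seq_len(n), function(h) {
      mut <- runif(length(chars)) < sub_rate
      out <- chars
      for (i in which(mut)) {
        alphabet <- if (!class_preserving) {
          AA_ALPHABET
        } else if (is_tm[i]) {
          HYDROPHOBIC_AA
        } else {
          HYDROPHILIC_AA
        }
        choices <- setdiff(alphabet, out[i])
        out[i] <- sample(choices, 1L)
      }
      paste(out, collapse = "")
    }, character(1))
    names(fam) <- paste0(attr(map, "seq_id"), "_hom", seq_len(n))
    fam
  })
}

#' Generate a synthetic reporter CDS
#'
#' A seeded random CDS beginning with ATG and ending with a single stop
#' codon, standing in for a fluorescent-reporter gene in tests and demos
#' (real reporter sequences are user inputs). Drawn free of KpnI/BamHI
#' sites, as a reporter destined for a multiple-cloning-site vector must be.
#'
#' @param seed Integer seed.
#' @param n_codons Number of internal codons (default 80).
#' @return DNA string.
#' @export
make_reporter <- function(seed = 99L, n_codons = 80L) {
  code <- genetic_code()
  sense <- code$codon[!code$is_stop & code$codon != "ATG"]
  withr::with_seed(seed, {
    repeat {
      cds <- paste0("ATG", paste(sample(sense, n_codons, replace = TRUE),
                                 collapse = ""), "TAA")
      if (!grepl("GGTACC", cds, fixed = TRUE) &&
          !grepl("GGATCC", cds, fixed = TRUE)) {
        return(cds)
      }
    }
  })
}

#' Generate a consistent backbone / target / chimera scenario
#'
#' Runs [make_7tm()] twice with seeds derived from the top-level seed,
#' assembles the classic full swap (`IL1, IL2, IL3, Ct`), and deterministically
#' back-translates all three proteins, so the chimera CDS agrees with the
#' parent CDSs codon-for-codon outside the swapped segments.
#'
#' @param seed Integer seed.
#' @param swap Swap set (default the full intracellular set).
#' @return A list of class `chimera_scenario`: `backbone`, `target`
#'   ([make_7tm()] objects), `design` (`chimera_design`), `backbone_cds`,
#'   `target_cds`, `chimera_cds`.
#' @export
make_parent_chimera_set <- function(seed, swap = c("IL1", "IL2", "IL3", "Ct")) {
  backbone <- make_7tm(derive_seed(seed, 1L), id = paste0("backbone_", seed))
  target <- make_7tm(derive_seed(seed, 2L), id = paste0("target_", seed))
  design <- assemble_chimera(
    backbone$protein, backbone$map, target$protein, target$map, swap = swap
  )
  tab <- codon_usage()
  structure(
    list(
      backbone = backbone, target = target, design = design,
      backbone_cds = back_translate(backbone$protein, tab),
      target_cds = back_translate(target$protein, tab),
      chimera_cds = back_translate(chimera_protein(design), tab)
    ),
    class = "chimera_scenario"
  )
}

#' Simulate a tidy qPCR Ct table with known fold changes
#'
#' Reference-gene Ct is a constant baseline plus Gaussian noise; target Ct is
#' the calibrator's target baseline minus `log2(fold)` plus noise, so a
#' noise-free table inverts exactly under [relative_expression()]. The
#' calibrator sample (fold 1) is always included.
#'
#' @param seed Integer seed.
#' @param true_fold_changes Named numeric vector of per-sample fold changes.
#' @param ct_noise_sd Gaussian Ct noise standard deviation (>= 0).
#' @param n_replicates Replicates per sample/gene (default 3).
#' @param reference_ct,target_baseline_ct Baseline cycles (defaults 18, 24).
#' @return A tibble with columns `sample`, `gene`, `replicate`, `ct`;
#'   attribute `truth` holds the fold changes (calibrator included).
#' @export
make_qpcr_table <- function(seed, true_fold_changes = c(treated = 4),
                            ct_noise_sd = 0.3, n_replicates = 3L,
                            reference_ct = 18, target_baseline_ct = 24) {
  if (any(true_fold_changes <= 0) || ct_noise_sd < 0) {
    abort("fold changes must be positive and noise sd non-negative",
      class = "optoxr_parameter_error"
    )
  }
  folds <- c(calibrator = 1, true_fold_changes)
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(names(folds), function(s) {
      tibble(
        sample = s,
        gene = rep(c("target", "reference"), each = n_replicates),
        replicate = rep(seq_len(n_replicates), 2L),
        ct = c(
          target_baseline_ct - log2(folds[[s]]) + rnorm(n_replicates, 0, ct_noise_sd),
          reference_ct + rnorm(n_replicates, 0, ct_noise_sd)
        )
      )
    })
    structure(rows, truth = folds)
  })
}

#' Write a full synthetic scenario to a directory
#'
#' Materialises one seeded scenario as plain-text files: backbone/target
#' proteins and topology truth, homolog family, parent and chimera CDSs, a
#' synthetic reporter, a qPCR table, and a manifest recording every
#' parameter and the seed.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
simulate_scenario <- function(seed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scen <- make_parent_chimera_set(seed)
  fam <- make_family(scen$target, n = 6L, sub_rate = 0.05,
                     seed = derive_seed(seed, 3L))
  qpcr <- make_qpcr_table(derive_seed(seed, 4L),
                          true_fold_changes = c(treated = 4))
  write_fasta(tibble(
    id = c(attr(scen$backbone$map, "seq_id"), attr(scen$target$map, "seq_id")),
    description = c("synthetic backbone", "synthetic target"),
    seq = c(scen$backbone$protein, scen$target$protein)
  ), file.path(dir, "proteins.fasta"))
  write_fasta(tibble(id = attr(scen$backbone$map, "seq_id"),
                     description = "synthetic backbone",
                     seq = scen$backbone$protein),
              file.path(dir, "backbone.fasta"))
  write_fasta(tibble(id = attr(scen$target$map, "seq_id"),
                     description = "synthetic target",
                     seq = scen$target$protein),
              file.path(dir, "target.fasta"))
  write_fasta(fam, file.path(dir, "family.fasta"))
  write_topology(scen$backbone$map, file.path(dir, "backbone_truth.bed"))
  write_topology(scen$target$map, file.path(dir, "target_truth.bed"))
  write_fasta(tibble(
    id = c("backbone_cds", "target_cds", "chimera_cds"),
    description = "",
    seq = c(scen$backbone_cds, scen$target_cds, scen$chimera_cds)
  ), file.path(dir, "cds.fasta"))
  write_fasta(tibble(id = "reporter_synthetic",
                     description = "synthetic reporter CDS",
                     seq = make_reporter(derive_seed(seed, 5L))),
              file.path(dir, "reporter_synthetic.fasta"))
  utils::write.csv(as.data.frame(qpcr), file.path(dir, "qpcr.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = seed,
    derived_seeds = list(backbone = derive_seed(seed, 1L),
                         target = derive_seed(seed, 2L),
                         family = derive_seed(seed, 3L),
                         qpcr = derive_seed(seed, 4L),
                         reporter = derive_seed(seed, 5L)),
    family = list(n = 6, sub_rate = 0.05, class_preserving = TRUE),
    qpcr = list(true_fold_changes = c(treated = 4), ct_noise_sd = 0.3,
                n_replicates = 3)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
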