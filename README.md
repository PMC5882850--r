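# optoxr

Design toolkit for **opto-XR chimeric receptors**: light-activatable
receptors built by grafting the intracellular signalling surfaces of a
G protein-coupled receptor (GPCR) onto a channelrhodopsin-like
seven-transmembrane (7TM) backbone. The classic construction keeps the
backbone's N-terminus, transmembrane helices and extracellular loops — the
light-sensing machinery — and replaces its three intracellular loops and
C-terminus with those of the target GPCR, so blue light drives the
target's G-protein signalling. This is the standard route to activating
**orphan GPCRs**, which have no known ligand.

The package covers the full in-silico workflow:

* **Topology calling** — Kyte–Doolittle hydropathy with windowed profiling,
  change-point edge refinement, and the canonical 15-segment partition
  (Nt, TM1–7, IL1–3, EL1–3, Ct); optional consensus over an aligned
  homolog family (median of projected boundaries through a star MSA built
  on affine-gap Needleman–Wunsch, BLOSUM62, gap open 10 / extend 1).
* **Chimera assembly** — whole-segment swaps at the backbone's TM
  boundaries with per-residue provenance tracking.
* **Cassette compilation** — codon-optimized back-translation (mouse table
  by default), KpnI/BamHI restriction-site removal by synonymous
  substitution, direct fusion to a reporter through the in-frame
  `GCGGCCGCC` linker (Ala-Ala-Ala, NotI core) with the reporter's start
  codon deleted, or a T2A bicistronic layout; annotated GenBank output.
* **qPCR support** — junction-spanning primer pairs verified by in-silico
  PCR to amplify the chimera and neither parent, and relative
  quantification by the 2^−ΔΔCt method.
* **Synthetic fixtures** — seeded generators for 7TM proteins with known
  topology, homolog families, parent/chimera scenarios, and qPCR tables,
  so everything is testable offline.

Results are tibbles designed for the pipe, with `tidy()`, `glance()` and
`autoplot()` methods throughout.

## Worked example

```r
library(optoxr)

# synthetic backbone and target with known ground truth
backbone <- make_7tm(3, id = "backbone")
target   <- make_7tm(5, id = "target")

bb_map <- call_topology(backbone$protein, id = "backbone")
glance(bb_map)
#> # A tibble: 1 × 5
#>   seq_id   length orientation    n_tm mean_tm_length
#> 1 backbone    347 extracellular     7           20.7

design <- assemble_chimera(backbone$protein, bb_map,
                           target$protein,
                           call_topology(target$protein, id = "target"))
glance(design)
#> # A tibble: 1 × 7
#>   backbone_id target_id swap           length n_backbone_residues n_target_residues
#> 1 backbone    target    Ct,IL1,IL2,IL3    315                 213               102
```

The chimera keeps the backbone's 213 residues of light-sensing scaffold
and carries 102 target-derived intracellular residues. Compile it into a
cloning-ready cassette and design a chimera-specific qPCR assay:

```r
tab <- codon_usage()                           # mouse host
cds <- back_translate(chimera_protein(design), tab)
cds <- remove_sites(cds, 0, restriction_enzymes(c("KpnI", "BamHI")), tab)
cass <- build_cassette("hSyn", fuse_reporter(cds, make_reporter(99)))
glance(cass)
#> # A tibble: 1 × 6
#>   id       style         promoter host  length n_elements
#> 1 cassette direct_fusion hSyn     mouse   1209          6

j <- chimera_junctions(design)
pair <- design_junction_primers(
  cds, 3 * j$junction[j$right_label == "IL3"],
  c(backbone = back_translate(backbone$protein, tab),
    target   = back_translate(target$protein, tab)))
pair
#> junction-spanning primer pair (junction at 612 ):
#>   forward 5'-TGGTTCGACGGCGAGCCTA-3'
#>   reverse 5'-CCAGAATCCACCAGGCCAG-3'
#>   amplicon [606, 676), specificity: specific
```

The 1209-bp cassette runs `GGTACC` … ORF–linker–reporter–stop … `GGATCC`:
one uninterrupted reading frame translating to chimera + Ala-Ala-Ala +
reporter-minus-Met. The primer pair's forward oligo straddles the TM5→IL3
splice point, so it amplifies the chimera (`specificity: "specific"`) but
yields no product on either parental coding sequence.

Relative expression from a (here simulated) Ct table:

```r
qpcr <- make_qpcr_table(1, c(stimulated = 4), ct_noise_sd = 0.3)
relative_expression(qpcr, "target", "reference", "calibrator")
#> # A tibble: 2 × 4
#>   sample       dct  ddct fold_change
#> 1 calibrator  5.76  0           1
#> 2 stimulated  4.02 -1.74        3.34
```

With three noisy replicates the true 4-fold induction is recovered as
3.34; noise-free tables invert exactly.

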