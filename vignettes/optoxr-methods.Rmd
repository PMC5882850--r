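---
title: "Designing opto-XR chimeras: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing opto-XR chimeras: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoxr)
```

## The design problem

An opto-XR is a chimeric receptor that couples a light-sensing
seven-transmembrane (7TM) scaffold — here a channelrhodopsin-like backbone —
to the intracellular signalling surfaces of a G protein-coupled receptor
(GPCR). The GPCR's G-protein coupling determinants live in its three
intracellular loops (IL1–IL3) and C-terminus; the backbone's light response
lives in its transmembrane helices and extracellular face. Replacing the
backbone's IL1, IL2, IL3 and C-terminus with those of a target GPCR
therefore yields a receptor that is activated by light but signals like the
target. This is particularly useful for orphan GPCRs, which have no known
ligand to activate them pharmacologically.

`optoxr` turns this construction into a reproducible computational
workflow: call the 15-segment 7TM topology of backbone and target
(Nt, TM1–7, IL1–3, EL1–3, Ct), splice the target's intracellular parts into
the backbone, compile a codon-optimized and restriction-audited expression
cassette fused to a fluorescent reporter, and design junction-spanning qPCR
primers whose amplicon exists only on the chimera.

## Topology calling

Topology is called from Kyte–Doolittle hydropathy. The per-residue scale is
averaged over a sliding window (default 19 residues, odd by construction);
windows are truncated at the sequence ends and averaged over the residues
present, so no hydropathy is fabricated by padding.

Candidate helices are maximal profile runs at or above a threshold (default
1.6). Runs separated by fewer than `min_loop_len` (default 4) positions are
merged; runs longer than `max_tm_len` (default 30) are split at their
interior profile minimum.

A windowed profile, however, smears each boundary inward: with a 19-residue
window, the mean only crosses 1.6 once roughly 80% of the window is
hydrophobic, so a raw run under-calls each helix by about five residues per
edge, and a minimum-length helix produces a run far shorter than the helix
itself. Two consequences shape the implementation:

* **Edge refinement.** Each run edge is refined by a change-point fit on
  the *unwindowed* per-residue hydropathy: KD zero is the natural midpoint
  between the hydrophobic and hydrophilic classes, so the best cut is the
  argmin (left edge) or argmax (right edge) of the KD prefix sum, searched
  outward from the detected run within one window length. Detected runs lie
  strictly inside the true helix, which is why the search extends outward
  only.
* **Filter order.** The `min_tm_len` filter (default 15) is applied to the
  *refined* intervals, with a two-residue allowance for boundary
  uncertainty — filtering raw runs would discard genuine helices.

When the number of candidates differs from seven, `partition_7tm()` fails
loudly and carries the candidate list in its error condition, rather than
silently keeping the "best 7": chimera correctness depends on segment
identity, and the caller can retune the threshold.

Loops alternate sides starting from the declared orientation of the
N-terminus (default extracellular, true of both channelrhodopsins and
GPCRs); no positive-inside inference is attempted. Boundaries can be
refined further by consensus over an aligned homolog family: each boundary
becomes the **median** of the homolog boundaries projected into reference
coordinates (the reference's own call included). The median gives an
integral coordinate and shrugs off a single divergent homolog; votes that
land in a reference-gap column are skipped with a notice. Published cut
points can always be imposed directly, since topology maps are plain
tibbles.

## Alignment

Homolog boundaries are transferred through a reference-centric star
multiple alignment built from optimal global pairwise alignments
(Needleman–Wunsch, affine gaps, three-state dynamic program in C++). A gap
of length $L$ costs $\mathrm{open} + (L-1)\cdot\mathrm{extend}$ (defaults
10 and 1, BLOSUM62). Ends are penalized — domain boundaries near termini
matter here, so terminal gaps are not free. Traceback ties are broken
deterministically (diagonal, then gap in the second sequence, then gap in
the first), making outputs bit-reproducible. A star layout was chosen over
progressive-tree MSA because the workflow only ever needs
homolog-to-reference coordinate transfer, which the star construction makes
exact ("once a gap, always a gap" merging in reference coordinates). The
defaults are conventional, not a reconstruction of any published alignment
protocol.

## Chimera assembly

Splice junctions fall exactly at the backbone's TM boundaries: the backbone
helices carry the light response and must remain intact, and whole loops
are swapped. Unequal loop lengths between backbone and target are expected
and preserved — the chimera simply changes length. The swap set defaults to
the full intracellular set `{IL1, IL2, IL3, Ct}`; only intracellular labels
are accepted. An optional per-junction offset allows TM-proximal anchor
residues to be retained where a published construct did so, without
asserting any particular choice. Every part records its source and original
coordinates, so re-assembly from a design is exact (idempotent) and the
per-residue provenance track always partitions the assembled length.

## Cassette compilation

Back-translation uses a host codon-usage table (default mouse, the usual
expression animal; the host is configurable and recorded in the output).
Deterministic mode takes each amino acid's most frequent codon with
alphabetical tie-breaks; sampled mode draws codons by frequency under a
seed. Restriction sites for the cloning pair (default KpnI `GGTACC` /
BamHI `GGATCC`) are removed from the ORF by iterated synonymous
substitution: the leftmost hit is recoded via the next-most-frequent
synonym of one overlapping codon, translation provably unchanged, until no
unprotected hit remains (bounded by `max_iter`). The default direct-fusion
linker `GCGGCCGCC` encodes Ala-Ala-Ala and deliberately carries a NotI
core, so it is protected from site removal.

Two cassette styles are supported. *Direct fusion* appends the linker and
the reporter with its initiator ATG deleted, closing with exactly one stop
codon (default TAA) — one continuous reading frame whose translation is
`chimera + AAA + reporter[-Met]`. *T2A bicistronic* inserts a self-cleaving
2A peptide and keeps the reporter initiator, the layout of AAV transfer
vectors; the 2A sequence is a required input with no baked-in default.
Terminal stop codons on inputs are stripped with a notice. Kozak insertion
is off by default. The assembled cassette is validated (elements
concatenate exactly; single terminal stop; no internal stop; reporter
initiator absent in direct fusion) and exported as an annotated GenBank
flat file via a minimal writer/parser implemented in the package.

## Primer design and qPCR

A chimera-specific qPCR assay needs an amplicon no parental transcript can
produce. The designer anchors the **forward primer across the splice
junction**, with at least `anchor` (default 6) bases on each side, so its
sequence is a composite that exists in neither parent; the reverse primer
binds downstream. Candidates (length 18–25, GC within 30–70%) are ranked
by melting-temperature balance then GC-closeness to 50%, and each pair is
screened by in-silico PCR against the chimera and both parents; the first
pair with at least one chimera product and zero parent products is
returned, so the designer can never disagree with the screener.

In-silico PCR reports every convergent primer placement on either strand
within `max_product` (default 2000 bp), allowing up to `max_mismatch`
(default 2) mismatches per primer but requiring the `three_prime_exact`
(default 5) 3'-terminal bases to match exactly, since extension initiates
there. Melting temperatures use the Wallace rule below 14 nt and the GC
formula $64.9 + 41(G{+}C-16.4)/N$ otherwise — adequate for ranking;
nearest-neighbour thermodynamics is a possible extension.

Relative expression follows the standard $2^{-\Delta\Delta C_t}$ method:
per-sample $\Delta C_t$ is the arithmetic mean of target-gene $C_t$
replicates minus that of the reference gene (e.g. GAPDH), referenced to a
calibrator sample, with no efficiency correction.

## The synthetic-data generators

Real opsin and GPCR sequences are inputs, not fixtures; the package tests
itself on seeded synthetic 7TM proteins with known ground truth. Helices
are drawn from a hydrophobic alphabet (`A I L V F M W C`), loops and
termini from a hydrophilic one (`D E K R S T N Q G P H Y`). Defaults — TM
lengths 18–25, loop lengths 8–40, Nt 25, Ct 50 — span the geometry of real
7TM receptors. Because the hydrophobic alphabet contains tryptophan
(KD −0.9), an unconstrained draw can produce a helix too weak to call;
each helix is therefore redrawn until every within-helix window (width up
to 19) averages KD ≥ 2.0, so generated helices clear the 1.6 calling
threshold with margin by construction — the margin is asserted by tests,
not assumed. Homolog families apply i.i.d. point substitutions (rate ≤
0.2, default 0.05), class-preserving by default and with **no indels**, so
homolog coordinates map one-to-one onto the reference and consensus logic
is tested in isolation from alignment quality. qPCR tables place the
target's calibrator baseline at Ct 24 and the reference gene at Ct 18 with
Gaussian noise, so a noise-free table inverts exactly.

What these fixtures do *not* emulate: real amino-acid composition
statistics, helix amphipathy, signal peptides, indels between species, or
PCR efficiency differences. Passing tests demonstrate that the algorithms
are correct on data satisfying their stated assumptions — they do not
certify boundary accuracy on any particular real receptor, which is why
the tools accept externally supplied (e.g. published) boundaries
everywhere.

All generators are pure functions of their arguments; sub-generator seeds
derive from one splitting rule, `(seed * 7919 + k) mod (2^31 - 1)`, so a
single top-level seed reproduces a whole scenario byte-for-byte.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; all human-facing output
  (GenBank, reports) is 1-based closed.
* Ambiguity codes are rejected, never expanded: a design tool must not
  emit ambiguity. RNA `U` is accepted and converted to `T` with a notice.
* Codon-usage fractions are renormalised per amino acid on load (sum to 1
  within 1e-6) and checked codon-by-codon against the standard genetic
  code.
* Zero-length termini are legal topology segments; a zero-length *swapped*
  segment is an assembly error naming the segment.
* Consensus boundary clipping enforces segment order and minimum TM
  lengths after the median vote.
* `ddct` requires at least one replicate per gene and positive Ct values.

## Problem sizes used by the checks

The shipped verification suite exercises: 100 synthetic proteins for
boundary recovery (≥95% of boundaries within ±2 residues, 7/7 helices on
all); several hundred short pairs against an exhaustive alignment
enumerator; 500 random proteins for back-translation round-trips; 100
ORFs with 1–5 planted cloning sites for site removal; 20 parent/chimera
scenarios for primer specificity plus 50 templates against a naive
quadratic PCR scan; 200 noisy qPCR tables for ΔΔCt recovery (mean
recovered fold for a true fold of 4, noise sd 0.3, 6 replicates, expected
in [3.85, 4.30] from the lognormal mean 4·exp((0.3·√(4/6)·ln 2)²/2) ≈ 4.06
plus simulation error); and a double pipeline run compared byte-for-byte.
These sizes give stable statistics while keeping the whole suite fast on a
single CPU.

## Known limitations

* Hydropathy-based calling is the classical method, not a machine-learned
  predictor; on real sequences with amphipathic or short helices it may
  require threshold tuning or externally supplied boundaries.
* Star MSA is exact for coordinate transfer but not a general-purpose
  aligner; there is no local alignment mode and no nucleotide alignment.
* Primer Tm uses simple counting formulas; no dimer/hairpin
  thermodynamics, no TaqMan probe design, no transcriptome-scale
  off-target search.
* Vector backbones (promoter and flanking plasmid sequence) are recorded
  as annotations only; the plasmid itself is not reconstructed.
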