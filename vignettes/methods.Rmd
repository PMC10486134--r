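---
title: "Methods: reference-anchored comparative genomics of insect-specific flaviviruses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-anchored comparative genomics of insect-specific flaviviruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

flavicomp analyses a small set of complete insect-specific flavivirus (ISFV)
genomes against a prototype reference. The genome model is the standard
flavivirus organisation: a single positive-sense RNA of ~10.8 kb with a
short 5′ UTR, one long open reading frame encoding a polyprotein that is
cleaved into mature peptides (C, prM/M, E, NS1–NS5, plus the short 2K
peptide), and a 3′ UTR. All coordinates in the data model are 1-based
inclusive; BED exports convert to that format's native 0-based half-open
convention and VCF stays 1-based, so each file format keeps its own idiom.
RNA `U` is normalized to `T` at ingest (one internal alphabet); the
frameshift module converts back to RNA for display.

The analysis is *reference-anchored*: every isolate is aligned pairwise to
the prototype and all downstream statistics (SNVs, per-region counts,
similarity tracks, pseudo-MSA columns for distances) live in reference
coordinates. At the within-species divergences this targets (≥ 84%
nucleotide identity, essentially collinear genomes), pairwise-to-reference
carries the same information as a progressive multiple alignment while
keeping the pipeline self-contained and deterministic; this is a deliberate
design choice, not an approximation we quantify per run.

## Alignment

`global_align()` implements the three-state affine-gap dynamic program
(match/mismatch state plus one gap state per sequence), restricted to the
band `|j − i| ≤ w`. Defaults: match +1, mismatch −1, gap open −4, gap
extend −1, `band_width` w = 600 nt. A gap of length *k* costs
`gap_open + (k − 1)·gap_extend`. The band is a speed device only: whenever
the optimal path stays inside the band the result equals the full dynamic
program (the test suite checks this against an independent full-matrix
implementation on random pairs), and a band narrower than the length
difference of the inputs is rejected up front. Traceback ties are resolved
diagonal > up > left, making the output a deterministic function of inputs
and parameters.

Percent identity uses a blastn-style convention: the denominator is every
column whose reference position falls in the interval of interest plus the
internal gap columns between them; terminal overhangs (columns before the
two sequences first meet, or after they last meet) are excluded, and any
column containing an IUPAC ambiguity code is excluded from both numerator
and denominator rather than guessed at. The same exclusion applies to SNV
calling, so no variant is ever fabricated from an ambiguous base.

## Variants

`call_snvs()` emits one record per aligned column where both genomes carry
a differing unambiguous base; indels are out of scope by design (the
analysis concerns substitutions). `classify_snvs()` substitutes each SNV
*alone* into the reference codon and translates with the standard genetic
code. This per-variant convention (the one used by common variant
annotators) means two SNVs in one codon are each judged against the
reference state; such codons are additionally flagged `MULTIHIT` in VCF
output so users can re-examine them jointly if they wish. Codon phase is
always derived from the single polyprotein ORF — `codon_index =
⌈(pos − orf_start + 1)/3⌉` — because mature-peptide boundaries can split
codons (the 69-nt 2K region does); a per-region frame would misclassify
there.

Summary tables report, per region, each isolate's SNV and nonsynonymous
counts with cross-isolate means. Means and all printed percentages round
half-up to one decimal. (With three isolates at 17, 18 and 18
nonsynonymous substitutions the mean is 17.67, printed 17.7; we note that
published tables sometimes print such a value as 17.6, which is consistent
with truncation rather than rounding.) Noncoding SNVs are counted under
their UTR rows; the totals row sums the coding (mature-peptide) regions
only, which is the convention under which the published genome-wide totals
of this study system reproduce as column sums.

## Region partitions and transfer

The packaged fixture stores the published 11-region partition of the QBV
prototype verbatim (ORF span 113..10189, i.e. 10,077 nt). The prototype's
text also describes a 10,080-nt coding region; whether the published table
omits the stop codon or starts one codon late cannot be resolved from the
text, so the fixture is kept verbatim while the synthetic generator uses
its own self-consistent coordinates (10,080-nt CDS whose last region
absorbs the stop codon). `transfer_regions()` maps a partition through an
alignment; a boundary landing in a query gap snaps inward (start right,
end left) so transferred regions are never padded with unaligned bases, and
a region entirely deleted from the query is flagged missing rather than
dropped.

## Phylogenetics

Distances are computed from either a user-supplied alignment or the
reference-anchored pseudo-MSA (`stack_alignments()`), with pairwise
deletion of gap/ambiguity columns. `tn93_distance()` is the closed-form
Tamura–Nei (1993) distance with empirical base frequencies pooled over the
pair, separate purine and pyrimidine transition terms, and the standard
gamma-rates variant (each `−k log w` term becomes `k·a·(w^{−1/a} − 1)`;
shape 1 mirrors common practice for this virus group). Saturated pairs
(log argument ≤ 0) return `Inf` with a warning instead of a fabricated
number. Analyses in this literature often report MEGA's maximum composite
likelihood distance; TN93 is the closed form in the same substitution
family, and the clade-level questions this pipeline answers are robust to
the difference — the package therefore documents TN93 as its model rather
than imitating MCL's simultaneous estimation.

`neighbor_joining()` is the standard Saitou–Nei agglomeration with the
Q-criterion, deterministic lowest-index tie-breaks, and negative branch
estimates clamped to zero (counted in an attribute; the complement is
transferred to the sibling branch, standard practice). Bootstrap supports
resample alignment columns with replacement under an explicit seed,
rebuild the tree per replicate, and count bipartitions of the original
tree; replicates in which every resampled sequence is identical carry no
signal and are skipped, with supports expressed over the replicates used.

## Frameshift elements

ISFVs express the overlapping *fifo* gene by programmed −1 ribosomal
frameshifting at a slippery heptamer followed by a stimulatory RNA
structure. `detect_prf()` scans for the five heptamers reported in insect
flaviviruses (exact matches, overlaps included, whole genome by default
with region labels attached; an interval argument restricts the scan),
then folds the 150 nt immediately 3′ of each heptamer — interpreting
"downstream" as starting after the heptamer's last base — and checks
hairpin geometry: a terminal loop of 3–10 nt closed by a helix of ≥ 4
stacked pairs (1-nt bulges allowed between stacks) whose 5′ end lies in the
first 60 nt of the window.

Folding is Nussinov-style base-pair maximization (Watson–Crick + GU wobble,
minimum hairpin loop 3) rather than thermodynamic minimum-free-energy
folding: the question asked — *is there a stem-loop?* — does not need an
energy model, and the dynamic program is exact and dependency-free. One
consequence is handled explicitly: the whole-window pairing maximum can
absorb a genuine local hairpin into long-range pairs of equal cardinality.
When the global structure shows no qualifying hairpin, the detector
refolds short (40-nt) subwindows across the search prefix and accepts a
hairpin found there. Users wanting thermodynamic structures can fold the
reported `downstream_seq` with an external MFE folder and re-apply
`stem_loop_check()` conventions to its output.

## The synthetic generator

`simulate_study()` defines the study conditions the package is validated
under: a reference genome with 98-nt 5′ UTR, 10,080-nt CDS, 653-nt 3′ UTR
(total 10,831 nt, GC 0.5), partitioned into the canonical 11 regions at
their published lengths (the generator's NS5 absorbs the 3-nt stop to make
the CDS self-consistent), and three isolates planted with exactly the
published per-region synonymous and nonsynonymous counts, drawn with a
transition/transversion bias of 2 — a typical value for RNA virus
divergence. Planted substitutions are verified by translation before
emission (site-wise rejection sampling, ≤ 1000 retries), avoid codon
double-hits by default so per-SNV truth is unambiguous, and never create
nonsense or start-loss mutations, keeping every simulated ORF intact.
UTRs are generated ATG-free so the planted ORF is the unique long one.
Tree-based simulation evolves sites independently under Jukes–Cantor or a
TN93 parameterization (transition matrices from the eigendecomposition of
the normalized rate matrix).

What the generator deliberately does not emulate: indels and alignment
ambiguity, mutational hotspots and context dependence, RNA secondary
structure constraints on the UTRs, recombination, and codon-usage
selection. Passing the planted-truth tests therefore demonstrates that the
pipeline's bookkeeping (alignment, coordinate arithmetic, codon logic,
counting) is exact under substitution-only divergence at realistic density;
it does not certify behaviour on genomes with substantial indel divergence,
where alignment choice genuinely matters.

## Problem sizes and determinism

The test suite validates at full genome scale (10.8-kb genomes, the
published per-region counts, 20 generator seeds for the recovery and
frameshift-detection properties) and at reduced scale where an exhaustive
oracle is the comparator: full-matrix alignment up to ~300 nt, exhaustive
structure enumeration up to 18-nt windows, exhaustive topology search up to
6 taxa — sizes chosen so the oracles are unambiguous, not as statements
about the method's limits. Every stochastic step takes an explicit seed;
replaying a seed reproduces byte-identical genomes, trees and reports.

## Known limitations

* Pairwise-to-reference anchoring ignores isolate-specific insertions
  (they are dropped from reference-coordinate tracks) — appropriate for
  collinear congeneric genomes, wrong for structurally divergent ones.
* The identity denominator convention differs from blastn's in edge cases
  (blastn restricts to its local HSPs); whole-CDS identities computed here
  can therefore differ from published blastn values by a few tenths of a
  percent, and no attempt is made to force agreement.
* Base-pair maximization is not an energy model: stem lengths reported for
  verified sites describe the maximal stacked helix in the computed
  pairing, not a thermodynamic structure.
* Neighbor-joining with TN93 is a distance method; it does not reproduce
  branch supports or exact branch lengths of likelihood-based published
  trees, and is validated here on topology recovery.
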