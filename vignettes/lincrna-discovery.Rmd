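---
title: "Discovering long intergenic non-coding RNAs from two-condition RNA-seq"
author: "poplinc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering long intergenic non-coding RNAs from two-condition RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poplinc)
```

## The problem

Deep RNA sequencing of a plant in two conditions — a well-watered control
(CL) and a drought treatment (DL), one library each — reveals substantial
transcription outside annotated protein-coding genes. Some of that signal is
genomic DNA contamination, some is unannotated coding sequence, some is
repeat or miRNA-precursor transcription, and some is genuine long intergenic
non-coding RNA (lincRNA): transcripts longer than 200 nt, at least 200 bp
away from any gene, with no substantial open reading frame. `poplinc`
implements the complete discovery pipeline — coverage-based assembly of
transcription units, a four-filter candidate cascade, coding-potential
assessment, a two-library count test for drought-responsive expression, and
miRNA target / target-mimic scanning — together with a synthetic-data
generator that plants elements of every class with known ground truth, so
each stage can be verified end to end without any external download.

## Assembly model

Reads are taken as already aligned (alignment itself is out of scope; the
package consumes SAM/BAM or its own plain-text BED-pair dialect). Per-base
**coverage** is the number of alignment blocks covering a base. A
**transcription active region** (TAR) is a maximal run of bases with depth
at least `min_depth`; the default of 2 encodes the rule that bases covered
by fewer than 2 reads per base pair are not considered, and it is applied
during TAR calling — the only reading that makes TAR boundaries
deterministic — while mean depth is still reported per TAR. TARs are
connected into **gene models** whenever at least `min_link` (default 1) mate
pairs have one mate overlapping each; connectivity is closed transitively,
gaps between consecutive exons become introns, and every intron is, by
construction of the connectivity argument, spanned by at least one linking
pair. A model is an **intergenic transcription unit** when it overlaps no
annotated gene and lies at least `min_distance` (default 200 bp, counted as
bases strictly between the model span and the gene) from the nearest gene
boundary; the quoted distance rule is ambiguous between strict and
non-strict, so the inclusive reading (exactly 200 bp away passes) was chosen
and is configurable. TARs and TUs carry no strand: the libraries are
unstranded, and all downstream sequence analyses scan both strands
explicitly.

## The four-filter cascade

Merged across libraries (two TUs belong to one locus when they overlap by at
least 1 bp on the same scaffold, transitively; locus exons are the union of
member exons — the field has no standard definition of locus identity across
libraries, so the weakest defensible one is used), each locus is tested by
four pure predicates, recorded in a filter trace in pipeline order:

1. **Length**: spliced length strictly greater than 200 bp ("longer than"
   read strictly: 200 fails, 201 passes).
2. **ORF**: the longest ORF over both strands strictly smaller than 100
   amino acids. An ORF starts at ATG and ends at the first in-frame stop; a
   partial ORF with no stop counts to the last complete codon — the
   conservative choice against miscalling coding transcripts as non-coding.
   Length in AA counts codons from the ATG, stop excluded.
3. **Both libraries**: the locus must contain TUs from CL *and* DL,
   protecting against genomic-DNA contamination private to one library.
4. **Similarity**: no high-similarity match to the repeat or miRNA-precursor
   libraries. The scanner is seed-and-extend local alignment — exact 11-mer
   seeds, ungapped extension at match +1 / mismatch −2 with X-drop 10 — and
   flags a candidate whose best alignment reaches 80% identity over at least
   50 bp on either strand. The source procedure names only "high
   similarity", so these thresholds are explicit, configurable stand-ins; an
   exact Smith–Waterman bound is part of the test suite. Near the identity
   boundary the heuristic and the exact optimum can select different best
   segments; on clearly-decided inputs they agree exactly.

## Coding-potential score

A transparent three-feature logistic model stands in for an external
coding-potential classifier while preserving its decision semantics (score
below 0.5 means non-coding; a locus counts as lincRNA only if **both**
orientations are non-coding, so the reported score is the maximum over
strands). Features, computed from the longest ORF of each strand: log ORF
length, ORF coverage of the transcript, and the mean per-codon
log-likelihood ratio of the ORF against a reference codon usage table over
the uniform distribution (61 sense codons; stop codons are excluded from all
codon-usage statistics, as frequency tables conventionally cover sense
codons). The weights are frozen constants, calibrated once by a seed-pinned
ridge-logistic fit (`tools/calibrate-coding-weights.R`) on the generator's
coding mRNAs versus shuffled intergenic sequence; the ORF-length weight is
constrained non-negative so the score is monotone in ORF length. On
held-out draws the frozen weights label ≥95% of coding mRNAs coding and
≥90% of shuffled intergenic sequence non-coding.

The reference codon table is shared between the scorer and the genome
generator. Because no species codon-usage reference can be bundled,
`synthetic_codon_table()` constructs a deterministic plant-like table:
typical proteome amino-acid composition with synonymous-codon preference
GC-biased (by bisection) to a target coding GC of 0.426, against an
intergenic background of 0.34 — the contrast between coding and
intergenic GC that the features exploit. A user-supplied 64-entry
per-thousand table is accepted anywhere this one is used.

## Differential expression

Counts are raw fragments (a mate pair counts once per locus when either
mate overlaps a locus exon by ≥1 bp; the counting rule is not specified by
the source procedure and this is the simplest defensible one). Within-library
normalisation is FPKM. The significance test is the classical two-library
read-count test of Audic & Claverie: conditional on `x` fragments in the
first library (total `N1`), the count `k` in the second (total `N2`) follows

    p(k | x) = (N2/N1)^k * (x+k)! / (x! k!) * (1 + N2/N1)^-(x+k+1),

a negative-binomial distribution in `k`, and the two-sided P-value is the
smaller of the two tail sums `sum_{k<=y}` and `sum_{k>=y}`. The printed form
of the final factor in the source is garbled; `(1 + N2/N1)^-(x+k+1)` is the
only resolution under which the distribution sums to one, and that
normalisation identity is itself a test. Numerically, terms are evaluated in
log space via log-gamma; the infinite upper tail uses the complement of the
finite lower sum with compensated summation, falling back to direct
log-space summation when the complement would cancel catastrophically
(upper tail below ~1e−4). Both tails as printed include the observed count,
which makes the two-sided minimum *not* invariant under swapping the
libraries — the exact identity that does hold (the swapped lower tail equals
the strict upper tail) is asserted in the tests. On 1e5 simulated null locus
pairs the test is conservative-to-nominal at α = 0.001.

A locus is called drought-responsive when the log2 FPKM ratio (DL over CL)
strictly exceeds 1 in magnitude **and** P is strictly below 0.001. Infinite
ratios (one-sided zero counts) satisfy the magnitude condition; a 0/0 locus
is excluded and reported missing. No multiple-testing correction is applied,
matching the source procedure; a Benjamini–Hochberg column is available as a
clearly-marked, off-by-default extension. With one library per condition no
dispersion can be estimated — biological variance is not modelled, which is
the main caveat when reading the calls.

## miRNA targets and target mimics

Scanning is by pure pairing-pattern rules (no free-energy model; the stated
criteria are pattern counts). Everything is in the DNA alphabet with T read
as U. A miRNA position j (5'→3') pairs antiparallel with window position
w+1−j, so a **target** window of miRNA length is an approximate match of the
miRNA's reverse complement: Watson–Crick pairs match; G:U wobbles (miRNA G
against window T, miRNA U against window G) and mismatches share a combined
budget of 3; no bulges. The full miRNA length is the pairing region. A
**mimic** (eTM) window is longer by the bulge: perfect Watson–Crick pairing
is required at miRNA positions 2–8, an unpaired lincRNA bulge of exactly 3
nt must sit opposite miRNA positions 9–11 (insertion point between
positions p and p+1 with both ends inside the range, i.e. p ∈ {9, 10}), and
the remaining positions share a budget of 3 mismatches + G:U. The mimicry
rules live in the eTM literature rather than in one fixed tool, so every
constant is a named `pairing_rules()` key rather than a hard-coded value. A
site that also satisfies the stricter bulge-free target rule is reported
only as a target. Both strands of every lincRNA are scanned; coordinates
are reported on the sense strand. Interaction sites collapse to a bipartite
miRNA–lincRNA network with per-miRNA counts of lincRNAs degraded versus
lincRNAs acting as mimics.

## The synthetic study

The generator emulates the statistical structure the pipeline assumes, not
sequencing reality:

* **Genome**: by default 2 scaffolds × 2 Mbp of i.i.d. sequence at
  intergenic GC 0.34, with 40 non-overlapping genes (ATG-initiated ORFs of
  250–500 codons drawn from the reference codon table, short UTRs), placed
  in evenly spread slots.
* **Planted elements**: true lincRNAs (500–1500 bp, rejection-sampled to be
  ORF-free under the package's own scanner, ≥200 bp from every gene; some
  carry planted miRNA target or mimic sites), long-ORF decoys (≥1200 bp with
  an embedded 120–180 AA ORF), exact copies of repeat and precursor library
  sequences, and near-gene decoys placed <200 bp from a gene.
* **Libraries**: per element and library the fragment count is Poisson with
  the manifest's mean — deliberately matching the Poisson null of the count
  test so type-I-error checks are interpretable (no negative-binomial
  overdispersion). Planted lincRNA fold changes default to 4× up and down
  (the "drought responsive" design) with two loci at exactly 2× probing the
  strict log2 > 1 boundary. Fragments are placed uniformly; each yields two
  90 bp mates on opposite strands with inner distance Normal(200, 30)
  truncated at zero, clipped to the element. Planted elements get ~15×
  read depth; coding genes absorb the rest of the ~5×10^5 fragments per
  library. Optional uniform background noise is off by default (no
  intergenic background rate is specified anywhere, and zero keeps the
  funnel's expectations exact).
* **Not emulated**: sequencing errors, splicing-aware placement, strand
  protocols, overdispersion, mapping ambiguity. Alignment is exact
  placement. Passing tests therefore demonstrate correctness of the
  pipeline's logic under its own model assumptions, not robustness to real
  library artefacts.

Everything is deterministic given the seed: reruns are byte-identical.

### Element sizing and what the assembler sees

With 90 bp mates and a ~200 bp inner distance, a fragment spans ~380 bp, so
elements shorter than roughly twice the span show an uncovered interior gap;
the mate pairs then correctly reassemble the element as a two-exon model,
and its *spliced* length is what the length filter sees. The 500 bp lower
bound on planted lincRNAs keeps spliced lengths comfortably above the
200 bp threshold; long-ORF decoys are ≥1200 bp with the ORF centred so the
decoy ORF survives assembly intact and is reliably caught by the ORF filter.

## Problem sizes used by the test suite

The acceptance-style checks run the full study at 2 × 2 Mbp / 40 genes /
~5×10^5 fragments per library (the funnel recovers exactly the 10 planted
lincRNAs and rejects every decoy); the P-value oracle grid covers x, y up to
100 with library ratios 0.5–2 and normalisation up to x = 10^4; the type-I
simulation uses 10^5 null loci; the miRNA brute-force comparison covers 200
lincRNAs × 10 miRNAs; ORF brute force covers 1000 random sequences of
0.2–2 kb. These sizes were chosen so the whole suite completes in a few
minutes while every check retains power.

## Known limitations

* Single library per condition: the count test sees only sampling noise.
* The coding score is calibrated on synthetic contrasts; on real data its
  absolute operating point depends on the supplied codon table.
* The similarity scanner is ungapped; diverged repeats with indels are only
  found through their longest ungapped block.
* TAR assembly has no isoform resolution and no spliced-alignment intron
  evidence; introns arise only from coverage gaps bridged by mate pairs.
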