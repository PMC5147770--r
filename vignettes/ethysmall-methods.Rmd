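---
title: "Models and methods behind ethysmall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ethysmall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ethysmall` re-creates, at desk scale, a genome-wide small-RNA analysis of
the kind used to ask how a hormone treatment (ethylene) reshapes miRNA and
gene expression across tissues and genotypes — and specifically, which
miRNA/target pairs move in opposite directions only in the wild type, i.e.
depend on a gene of interest such as the nuclear cap-binding subunit CBP20.
This vignette explains the models, the tunable parameters, and the design
choices made where the underlying conventions are not fully standardized.

## The discovery model

De novo miRNA identification proceeds from collapsed, genome-anchored
sequence tags:

1. **Read processing.** Reads are kept when their mean Phred score is at
   least 20 and they contain no `N`. The 3' adapter is removed at its
   leftmost exact match of at least 8 nt; trimmed reads shorter than 15 nt
   are dropped. Distinct sequences become *tags* with per-library counts.
2. **Anchoring.** Tags are matched exactly (both strands, all occurrences)
   against the genome. Multi-mapping tags keep all hits — discovery needs
   every locus, and counts stay per-tag. Tags touching an annotated tRNA,
   rRNA, snRNA or snoRNA by even one nucleotide are removed entirely
   (strand-agnostic; the strictest reading avoids false miRNA calls).
   Tags of 18–28 nt are then selected. Structural exclusion is applied
   before the length window; the order is configurable because neither
   order is canonical.
3. **Seeding and windows.** Tags with at least 50 reads pooled across all
   libraries seed precursor search. Pooling is the sensitive reading of a
   support threshold with no per-library qualifier; it is configurable.
   Around each hit, candidate precursor windows extend 100–500 nt each
   side in 100-nt steps; the smallest window that validates wins, giving
   the minimal precursor, which is the conventional annotation.
4. **Folding.** Each window is folded and the miRNA/miRNA* duplex read
   off: the star arm is the minimal interval containing all partners of
   mature positions, extended 2 nt at its 3' end for the canonical 2-nt
   overhang of plant miRNA duplexes. The *mismatch ratio* is the fraction
   of mature positions with no partner, mature length in the denominator —
   the simplest testable reading; a duplex-length denominator is available
   via the duplex statistics. Windows pass at ratio ≤ 0.3.
5. **Margin refold and annotation criteria.** The minimal
   mature-through-star interval, widened by 15 nt margins, is refolded and
   must form a single hairpin. The duplex must additionally have at most 5
   unpaired mature positions and at most 2 nt of asymmetric bulge, and at
   least one mapped tag must overlap the predicted star interval by half
   its length — miRNA* reads are the standard supporting evidence that a
   locus produces a processed duplex, and they are what separates genuine
   loci from the incidental hairpins that surround a well-expressed tag in
   any genome. Each sub-criterion can be switched or re-thresholded
   independently.
6. **Families and known miRNAs.** Candidates cluster into families by
   single linkage (mature sequences within 2 substitutions, or overlapping
   precursors); the family id is the lexicographically smallest mature. A
   candidate matches a known mature miRNA at up to 2 substitutions, no
   gaps, length within 2 nt; one match labels the whole family.

### Folding engines

Two folding engines sit behind one interface (`fold()`; a sequence in, a
pair table out). The self-contained engine is base-pair maximization
(Nussinov dynamic programming) over nested structures with A:U, G:C and
G:U pairs and a minimum loop of 3 nt, with a deterministic traceback
(each position pairs its smallest admissible partner among optimal
structures). It is exact, dependency-free, and oracle-tested against
exhaustive enumeration.

Maximum-pairing structures, however, saturate: on windows hundreds of
nucleotides long, random background sequence pairs almost everywhere, so
the partners of mature positions scatter and the star interval loses its
meaning. The discovery stages therefore default to the thermodynamic
engine, which shells out to `RNAfold` (ViennaRNA) for the
minimum-free-energy structure; on the same windows the planted duplex
dominates the MFE structure and the star interval is recovered cleanly.
Both engines are deterministic. If `RNAfold` is absent the discovery
functions can be pointed back at the Nussinov engine, at reduced
specificity on long windows.

Two measurement choices follow from folding realities rather than from any
single convention:

* **Single-hairpin test.** "One stem" is evaluated after discarding
  branches with fewer than 8 pairs. Any fold of a real precursor
  accumulates incidental helices in its 15-nt margins (a 15-nt flank can
  form at most 6 pairs given the loop constraint), so a literal "no second
  helix anywhere" rejects every genuine hairpin, while a genuine tandem
  hairpin contributes a branch of ~20 pairs and still fails.
* **Duplex criteria on a duplex alignment.** The unpaired-position and
  asymmetric-bulge criteria describe the miRNA/miRNA* duplex, not the
  whole precursor fold. MFE structures reorganize mismatch-containing
  duplexes (recruiting alternative partners, bulging star nucleotides),
  so these criteria are measured on a direct overlap alignment of the
  mature against the reversed star arm (`duplex_align()`): end overhangs
  free, aligned non-pairable columns are symmetric mismatches, interior
  gap columns count as asymmetric-bulge nucleotides. The gap cost (0.6 per
  nucleotide against a pair's 1.0) makes a gap worth taking only when it
  restores a downstream helix, never to convert an isolated mismatch.

## The target-prediction model

A miRNA:target site alignment is scored with a position-dependent
mispairing penalty ("T score"): Watson–Crick 0, G:U wobble +0.5, mismatch,
single-nucleotide target bulge or single-nucleotide miRNA gap +1 — doubled
when the lesion falls at miRNA positions 2–13 from the 5' end. Position 1
lies outside the doubled region. Only one bulge *or* one gap is allowed in
a site. Sites score ≤ 6 to be retained; ≤ 5 marks high confidence. Both
thresholds are arguments.

Scanning is exhaustive: windows of the miRNA length ±1 slide over each
transcript, every admissible alignment of each window is enumerated, and
the minimum-score alignment wins (ties to the leftmost bulge/gap). A
compiled kernel enumerates windows; the R-level `align_site()` carries the
reference semantics and the two are cross-checked in the tests.
Overlapping retained sites resolve to the lower score, then leftmost.
The bulge position index used for doubling is the miRNA position whose
state slot carries the bulge (leftmost-adjacent convention); the
convention only matters for reporting, not for the minimum score.

Cleavage is predicted at the bond between the target nucleotides paired to
miRNA positions 10 and 11 — the canonical RISC slicing site. The returned
coordinate `b` means "between transcript offsets `b - 1` and `b`"
(0-based). If position 10 or 11 sits in a bulge the nearest paired
flanking bond is used and flagged. `race_fraction()` reduces 5'-RACE clone
ends to the fraction at the canonical bond.

## Differential expression

Small-RNA expression is normalized as CP10M (count per 10 million mapped
reads); genes as FPKM/RPKM (`count * 1e9 / (length * total)`). For a
contrast, counts pool across the replicate libraries of each condition and
each feature is tested with a two-sided conditional exact test of its
pooled count against the pooled library totals (a 2×2 hypergeometric —
chosen for determinism and robustness at two replicates; a t-test on log2
CP10M would be the parametric alternative). BH correction runs across all
tested features. A call requires both the fold-change threshold (miRNA
1.5, genes 2.0 — the 1.5 gene convention is available via `min_fc`) and
adjusted p < 0.05. Fold changes use a 0.5 pseudo-count on raw counts, so
zeros never produce infinite ratios; the threshold is inclusive (a fold
change of exactly 1.5 at `min_fc = 1.5` is called). Genes below 1 RPKM in
both conditions are not tested. Replicate quality is the Pearson
correlation of `log2(FPKM + 1)` over genes with FPKM > 0.5 (strict) in
both replicates.

## Integration

Differential sets feed plain set algebra: Venn partitions, root-not-shoot
tissue specificity, and CBP20 dependence — differential in the wild type
*and* not significant in the mutant at the same thresholds (matching a
Venn construction on calls; a fold-change-only criterion would be weaker
and is not the default). Anti-correlated pairs join a differential miRNA
to a predicted target differential in the opposite direction in the same
contrast, carrying the dependence flag and the site's T score.

## The synthetic-data generator

All inputs are generated with machine-readable ground truth so that every
stage is testable offline:

* **Genome.** Uniform random background (25% each base; composition is
  irrelevant to the assertions and uniformity avoids accidental hairpin
  enrichment). Each planted miRNA locus is mature + 15-nt loop + reverse
  complement of the mature with an exact number of non-pairing
  substitutions, placed without overlap on a random strand; structural
  loci (tRNA/rRNA/snRNA/snoRNA) are labeled intervals. Coordinates are
  0-based half-open internally; GFF3 output is 1-based inclusive.
* **Libraries.** The design is 2 genotypes × 2 tissues × 2 treatments × 2
  replicates. Reads are drawn multinomially from tag weights: mature tags,
  star tags at 10% of mature (any value below the mature works for arm
  logic; 10% is a typical passenger-strand abundance), structural
  fragments of 15–35 nt, and genome-derived background tags. Per-condition
  fold effects multiply mature/star weights. The 3' adapter is appended
  and the read truncated to the read length; quality is uniformly high
  with an optional low-quality fraction. Each planted mature is ~0.1% of
  its library: small enough that a 3-fold effect changes library
  composition negligibly and CP10M ratios reflect planted effects, large
  enough to clear the 50-read seed threshold at the default depth of
  50,000 reads per library (16 libraries pool to ~800 reads per mature).
* **Transcriptome.** Each locus gets a host transcript embedding a target
  site constructed to score exactly its intended penalty (lesions placed
  3'-first, positions 10/11 kept paired so the cleavage site stays
  defined); decoys carry no site. Counts are Poisson around expectations
  (`count_noise = "none"` gives the expectations exactly); transcripts
  hosting targets of up-regulated miRNAs are down-regulated by the
  configured fold in exactly the matching conditions.

What the generator does **not** emulate: sequencing errors, indels,
realistic quality distributions, isomiRs, compositional biases, or
dispersion beyond Poisson. Passing tests therefore demonstrate the
correctness of the pipeline's logic and thresholds on clean signals, not
performance on real libraries — on real data the exact-test p-values will
be anti-conservative relative to biological replicate variability, and
adapter trimming is exact-match only.

## Problem sizes and determinism

The shipped test scenarios use a 60-kb genome with 10 miRNA loci
(2 star substitutions each), 4 structural loci, 30 background tags and
50,000 reads per library; differential calibration uses 2,000 features at
a depth of 10^6 with two replicates per condition; the end-to-end scenario
plants one ethylene-responsive locus (3× up in wild-type roots), its
target 2× down there only, with the mutant flat and noiseless counts —
that scenario must yield exactly one anti-correlated, genotype-dependent
pair. Every stochastic step derives from one configured seed fanned out
per stage, so all outputs — FASTQ included — are byte-identical across
runs at a fixed seed.

## Known limitations

* Exact-match mapping only; a single sequencing error unmaps a read.
* The exact test treats replicates as pooled counts; real dispersion
  calls for a negative-binomial model, which is out of scope here.
* Target prediction is complementarity-only (no accessibility or
  conservation terms) and allows one bulge/gap at most, per the scoring
  rules it implements.
* `RNAfold` is an external binary; runs without it fall back to
  maximum-pairing folds, which are unreliable for star delineation on
  windows beyond ~100 nt.
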