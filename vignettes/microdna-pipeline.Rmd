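---
title: "Calling and characterizing microDNA from circle-enriched paired-end libraries"
author: "microDNAseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing microDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(0)
```

# The problem

MicroDNA are the smallest class of extrachromosomal circular DNA (eccDNA):
circles of roughly 100-1000 bp excised from unique genomic loci, with a
length distribution that peaks at 200-400 bp and repeats at the nucleosome
spacing. They are typically recovered by enriching circular DNA,
amplifying it by rolling-circle amplification (RCA), and paired-end
sequencing the amplification products. Because RCA turns a circle into a
long tandem concatemer of its sequence, a sequencing fragment can start
anywhere on the circle and run across the ligation junction any number of
times.

In genome coordinates the junction joins the *right* edge of the excised
segment back to its *left* edge. A read that crosses the junction
therefore aligns as a **split read**: two parts on the same strand at the
two edges of the circle, with the query order of the parts *inverted*
relative to their reference order. Its mate, when it does not cross the
junction, maps uniquely and contiguously *inside* the circle on the
opposite strand — the **anchor** (mapped end). This package identifies
microDNA at base-pair resolution from exactly that signature, and ships a
synthetic test bed that generates the whole data path (genome, circles,
reads, alignments) with known ground truth.

# The junction-calling model

`runCaller()` composes four steps, each exposed separately:

1. `readAlignments()` loads every SAM/BAM record (primary, supplementary,
   secondary) with its soft-clip geometry.
2. `assembleSplitPairs()` keeps pairs in which exactly one mate is split
   into exactly two parts (one primary plus one supplementary record) and
   the other mate is a single full-length alignment with
   `mapq >= mapqMin` and no secondary hits. Every other pair is dropped
   under a named counter (`no-split`, `unpaired`, `both-split`,
   `multi-split`, `anchor-split`, `low-mapq`, `duplicate`).
3. `callJunctions()` accepts a candidate pair if and only if
   (a) both parts and the anchor share a chromosome,
   (b) both parts have at least `minPart` aligned bases,
   (c) the parts share a strand,
   (d) the anchor is on the opposite strand,
   (e) the anchor lies between the parts' reference intervals, and
   (f) the query order of the parts is inverted relative to reference
   order. The call is `[leftmost base of the left part, rightmost base of
   the right part]` — the circle's genomic edges.
4. `deduplicateCalls()` merges identical calls (exact identity by
   default), sums support, and orders output deterministically.

Two details of rule (f) and rule (e) deserve explanation because the
design was genuinely open:

* **Query order is compared in the aligned (SEQ) orientation.** In SAM,
  the stored sequence of a minus-strand alignment is
  reverse-complemented, i.e. reference-forward. In that frame a deletion
  artifact's two parts are colinear and a circular junction's parts are
  inverted *on either strand*; comparing in raw read orientation would
  invert the test for minus-strand evidence and silently discard half of
  all junctions.
* **"Between the parts" means containment, not gap insertion.** The
  anchor must lie inside the span delimited by the two parts
  (`leftPart.start <= anchor.start` and `anchor.end <= rightPart.end`).
  Requiring the anchor to fit strictly into the gap *between* the parts
  would reject every fragment whose mates overlap (half of a 300 +/- 30 bp
  insert distribution at 150 bp reads) and would make circles shorter than
  twice the read length uncallable even from short reads, because on a
  small circle the anchor necessarily overlaps the split parts' footprint
  in the circular coordinate system.

## Defaults and why

| Parameter | Default | Rationale |
|---|---|---|
| `mapqMin` | 20 | operationalizes "maps uniquely"; with no secondary hits this is the usual BWA-MEM-style uniqueness proxy |
| `minPart` | 20 bp | near the practical seed floor below which aligners cannot place a split segment |
| `minCircleLength` | 50 bp | smallest circle the evidence model can support; no maximum, to avoid biasing length histograms |
| `mergeTolerance` | 0 bp | calls are base-pair exact on oracle data; a small tolerance (1-2 bp) absorbs junction-breakpoint shifts that real aligners introduce when sequencing errors or microhomology sit at the junction |
| `minSupport` | 0 | complexity counting uses all junctions, not a high-confidence subset |
| duplicate collapsing | on | RCA makes duplicate pairs likely; identical coordinates + CIGARs would otherwise inflate support |

Microhomology at a real junction lets an aligner shift the breakpoint a
few bases; the oracle aligner computes placements from truth and has no
such ambiguity, so the package does not re-canonicalize coordinates. With
real alignments, `mergeTolerance` is the knob that absorbs these shifts.

# The synthetic data generator

The generator is first-class, tested code — it defines the conditions
under which every property of the caller is demonstrated.

* `simulateGenome()` draws i.i.d. bases at a target GC (default 0.45,
  matching the 45-50% GC observed for microDNA).
* `simulateCircles()` samples circle lengths from a Gaussian mixture with
  means 180/360/540 bp (SD 30 bp, weights 0.5/0.3/0.2): mono-, di- and
  tri-nucleosome-sized circles, reproducing the 200-400 bp peak with
  nucleosome-period repeats. Start points are uniform per bp, or biased
  per feature class (a class with fold *f* is *f* times as likely per
  bp). Note the normalization: a planted per-bp fold of 4 on a class
  covering 10% of the genome yields an *observable* enrichment of
  4 / (0.9 + 4 x 0.1) ≈ 3.1, further modified by overlap geometry.
* `simulateReads()` draws fragments on the infinite concatemer
  coordinate system (uniform offset on the circle, Normal(300, 30)
  length), with FR-oriented mates, equal-probability template strands,
  i.i.d. substitution errors, constant Q30 qualities (an optional linear
  decay profile mimics late-cycle quality loss), and a configurable
  fraction of linear-genome background pairs standing in for genomic
  contamination.
* `oracleAlign()` converts truth to exact SAM: full-length matches for
  non-crossing mates; for crossing mates, the longest part as primary
  with the remainder soft-clipped and each other part of at least
  `minPart` bases as a supplementary record with `SA` tags. It replaces
  an external aligner in every test, so results isolate the caller's
  logic from aligner heuristics.

One boundary was set deliberately: circles are simulated only when the
read length is at most **twice** the circle length. Beyond that every
mate would cross the junction at least twice and could never satisfy the
two-part signature; within it, reads wrapping once are kept because they
are exactly what makes short circles callable after re-slicing. A 120 bp
circle sequenced at 150 bp produces only split or multi-split mates —
there is no intact anchor, so it is invisible; re-sliced to 75 bp
(`resliceReads()`, a 5'-anchored truncation mirroring the removal of
unreliable late cycles), anchors reappear and the circle is called. This
is the mechanism behind analyzing the same library at both 150 bp and
75 bp.

What the generator does **not** model: RCA/PCR chimeric artifacts (no
published rate to emulate), indel sequencing errors, aligner-induced
breakpoint ambiguity, and real genome sequence composition
(repeats, assembly gaps). Passing tests therefore demonstrate the
*logic* of the pipeline under clean and noisy-but-well-behaved
conditions, not robustness to every artifact of real libraries.

# Library complexity

`subsampleComplexity()` draws `reps` independent subsamples of `depth`
mapped read **pairs** without replacement, re-runs the caller on each
draw, and reports the per-draw unique-junction counts with their mean and
sample SD (n−1). Defaults are `depth = 500000`, `reps = 10`. Pairs — not
single mates — are the sampling unit: sampling mates independently would
tear apart the anchor/junction pairing the caller depends on.

Because pair acceptance is decided pair by pair, the implementation
computes each pair's verdict once and re-deduplicates the sampled calls
per draw; this is exactly equivalent to re-running the caller on every
subsample and keeps the estimator fast. Duplicate collapsing is disabled
inside the subsampler since unique-junction counts are invariant to
duplicates.

For an equal-abundance synthetic library the expected unique count has a
closed form: with junction *i* supported by *m<sub>i</sub>* of *N* pairs
and draws of *d* pairs,
*E[U] = Σ<sub>i</sub> (1 − C(N−m<sub>i</sub>, d)/C(N, d))*
(`expectedUniqueJunctions()`). The tests also use the exact variance
(pairwise inclusion–exclusion over the disjoint support sets) so that the
Monte-Carlo mean is checked against a true 3-standard-error band rather
than an SE estimated from ten draws.

# Characterization

`featureEnrichment()` computes, per feature class, the fraction of calls
overlapping the class by at least 1 bp and the fraction expected under a
length-preserving null: each placement re-places the same call lengths
uniformly on the genome (chromosome chosen proportional to length, gaps
excluded when a mask is given). The fold is observed/expected; the
reported interval divides the observed fraction by the 97.5/2.5
percentiles of the placement distribution, so under the null it covers
1.0 and under enrichment it brackets the measured fold with the
placement noise. Classes are scored independently (a call may count
toward several), with a per-base option. When the expected fraction and
the observed fraction carry comparable sampling noise, a single library
is an even-odds test of whether the theoretical fold lands in the
interval; the acceptance analysis therefore averages fold and interval
over three replicate libraries, which brings the comparison back to a
~3-sigma test without widening anything.

`lengthProfile()` bins lengths (10 bp bins), reports KDE modes, and
detects the dominant length periodicity as the lag of the strongest
positive local maximum of the autocorrelation of the mean-subtracted
histogram, accepted only above the white-noise band `2/sqrt(n_bins)`;
with fewer than 50 calls or no significant peak the periodicity is
reported as undetermined rather than guessed.

`gcProfile()` computes per-call GC from the reference sequence,
excluding ambiguous bases from the denominator; calls that are entirely
ambiguous either error or are excluded with a warning, per flag.

# Problem sizes

The shipped tests and the acceptance analysis run on a 100 kb
single-chromosome genome with up to 200 planted circles at 50x coverage
(about 10<sup>4</sup> read pairs), 50-junction equal-abundance libraries
for the complexity closed form, and 100 independent 4000-call runs for
the null-enrichment calibration. These sizes were chosen so every
statistical check has comfortable power while the whole suite stays
interactive; all of them are parameters, and nothing in the
implementation depends on scale.

# Known limitations

* Only the split-read signature is used; discordant everted (outward
  facing) pairs, which some eccDNA callers use as corroboration, are not.
* Multi-fragment or rearranged circles and copy-number quantitation from
  coverage are out of scope.
* The oracle aligner cannot reproduce aligner-specific artifacts
  (clipping heuristics, microhomology-shifted breakpoints); with real
  BWA-MEM output those appear and `mergeTolerance` should be set to 1-2.
* Single- versus double-strandedness of circles is a wet-lab property
  invisible to sequencing and is not modeled.

# A minimal end-to-end run

```{r, eval = FALSE}
library(microDNAseq)
genome  <- simulateGenome(1, 100000, gc = 0.45, seed = 1)
circles <- simulateCircles(genome, n = 200, seed = 2)
reads   <- simulateReads(genome, circles, readLength = 150,
                         coverage = 50, errorRate = 0.001, seed = 3)
sam <- tempfile(fileext = ".sam")
writeSam(oracleAlign(reads, genome), sam)

calls <- runCaller(sam)
calls
lengthProfile(calls)
gcProfile(calls, genome)
subsampleComplexity(sam, depth = 2000, reps = 10, seed = 4)
```
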