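# microDNAseq

Base-pair-resolution identification and characterization of **microDNA**
— the smallest class of extrachromosomal circular DNA (eccDNA), mostly
200–400 bp circles excised from unique genomic loci — from paired-end
sequencing of circle-enriched, rolling-circle-amplified (RCA) libraries.
It is written for people analyzing eccDNA/Circle-Seq-style data and for
people building or validating such pipelines, and it ships a complete
synthetic test bed (genome, planted circles, reads, oracle alignments)
so every stage can be demonstrated against known ground truth without an
external aligner.

## The signature

A circle ligates the right edge of a genomic segment `[s, e]` back to its
left edge. In an RCA library a read pair supports that circle when:

* one mate (the **anchor**) maps uniquely and contiguously inside
  `[s, e]`, and
* the other mate crosses the junction and aligns as a **split read**: two
  parts on the same strand (opposite to the anchor), one at each edge,
  with the query order of the parts *inverted* relative to their
  reference order — in aligned (SEQ) orientation the query-earlier part
  maps to the right interval. Colinear order is the signature of a
  deletion, not a circle, and is rejected.

An accepted pair calls the circle as
`[leftmost base of the left part, rightmost base of the right part]` —
exact to the base pair. Calls identical on (chrom, start, end) are merged
with support summed. Around the caller the package provides:

* `simulateGenome()`, `simulateCircles()`, `simulateReads()`,
  `oracleAlign()` — the synthetic data path (nucleosome-period length
  mixture 180/360/540 bp, circular-template fragments, sequencing errors,
  linear-genome background, exact SAM with soft-clips/supplementaries);
* `resliceReads()` / `resliceFastq()` — 5′-anchored truncation (250→150,
  150→75), which is what makes circles shorter than the read length
  callable;
* `subsampleComplexity()` — library complexity as the mean ± SD of
  unique junctions over repeated random draws of a fixed number of
  mapped read pairs (default 500 000 pairs × 10 draws), with
  `expectedUniqueJunctions()` giving the hypergeometric closed form
  `E[U] = Σᵢ (1 − C(N−mᵢ, d)/C(N, d))` for validation and
  `compareComplexity()` for cross-library fold ratios;
* `featureEnrichment()`, `lengthProfile()`, `gcProfile()` — fold
  enrichment over a length-preserving random-placement null,
  length-distribution modes and nucleosome periodicity (histogram
  autocorrelation), and per-call GC content, each with a ggplot panel.

## Worked example

```r
library(microDNAseq)
genome  <- simulateGenome(1, 100000, gc = 0.45, seed = 1)
circles <- simulateCircles(genome, n = 200, seed = 2)
reads   <- simulateReads(genome, circles, readLength = 150,
                         coverage = 50, errorRate = 0.001, seed = 3)
sam <- tempfile(fileext = ".sam")
writeSam(oracleAlign(reads, genome), sam)
calls <- runCaller(sam)
calls
```

```
CallSet: 181 unique junction calls
  pairs examined: 10191  accepted: 3954
  dropped: no-split=4149, both-split=1298, anchor-split=787, duplicate=3
GRanges object with 5 ranges and 3 metadata columns:
      seqnames    ranges strand |     call_id   support strand_evidence
  [1]     chr1   325-675      * |   call00001        30       -:17,+:13
  [2]     chr1   710-906      * |   call00002        12         -:5,+:7
  ...
```

181 of the 200 planted circles are recovered with base-pair-exact
coordinates and zero false calls; the missing ones are circles shorter
than the 150 bp reads, which have no intact anchor mate at this read
length (re-slice to 75 bp to recover them). The drop counters explain
every examined pair: `no-split` pairs carry no junction evidence,
`both-split` pairs have both mates crossing the junction,
`anchor-split` pairs lack an intact full-length anchor.

```r
gcProfile(calls, genome)
subsampleComplexity(sam, depth = 2000, reps = 10, seed = 4)
```

```
GCProfile: 181 calls
  mean GC: 0.449  median GC: 0.448
ComplexityEstimate: depth 2000 pairs x 10 draws
  mean unique junctions: 157.3  SD: 2.11
```

GC tracks the genome it was drawn from (0.45), and at a subsample depth
of 2000 pairs the library yields 157.3 ± 2.1 unique junctions per draw.
With thousands of calls, `lengthProfile()` additionally reports the
nucleosome periodicity of the length histogram (180 bp for the default
mixture); with only ~180 calls it honestly reports the periodicity as
undetermined rather than guessing below its significance band.

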