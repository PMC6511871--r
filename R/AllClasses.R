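#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("DataFrameOrNULL", c("DataFrame", "NULL"))

#' Simulated paired-end reads from circular templates
#'
#' Container returned by [simulateReads()]: the two mate sets (with Phred
#' qualities) plus a truth table recording, for every pair, the template it
#' was drawn from (planted circle or linear background), the fragment
#' geometry on that template, and whether each mate crosses the circle
#' junction. The truth table is what [oracleAlign()] uses to construct exact
#' alignments without running an aligner.
#'
#' @slot mate1,mate2 `QualityScaledDNAStringSet` of the two mates.
#' @slot truth `DataFrame` with one row per pair: `read_id`, `source`
#'   (`"circle"` or `"background"`), `circle_id`, `chrom`, `tmpl_start`,
#'   `tmpl_end` (1-based template interval on the genome), `tmpl_strand`,
#'   `frag_offset` (0-based fragment start on the template), `frag_length`,
#'   `m1_crosses`, `m2_crosses`.
#' @slot readLength Integer read length of both mates.
#' @slot params List of simulation parameters (fragment model, error rate,
#'   background fraction, seed).
#' @exportClass SimulatedReads
setClass("SimulatedReads",
    representation(
        mate1 = "QualityScaledDNAStringSet",
        mate2 = "QualityScaledDNAStringSet",
        truth = "DataFrame",
        readLength = "integer",
        params = "list"
    )
)

setValidity("SimulatedReads", function(object) {
    msg <- NULL
    n <- length(object@mate1)
    if (length(object@mate2) != n)
        msg <- c(msg, "mate1 and mate2 must have equal length")
    if (nrow(object@truth) != n)
        msg <- c(msg, "truth table must have one row per read pair")
    if (n > 0 && !all(Biostrings::width(object@mate1) == object@readLength))
        msg <- c(msg, "all mate1 reads must have the configured read length")
    if (n > 0 && !all(Biostrings::width(object@mate2) == object@readLength))
        msg <- c(msg, "all mate2 reads must have the configured read length")
    if (n > 0 && anyDuplicated(object@truth$read_id))
        msg <- c(msg, "read ids must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Deduplicated microDNA junction calls
#'
#' Result of [runCaller()] (or [deduplicateCalls()]): unique junctions as a
#' `GRanges` (one range per circle, `start`/`end` the circle's genomic
#' edges) with per-call split-read support, plus bookkeeping on how many
#' pairs went in and why the rest were dropped.
#'
#' @slot calls `GRanges` with metadata columns `call_id` and `support`.
#' @slot nInputPairs Number of read pairs examined.
#' @slot nSupportingPairs Number of pairs accepted as junction evidence.
#' @slot dropCounts Named integer vector of drop/rejection reasons.
#' @slot params Caller parameters used.
#' @exportClass CallSet
setClass("CallSet",
    representation(
        calls = "GRanges",
        nInputPairs = "integer",
        nSupportingPairs = "integer",
        dropCounts = "integer",
        params = "list"
    )
)

setValidity("CallSet", function(object) {
    msg <- NULL
    gr <- object@calls
    mc <- S4Vectors::mcols(gr)
    if (!all(c("call_id", "support") %in% colnames(mc)))
        return("calls must carry 'call_id' and 'support' metadata columns")
    if (length(gr) > 0) {
        key <- paste(GenomeInfoDb::seqnames(gr), BiocGenerics::start(gr),
                     BiocGenerics::end(gr))
        if (anyDuplicated(key))
            msg <- c(msg, "calls must be unique on (chrom, start, end)")
        if (any(mc$support < 1))
            msg <- c(msg, "every call needs support >= 1")
    }
    if (sum(mc$support) > object@nSupportingPairs)
        msg <- c(msg, "summed support cannot exceed the accepted pair count")
    if (is.null(msg)) TRUE else msg
})

#' Subsampling-based library-complexity estimate
#'
#' Result of [subsampleComplexity()]: the unique-junction count obtained in
#' each of `reps` independent draws of `depth` mapped read pairs, from
#' which the mean and sample standard deviation summarize how complex
#' (diverse) the circle library is at a fixed sequencing depth.
#'
#' @slot depth Mapped read pairs per draw.
#' @slot reps Number of independent draws.
#' @slot uniqueCounts Integer vector, one unique-junction count per draw.
#' @slot seed Seed the draws were derived from.
#' @slot label Optional library label.
#' @slot params Caller parameters used on each subsample.
#' @exportClass ComplexityEstimate
setClass("ComplexityEstimate",
    representation(
        depth = "integer",
        reps = "integer",
        uniqueCounts = "integer",
        seed = "integer",
        label = "character",
        params = "list"
    )
)

setValidity("ComplexityEstimate", function(object) {
    msg <- NULL
    if (length(object@uniqueCounts) != object@reps)
        msg <- c(msg, "uniqueCounts must have one entry per rep")
    if (any(object@uniqueCounts < 0))
        msg <- c(msg, "unique counts cannot be negative")
    if (is.null(msg)) TRUE else msg
})

#' Feature-class enrichment of a call set
#'
#' Result of [featureEnrichment()]: per feature class, the observed
#' fraction of calls overlapping the class, the fraction expected under
#' length-preserving uniform random placement, their ratio (fold
#' enrichment), and a Monte-Carlo placement interval on the fold.
#'
#' @slot result `DataFrame` with columns `class`, `observed`, `expected`,
#'   `fold`, `lo`, `hi`, `n_calls`.
#' @slot nPlacements Number of random placements behind `expected`.
#' @slot seed Seed used for placements.
#' @slot perBase Whether fractions are per-base rather than per-call.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
    representation(
        result = "DataFrame",
        nPlacements = "integer",
        seed = "integer",
        perBase = "logical"
    )
)

#' Length distribution profile of a call set
#'
#' Result of [lengthProfile()]: binned length histogram, mode estimates,
#' and the dominant histogram periodicity (bp) from the autocorrelation of
#' the mean-subtracted histogram — the signature used to detect
#' nucleosome-spaced circle length peaks.
#'
#' @slot lengths Integer circle lengths (bp).
#' @slot binWidth Histogram bin width (bp).
#' @slot histogram `data.frame` with `mid` and `count`.
#' @slot modes Numeric mode estimates (bp) from kernel density maxima.
#' @slot periodicity Dominant spacing (bp), or `NA` if undetermined.
#' @slot acfPeaks `data.frame` of candidate autocorrelation peaks.
#' @exportClass LengthProfile
setClass("LengthProfile",
    representation(
        lengths = "integer",
        binWidth = "integer",
        histogram = "data.frame",
        modes = "numeric",
        periodicity = "numeric",
        acfPeaks = "data.frame"
    )
)

#' GC-content profile of a call set
#'
#' Result of [gcProfile()]: per-call GC fraction computed from the
#' reference sequence of each called interval (ambiguous bases excluded
#' from the denominator), with summary statistics.
#'
#' @slot gc Numeric per-call GC fractions in `[0, 1]`.
#' @slot mean,median Summary statistics of `gc`.
#' @exportClass GCProfile
setClass("GCProfile",
    representation(
        gc = "numeric",
        mean = "numeric",
        median = "numeric"
    )
)

setValidity("GCProfile", function(object) {
    ok <- is.na(object@gc) | (object@gc >= 0 & object@gc <= 1)
    if (all(ok)) TRUE else "GC fractions must lie in [0, 1]"
})
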