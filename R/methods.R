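# Accessors and show() methods for the package's S4 containers.

#' Extract junction calls from a CallSet
#'
#' @param x A [CallSet-class].
#' @return `GRanges` of unique junction calls with `call_id` and `support`.
#' @export
#' @examples
#' genome <- simulateGenome(1, 50000, gc = 0.45, seed = 1)
#' circles <- simulateCircles(genome, n = 10, seed = 2)
#' reads <- simulateReads(genome, circles, readLength = 100, coverage = 30,
#'                        seed = 3)
#' sam <- tempfile(fileext = ".sam")
#' writeSam(oracleAlign(reads, genome), sam)
#' cs <- runCaller(sam)
#' junctionCalls(cs)
setGeneric("junctionCalls", function(x) standardGeneric("junctionCalls"))

#' @rdname junctionCalls
#' @export
setMethod("junctionCalls", "CallSet", function(x) x@calls)

#' Drop/rejection counters of a CallSet
#'
#' Named integer vector recording why read pairs were not used as junction
#' evidence (e.g. `no-split`, `both-split`, `low-mapq`, `colinear-split`).
#'
#' @param x A [CallSet-class].
#' @return Named integer vector.
#' @export
setGeneric("dropCounts", function(x) standardGeneric("dropCounts"))

#' @rdname dropCounts
#' @export
setMethod("dropCounts", "CallSet", function(x) x@dropCounts)

#' Number of read pairs examined / accepted by the caller
#'
#' @param x A [CallSet-class].
#' @return Integer scalar.
#' @export
setGeneric("nInputPairs", function(x) standardGeneric("nInputPairs"))

#' @rdname nInputPairs
#' @export
setMethod("nInputPairs", "CallSet", function(x) x@nInputPairs)

#' @rdname nInputPairs
#' @export
setGeneric("nSupportingPairs", function(x) standardGeneric("nSupportingPairs"))

#' @rdname nInputPairs
#' @export
setMethod("nSupportingPairs", "CallSet", function(x) x@nSupportingPairs)

#' Per-draw unique-junction counts of a complexity estimate
#'
#' @param x A [ComplexityEstimate-class].
#' @return Integer vector of length `reps`.
#' @export
setGeneric("uniqueCounts", function(x) standardGeneric("uniqueCounts"))

#' @rdname uniqueCounts
#' @export
setMethod("uniqueCounts", "ComplexityEstimate", function(x) x@uniqueCounts)

#' @describeIn uniqueCounts Mean unique-junction count over draws.
#' @export
setMethod("mean", "ComplexityEstimate", function(x, ...) mean(x@uniqueCounts))

#' Sample standard deviation of the per-draw unique counts
#'
#' Uses the n-1 denominator; `NA` when fewer than 2 draws were made.
#'
#' @param x A [ComplexityEstimate-class].
#' @return Numeric scalar.
#' @export
complexitySD <- function(x) {
    stopifnot(is(x, "ComplexityEstimate"))
    if (x@reps < 2L) NA_real_ else sd(x@uniqueCounts)
}

#' Enrichment table of an EnrichmentResult
#'
#' @param x An [EnrichmentResult-class].
#' @return `DataFrame` with one row per feature class.
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' @rdname enrichmentTable
#' @export
setMethod("enrichmentTable", "EnrichmentResult", function(x) x@result)

#' Truth table of a simulated read set
#'
#' @param x A [SimulatedReads-class].
#' @return `DataFrame` with one row per read pair.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname truthTable
#' @export
setMethod("truthTable", "SimulatedReads", function(x) x@truth)

#' Read length of a simulated read set
#'
#' @param x A [SimulatedReads-class].
#' @return Integer scalar.
#' @export
setGeneric("readLength", function(x) standardGeneric("readLength"))

#' @rdname readLength
#' @export
setMethod("readLength", "SimulatedReads", function(x) x@readLength)

#' @rdname truthTable
#' @export
setMethod("length", "SimulatedReads", function(x) length(x@mate1))

#' Periodicity (bp) detected in a length profile
#'
#' @param x A [LengthProfile-class].
#' @return Numeric scalar (bp), `NA` when undetermined.
#' @export
setGeneric("periodicity", function(x) standardGeneric("periodicity"))

#' @rdname periodicity
#' @export
setMethod("periodicity", "LengthProfile", function(x) x@periodicity)

#' Mode estimates (bp) of a length profile
#'
#' @param x A [LengthProfile-class].
#' @return Numeric vector of mode locations (bp).
#' @export
setGeneric("lengthModes", function(x) standardGeneric("lengthModes"))

#' @rdname lengthModes
#' @export
setMethod("lengthModes", "LengthProfile", function(x) x@modes)

#' Per-call GC fractions
#'
#' @param x A [GCProfile-class].
#' @return Numeric vector in `[0, 1]`.
#' @export
setGeneric("gcFractions", function(x) standardGeneric("gcFractions"))

#' @rdname gcFractions
#' @export
setMethod("gcFractions", "GCProfile", function(x) x@gc)

# --- show methods -----------------------------------------------------------

setMethod("show", "SimulatedReads", function(object) {
    tr <- object@truth
    nbg <- sum(tr$source == "background")
    cat("SimulatedReads:", length(object@mate1), "pairs,",
        object@readLength, "bp reads\n")
    cat("  circle pairs:", nrow(tr) - nbg, " background pairs:", nbg, "\n")
    cat("  junction-crossing mates:", sum(tr$m1_crosses) + sum(tr$m2_crosses),
        "\n")
})

setMethod("show", "CallSet", function(object) {
    cat("CallSet:", length(object@calls), "unique junction calls\n")
    cat("  pairs examined:", object@nInputPairs,
        " accepted:", object@nSupportingPairs, "\n")
    if (length(object@dropCounts)) {
        dc <- object@dropCounts[object@dropCounts > 0]
        if (length(dc))
            cat("  dropped:", paste(names(dc), dc, sep = "=", collapse = ", "),
                "\n")
    }
    if (length(object@calls))
        show(utils::head(object@calls, 5))
})

setMethod("show", "ComplexityEstimate", function(object) {
    lab <- if (length(object@label) && nzchar(object@label))
        paste0(" [", object@label, "]") else ""
    cat("ComplexityEstimate", lab, ": depth ", object@depth,
        " pairs x ", object@reps, " draws\n", sep = "")
    cat("  mean unique junctions:", round(mean(object@uniqueCounts), 1),
        " SD:", round(complexitySD(object), 2), "\n")
})

setMethod("show", "EnrichmentResult", function(object) {
    cat("EnrichmentResult (", object@nPlacements, " random placements, ",
        if (object@perBase) "per-base" else "per-call", ")\n", sep = "")
    show(object@result)
})

setMethod("show", "LengthProfile", function(object) {
    cat("LengthProfile:", length(object@lengths), "calls, bin",
        object@binWidth, "bp\n")
    cat("  modes (bp):", paste(round(object@modes), collapse = ", "), "\n")
    cat("  periodicity (bp):",
        if (is.na(object@periodicity)) "undetermined"
        else round(object@periodicity), "\n")
})

setMethod("show", "GCProfile", function(object) {
    cat("GCProfile:", length(object@gc), "calls\n")
    cat(sprintf("  mean GC: %.3f  median GC: %.3f\n",
                object@mean, object@median))
})
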