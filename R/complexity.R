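#' Estimate library complexity by repeated random subsampling
#'
#' Draws `reps` independent random subsamples of `depth` mapped read
#' pairs (uniform, without replacement within a draw), runs the junction
#' caller on each subsample, and records the unique-junction count per
#' draw. The mean over draws is the library's complexity at that depth and
#' the sample SD its subsampling variability — the standard way to compare
#' circle diversity across libraries sequenced to different depths.
#' Defaults (`depth` 500000, `reps` 10) match that normalization
#' procedure.
#'
#' Internally the caller's per-pair verdicts are computed once and each
#' draw re-deduplicates the accepted calls of its sampled pairs; because
#' acceptance is decided pair by pair, this is exactly equivalent to
#' re-running the full caller on every subsample. Duplicate-pair
#' collapsing is not applied since unique-junction counts are invariant
#' to duplicates.
#'
#' @param input SAM/BAM path or segment `DataFrame` from
#'   [readAlignments()].
#' @param depth Mapped read pairs per draw. Must not exceed the library
#'   size unless `allowClamp = TRUE` (then clamped with a warning).
#' @param reps Number of draws; at least 2 for a defined SD.
#' @param seed Integer seed; per-draw child seeds are derived
#'   deterministically, so the same seed reproduces the same counts.
#' @param label Optional library label carried into comparisons.
#' @param mapqMin,minPart,minCircleLength,mergeTolerance Caller
#'   parameters, as in [runCaller()].
#' @param allowClamp Clamp `depth` to the library size instead of
#'   erroring.
#' @return A [ComplexityEstimate-class].
#' @export
#' @examples
#' genome <- simulateGenome(1, 50000, seed = 1)
#' circles <- simulateCircles(genome, n = 20, seed = 2)
#' reads <- simulateReads(genome, circles, readLength = 100, coverage = 30,
#'                        seed = 3)
#' sam <- tempfile(fileext = ".sam")
#' writeSam(oracleAlign(reads, genome), sam)
#' subsampleComplexity(sam, depth = 200, reps = 5, seed = 9)
subsampleComplexity <- function(input, depth, reps = 10L, seed = 1L,
                                label = "", mapqMin = 20L, minPart = 20L,
                                minCircleLength = 50L, mergeTolerance = 0L,
                                allowClamp = FALSE) {
    segments <- if (is.character(input)) readAlignments(input) else input
    depth <- as.integer(depth); reps <- as.integer(reps)
    if (reps < 1L) stop("'reps' must be at least 1")
    qn <- unique(segments$qname)
    nPairs <- length(qn)
    if (depth > nPairs) {
        if (allowClamp) {
            warning("depth ", depth, " exceeds library size ", nPairs,
                    "; clamped")
            depth <- nPairs
        } else {
            stop("depth ", depth, " exceeds the ", nPairs,
                 " mapped read pairs in the library")
        }
    }
    asm <- assembleSplitPairs(segments, mapqMin = mapqMin,
                              collapseDuplicates = FALSE)
    verdicts <- callJunctions(asm$pairs, minPart = minPart,
                              minCircleLength = minCircleLength)
    acc <- as.data.frame(verdicts[verdicts$accepted, , drop = FALSE])

    counts <- vapply(seq_len(reps), function(k) {
        withSeed(childSeed(seed, k), {
            drawn <- sample(qn, depth, replace = FALSE)
            sub <- acc[acc$qname %in% drawn, , drop = FALSE]
            nrow(deduplicateCalls(sub, mergeTolerance = mergeTolerance))
        })
    }, integer(1))
    if (reps < 2L)
        warning("fewer than 2 reps: SD is undefined")
    new("ComplexityEstimate",
        depth = depth, reps = reps, uniqueCounts = counts,
        seed = as.integer(seed), label = label,
        params = list(mapqMin = mapqMin, minPart = minPart,
                      minCircleLength = minCircleLength,
                      mergeTolerance = mergeTolerance))
}

#' Closed-form expected unique junctions under subsampling
#'
#' For a library of `totalPairs` read pairs in which junction `i` is
#' supported by `supportCounts[i]` pairs, the expected number of distinct
#' junctions seen in a uniform draw of `depth` pairs without replacement
#' is `sum_i (1 - C(N - m_i, d) / C(N, d))` (hypergeometric
#' zero-capture complement). Useful as an analytic reference for the
#' Monte-Carlo estimate of [subsampleComplexity()].
#'
#' @param supportCounts Integer vector of supporting pairs per junction.
#' @param totalPairs Total mapped read pairs in the library.
#' @param depth Pairs drawn.
#' @return Expected unique-junction count (numeric scalar).
#' @export
expectedUniqueJunctions <- function(supportCounts, totalPairs, depth) {
    stopifnot(depth <= totalPairs, all(supportCounts >= 0),
              sum(supportCounts) <= totalPairs)
    pZero <- exp(lchoose(totalPairs - supportCounts, depth) -
                     lchoose(totalPairs, depth))
    pZero[totalPairs - supportCounts < depth] <- 0
    sum(1 - pZero)
}

#' Compare complexity estimates across libraries
#'
#' @param estimates A list of [ComplexityEstimate-class] objects (named,
#'   or carrying labels).
#' @param reference Label of the reference library for fold ratios.
#' @return `data.frame` with `label`, `depth`, `reps`, `mean`, `sd`,
#'   `fold` (mean relative to the reference's mean).
#' @export
#' @examples
#' # see vignette for an end-to-end comparison of two libraries
compareComplexity <- function(estimates, reference) {
    stopifnot(is.list(estimates), length(estimates) >= 1L)
    labs <- names(estimates)
    if (is.null(labs) || any(!nzchar(labs)))
        labs <- vapply(estimates, function(e) e@label, character(1))
    if (any(!nzchar(labs)))
        stop("every estimate needs a label (use a named list)")
    depths <- vapply(estimates, function(e) e@depth, integer(1))
    if (length(unique(depths)) != 1L)
        stop("estimates were made at different depths; fold ratios would ",
             "not be comparable")
    if (!reference %in% labs)
        stop("reference label '", reference, "' not found")
    means <- vapply(estimates, function(e) mean(e@uniqueCounts), numeric(1))
    sds <- vapply(estimates, complexitySD, numeric(1))
    ref <- means[match(reference, labs)]
    data.frame(label = labs, depth = depths,
               reps = vapply(estimates, function(e) e@reps, integer(1)),
               mean = means, sd = sds, fold = means / ref,
               stringsAsFactors = FALSE, row.names = NULL)
}
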