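#' Read a feature set from BED
#'
#' Imports a BED file whose name column carries the feature class label
#' (e.g. `exon`, `5UTR`, `CpG-island`) into the `GRanges` shape the
#' enrichment functions expect.
#'
#' @param path BED file (0-based half-open; converted on import).
#' @return `GRanges` with a `class` metadata column.
#' @export
readFeaturesBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$name) || any(is.na(gr$name)) || any(!nzchar(gr$name)))
        stop("every BED record needs a class label in the name column")
    mcols(gr) <- DataFrame(class = gr$name)
    gr
}

#' Feature-class enrichment relative to random expectation
#'
#' For each feature class, computes the fraction of calls overlapping the
#' class by at least 1 bp (or the per-base fraction with
#' `perBase = TRUE`), the fraction expected under `nPlacements`
#' length-preserving uniform random re-placements of the same call
#' lengths (chromosome chosen proportional to length, start uniform;
#' assembly gaps excluded when a `gapMask` is supplied), the fold
#' enrichment observed/expected, and a Monte-Carlo interval on the fold
#' obtained by dividing the observed fraction by the 97.5 and 2.5
#' percentiles of the placement distribution. Classes are evaluated
#' independently: a call may count toward several.
#'
#' @param calls A [CallSet-class] or `GRanges` of calls.
#' @param features `GRanges` with a `class` metadata column.
#' @param genome Named `DNAStringSet` or named chromosome-length vector.
#' @param nPlacements Number of random placements (>= 100).
#' @param seed Integer seed for the placements.
#' @param gapMask Optional `GRanges` of assembly gaps to exclude.
#' @param perBase Use per-base overlap fractions instead of per-call.
#' @return An [EnrichmentResult-class].
#' @export
#' @examples
#' genome <- simulateGenome(1, 50000, seed = 1)
#' feats <- simulateFeatures(genome, "exon", n = 5, width = 1000, seed = 2)
#' calls <- simulateCircles(genome, n = 200, seed = 3)  # uniform placement
#' featureEnrichment(calls, feats, genome, nPlacements = 200, seed = 4)
featureEnrichment <- function(calls, features, genome, nPlacements = 1000L,
                              seed = 1L, gapMask = NULL, perBase = FALSE) {
    gr <- if (is(calls, "CallSet")) junctionCalls(calls) else calls
    stopifnot(is(gr, "GRanges"), is(features, "GRanges"),
              "class" %in% colnames(mcols(features)))
    if (length(gr) == 0L)
        stop("empty call set: nothing to characterize")
    nPlacements <- as.integer(nPlacements)
    if (nPlacements < 100L)
        stop("'nPlacements' must be at least 100")
    lens <- genomeLengths(genome)
    if (!all(as.character(seqnames(gr)) %in% names(lens)))
        stop("calls on chromosomes absent from the genome")
    w <- BiocGenerics::width(gr)
    nCalls <- length(gr)
    classes <- sort(unique(mcols(features)$class))

    frac <- function(ranges, cls) {
        sel <- features[mcols(features)$class == cls]
        if (perBase) {
            # per-range overlap bases (calls are not merged first, so the
            # observed and null fractions use the same definition)
            red <- reduce(granges(sel), ignore.strand = TRUE)
            hits <- findOverlaps(ranges, red, ignore.strand = TRUE)
            ovw <- BiocGenerics::width(IRanges::pintersect(
                IRanges::ranges(ranges)[S4Vectors::queryHits(hits)],
                IRanges::ranges(red)[S4Vectors::subjectHits(hits)]))
            sum(as.numeric(ovw)) /
                sum(as.numeric(BiocGenerics::width(ranges)))
        } else {
            mean(countOverlaps(ranges, sel, ignore.strand = TRUE) > 0L)
        }
    }
    observed <- vapply(classes, function(cls) frac(gr, cls), numeric(1))

    ## null: length-preserving placements
    nullFrac <- withSeed(seed, {
        out <- matrix(NA_real_, nrow = nPlacements, ncol = length(classes),
                      dimnames = list(NULL, classes))
        total <- nPlacements * nCalls
        chromIdx <- sample.int(length(lens), total, replace = TRUE,
                               prob = as.numeric(lens))
        chrom <- names(lens)[chromIdx]
        wAll <- rep(w, nPlacements)
        maxs <- pmax(lens[chromIdx] - wAll + 1L, 1L)
        starts <- as.integer(floor(runif(total) * maxs)) + 1L
        if (!is.null(gapMask)) {
            # re-place anything touching a gap (few iterations suffice for
            # realistic gap fractions)
            for (it in 1:20) {
                cand <- GRanges(chrom, IRanges(starts, width = wAll))
                bad <- countOverlaps(cand, gapMask,
                                     ignore.strand = TRUE) > 0L
                if (!any(bad)) break
                nbad <- sum(bad)
                ci <- sample.int(length(lens), nbad, replace = TRUE,
                                 prob = as.numeric(lens))
                chrom[bad] <- names(lens)[ci]
                mx <- pmax(lens[ci] - wAll[bad] + 1L, 1L)
                starts[bad] <- as.integer(floor(runif(nbad) * mx)) + 1L
            }
        }
        placed <- GRanges(chrom, IRanges(starts, width = wAll))
        placement <- rep(seq_len(nPlacements), each = nCalls)
        for (ci in seq_along(classes)) {
            sel <- features[mcols(features)$class == classes[ci]]
            if (perBase) {
                red <- reduce(granges(sel))
                hits <- findOverlaps(placed, red, ignore.strand = TRUE)
                ovw <- BiocGenerics::width(IRanges::pintersect(
                    IRanges::ranges(placed)[S4Vectors::queryHits(hits)],
                    IRanges::ranges(red)[S4Vectors::subjectHits(hits)]))
                num <- rowsum(c(ovw, rep(0, nPlacements)),
                              c(placement[S4Vectors::queryHits(hits)],
                                seq_len(nPlacements)))
                out[, ci] <- num[, 1] / sum(as.numeric(w))
            } else {
                hit <- countOverlaps(placed, sel, ignore.strand = TRUE) > 0L
                out[, ci] <- rowsum(as.numeric(hit), placement)[, 1] / nCalls
            }
        }
        out
    })
    expected <- colMeans(nullFrac)
    q025 <- apply(nullFrac, 2, quantile, probs = 0.025, names = FALSE)
    q975 <- apply(nullFrac, 2, quantile, probs = 0.975, names = FALSE)
    fold <- observed / expected
    if (any(expected == 0))
        warning("expected fraction 0 for class(es): ",
                paste(classes[expected == 0], collapse = ", "),
                "; fold reported as Inf")
    res <- DataFrame(class = classes,
                     observed = unname(observed),
                     expected = unname(expected),
                     fold = unname(fold),
                     lo = unname(observed / q975),
                     hi = unname(observed / q025),
                     n_calls = nCalls)
    new("EnrichmentResult", result = res,
        nPlacements = nPlacements, seed = as.integer(seed),
        perBase = perBase)
}

#' Length distribution profile with periodicity detection
#'
#' Bins call lengths into a histogram, finds modes as local maxima of a
#' kernel density estimate (prominence-filtered), and detects the dominant
#' length periodicity as the lag of the strongest significant positive
#' autocorrelation peak of the mean-subtracted histogram. MicroDNA length
#' distributions show peaks spaced by the nucleosome repeat (~180 bp);
#' this statistic makes that spacing a number.
#'
#' @param calls A [CallSet-class], `GRanges`, or an integer vector of
#'   lengths (bp).
#' @param binWidth Histogram bin width (bp), >= 1.
#' @param modeProminence Minimum density of a reported mode, as a fraction
#'   of the global density maximum.
#' @param minCallsForPeriod Below this number of calls periodicity is
#'   reported as undetermined (`NA`).
#' @return A [LengthProfile-class].
#' @export
#' @examples
#' lens <- round(c(rnorm(500, 180, 25), rnorm(300, 360, 25)))
#' lp <- lengthProfile(lens)
#' lengthModes(lp)
#' periodicity(lp)
lengthProfile <- function(calls, binWidth = 10L, modeProminence = 0.25,
                          minCallsForPeriod = 50L) {
    lengths <- if (is(calls, "CallSet"))
        BiocGenerics::width(junctionCalls(calls))
    else if (is(calls, "GRanges")) BiocGenerics::width(calls)
    else as.integer(calls)
    binWidth <- as.integer(binWidth)
    if (binWidth < 1L) stop("'binWidth' must be >= 1")
    if (length(lengths) == 0L) stop("no calls to profile")
    lengths <- as.integer(lengths)

    lo <- (min(lengths) %/% binWidth) * binWidth
    breaks <- seq(lo, max(lengths) + binWidth, by = binWidth)
    counts <- as.integer(table(cut(lengths, breaks, right = FALSE,
                                   include.lowest = TRUE)))
    hist <- data.frame(mid = breaks[-length(breaks)] + binWidth / 2,
                       count = counts)

    ## modes: KDE local maxima
    if (length(unique(lengths)) > 1L) {
        d <- density(lengths, bw = max(binWidth, stats::bw.nrd0(lengths)))
        y <- d$y
        isMax <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
        keep <- isMax & y >= modeProminence * max(y)
        modes <- d$x[keep]
    } else {
        modes <- as.numeric(unique(lengths))
    }

    ## periodicity: autocorrelation of the mean-subtracted histogram
    per <- NA_real_
    acfPeaks <- data.frame(lag_bp = numeric(0), acf = numeric(0))
    nb <- length(counts)
    if (length(lengths) >= minCallsForPeriod && nb >= 8L) {
        a <- acf(counts - mean(counts), lag.max = nb - 2L, plot = FALSE,
                 demean = FALSE)$acf[, 1, 1]
        lag <- seq_along(a) - 1L
        # local maxima at lag >= 2 bins
        cand <- which(diff(sign(diff(a))) < 0) + 1L
        cand <- cand[lag[cand] >= 2L & a[cand] > 0]
        thresh <- 2 / sqrt(nb)
        sig <- cand[a[cand] >= thresh]
        acfPeaks <- data.frame(lag_bp = lag[cand] * binWidth,
                               acf = a[cand])
        if (length(sig))
            per <- lag[sig[which.max(a[sig])]] * binWidth
    }
    new("LengthProfile", lengths = lengths, binWidth = binWidth,
        histogram = hist, modes = modes, periodicity = per,
        acfPeaks = acfPeaks)
}

#' GC content of called intervals
#'
#' Per-call GC fraction computed from the reference sequence of each call,
#' `(G + C) / (A + C + G + T)`; ambiguous bases (N) are excluded from the
#' denominator.
#'
#' @param calls A [CallSet-class] or `GRanges`.
#' @param genome Named `DNAStringSet` containing every call's chromosome.
#' @param onAllN What to do with calls whose sequence is entirely
#'   ambiguous: `"error"` (default) or `"exclude"` (drop with a warning).
#' @return A [GCProfile-class].
#' @export
#' @examples
#' genome <- simulateGenome(1, 50000, gc = 0.45, seed = 1)
#' calls <- simulateCircles(genome, n = 50, seed = 2)
#' gcProfile(calls, genome)
gcProfile <- function(calls, genome, onAllN = c("error", "exclude")) {
    onAllN <- match.arg(onAllN)
    gr <- if (is(calls, "CallSet")) junctionCalls(calls) else calls
    stopifnot(is(gr, "GRanges"), is(genome, "DNAStringSet"))
    if (length(gr) == 0L) stop("no calls to profile")
    chrom <- as.character(seqnames(gr))
    missing <- !(chrom %in% names(genome))
    if (any(missing))
        stop("call(s) on chromosome(s) absent from the genome: ",
             paste(unique(chrom[missing]), collapse = ", "))
    if (any(BiocGenerics::end(gr) > genomeLengths(genome)[chrom]))
        stop("call extends beyond its chromosome")
    seqs <- DNAStringSet(lapply(seq_along(gr), function(i) {
        subseq(genome[[chrom[i]]], BiocGenerics::start(gr)[i],
               BiocGenerics::end(gr)[i])
    }))
    gcCount <- letterFrequency(seqs, "GC")[, 1]
    acgt <- letterFrequency(seqs, "ACGT")[, 1]
    allN <- acgt == 0
    if (any(allN)) {
        if (onAllN == "error")
            stop(sum(allN), " call(s) consist entirely of ambiguous bases")
        warning(sum(allN), " all-ambiguous call(s) excluded")
    }
    gc <- ifelse(acgt > 0, gcCount / acgt, NA_real_)
    gc <- gc[!allN]
    new("GCProfile", gc = unname(gc),
        mean = mean(gc), median = median(gc))
}
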