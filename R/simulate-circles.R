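#' Default circle length mixture
#'
#' Gaussian mixture peaking at 180/360/540 bp, i.e. mono-, di- and
#' tri-nucleosome-sized circles: microDNA length distributions peak at
#' 200-400 bp with nucleosome-period spacing, and this mixture reproduces
#' that shape in the simulator.
#'
#' @param means,sds,weights Component means, SDs (bp) and weights
#'   (normalized internally).
#' @return `data.frame` with columns `mean`, `sd`, `weight`.
#' @export
#' @examples
#' defaultLengthModel()
defaultLengthModel <- function(means = c(180, 360, 540),
                               sds = c(30, 30, 30),
                               weights = c(0.5, 0.3, 0.2)) {
    stopifnot(length(means) == length(sds), length(means) == length(weights),
              all(sds > 0), all(weights > 0))
    data.frame(mean = means, sd = sds, weight = weights / sum(weights))
}

#' Mixture CDF of a length model
#'
#' @param q Lengths (bp).
#' @param lengthModel A `data.frame` as returned by [defaultLengthModel()].
#' @return CDF values; useful for goodness-of-fit checks of simulated sets.
#' @export
lengthModelCDF <- function(q, lengthModel = defaultLengthModel()) {
    rowSums(vapply(seq_len(nrow(lengthModel)), function(i) {
        lengthModel$weight[i] * pnorm(q, lengthModel$mean[i], lengthModel$sd[i])
    }, numeric(length(q))))
}

#' Simulate non-overlapping feature intervals
#'
#' Places `n` equally sized intervals of one class (e.g. exons) without
#' overlap on the genome; a convenience for constructing feature sets with
#' known genomic coverage in tests and demonstrations.
#'
#' @param genome Named `DNAStringSet` or named chromosome-length vector.
#' @param class Class label stored in the `class` metadata column.
#' @param n Number of intervals.
#' @param width Interval width (bp).
#' @param seed Integer seed.
#' @return `GRanges` with a `class` metadata column.
#' @export
#' @examples
#' genome <- simulateGenome(1, 50000, seed = 1)
#' simulateFeatures(genome, "exon", n = 5, width = 1000, seed = 2)
simulateFeatures <- function(genome, class = "exon", n = 10L, width = 1000L,
                             seed = 1L) {
    lens <- genomeLengths(genome)
    n <- as.integer(n); width <- as.integer(width)
    if (sum(lens %/% (2L * width)) < n)
        stop("genome too small to place ", n, " non-overlapping features")
    gr <- withSeed(seed, {
        res <- vector("list", n)
        placed <- GRanges()
        tries <- 0L
        k <- 0L
        while (k < n && tries < 50L * n) {
            tries <- tries + 1L
            chrom <- sample(names(lens), 1L, prob = as.numeric(lens))
            if (lens[[chrom]] < width) next
            s <- sample.int(lens[[chrom]] - width + 1L, 1L)
            cand <- GRanges(chrom, IRanges(s, s + width - 1L))
            if (length(placed) == 0L || !any(countOverlaps(cand, placed)))  {
                placed <- c(placed, cand)
                k <- k + 1L
            }
        }
        if (k < n) stop("could not place requested features without overlap")
        BiocGenerics::sort(placed)
    })
    mcols(gr)$class <- class
    seqlengths(gr) <- lens[seqlevels(gr)]
    gr
}

#' Simulate planted circles (ground-truth microDNA)
#'
#' Samples `n` circle loci on the genome. Lengths come from a Gaussian
#' mixture (`lengthModel`); start points are uniform per bp, or biased so
#' that a feature class with fold `f` is `f` times as likely per bp when
#' `featureBias` is given (emulating the genomic-feature enrichment seen in
#' real microDNA populations).
#'
#' @param genome Named `DNAStringSet` or named chromosome-length vector.
#' @param n Number of circles (0 gives an empty result).
#' @param lengthModel `data.frame(mean, sd, weight)`; see
#'   [defaultLengthModel()].
#' @param featureBias Optional `list(features = GRanges with a 'class'
#'   column, fold = named numeric)` giving the per-bp start-point weight
#'   multiplier for each class.
#' @param minLength Minimum circle length (bp); sampled lengths are
#'   truncated up to this floor.
#' @param copyNumber Template copy number given to every circle (positive
#'   integer, recycled), weighting read simulation.
#' @param seed Integer seed.
#' @return `GRanges` with metadata columns `circle_id` and `copy_number`.
#' @export
#' @examples
#' genome <- simulateGenome(1, 50000, seed = 1)
#' circles <- simulateCircles(genome, n = 100, seed = 3)
#' summary(BiocGenerics::width(circles))
simulateCircles <- function(genome, n, lengthModel = defaultLengthModel(),
                            featureBias = NULL, minLength = 50L,
                            copyNumber = 1L, seed = 1L) {
    lens <- genomeLengths(genome)
    n <- as.integer(n)
    if (n == 0L) {
        gr <- GRanges()
        mcols(gr)$circle_id <- character(0)
        mcols(gr)$copy_number <- integer(0)
        return(gr)
    }
    stopifnot(is.data.frame(lengthModel),
              all(c("mean", "sd", "weight") %in% colnames(lengthModel)))
    if (max(lens) < max(2L * minLength, 10L))
        stop("no chromosome can accommodate a circle")

    # per-bp start-point weight intervals (disjoint, one weight each)
    wivs <- startWeightIntervals(lens, featureBias)

    gr <- withSeed(seed, {
        comp <- sample.int(nrow(lengthModel), n, replace = TRUE,
                           prob = lengthModel$weight)
        len <- as.integer(pmax(minLength,
                               round(rnorm(n, lengthModel$mean[comp],
                                           lengthModel$sd[comp]))))
        if (any(len > max(lens)))
            stop("a sampled circle cannot fit on any chromosome; ",
                 "shrink the length model or enlarge the genome")
        # sample start intervals by weight mass, then uniform within;
        # draws whose circle would run off the chromosome end are
        # redrawn, so starts stay uniform over the valid positions
        drawPos <- function(k) {
            ividx <- sample.int(nrow(wivs), k, replace = TRUE,
                                prob = wivs$mass)
            list(pos = wivs$start[ividx] +
                     floor(runif(k) *
                               (wivs$end[ividx] - wivs$start[ividx] + 1L)),
                 chrom = wivs$chrom[ividx])
        }
        d <- drawPos(n)
        pos <- d$pos; chrom <- d$chrom
        for (it in 1:100) {
            bad <- pos > lens[chrom] - len + 1L
            if (!any(bad)) break
            rd <- drawPos(sum(bad))
            pos[bad] <- rd$pos
            chrom[bad] <- rd$chrom
        }
        if (any(pos > lens[chrom] - len + 1L))
            stop("a sampled circle cannot fit on its chromosome")
        GRanges(chrom, IRanges(start = as.integer(pos),
                               width = len))
    })
    mcols(gr)$circle_id <- sprintf("circle%04d", seq_len(n))
    mcols(gr)$copy_number <- as.integer(rep_len(copyNumber, n))
    if (any(mcols(gr)$copy_number < 1L))
        stop("'copyNumber' must be positive")
    seqlengths(gr) <- lens[seqlevels(gr)]
    gr
}

# Disjoint per-bp weight intervals for start-point sampling.
# Returns data.frame(chrom, start, end, weight, mass).
startWeightIntervals <- function(lens, featureBias) {
    base <- data.frame(chrom = names(lens), start = 1L,
                       end = as.integer(lens), weight = 1,
                       stringsAsFactors = FALSE)
    if (is.null(featureBias)) {
        base$mass <- base$weight * (base$end - base$start + 1)
        return(base)
    }
    stopifnot(is.list(featureBias),
              all(c("features", "fold") %in% names(featureBias)))
    feats <- featureBias$features
    fold <- featureBias$fold
    stopifnot(is(feats, "GRanges"), "class" %in% colnames(mcols(feats)),
              !is.null(names(fold)))
    gr <- GRanges(base$chrom, IRanges(base$start, base$end))
    pieces <- GenomicRanges::disjoin(c(gr, granges(feats)))
    w <- rep(1, length(pieces))
    for (cls in names(fold)) {
        sel <- feats[mcols(feats)$class == cls]
        if (length(sel))
            w[countOverlaps(pieces, sel) > 0] <-
                w[countOverlaps(pieces, sel) > 0] * fold[[cls]]
    }
    out <- data.frame(chrom = as.character(seqnames(pieces)),
                      start = BiocGenerics::start(pieces),
                      end = BiocGenerics::end(pieces),
                      weight = w, stringsAsFactors = FALSE)
    out$mass <- out$weight * (out$end - out$start + 1)
    out
}

#' Write circles as a 6-column truth BED
#'
#' BED is 0-based half-open: `chrom  start-1  end  circle_id  copy_number
#' strand`. Strand is `.` because circle templates are sequenced from both
#' strands.
#'
#' @param circles `GRanges` from [simulateCircles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTruthBed <- function(circles, path) {
    if (length(circles) == 0L) {
        writeLines(character(0), path)
        return(invisible(path))
    }
    df <- data.frame(
        chrom = as.character(seqnames(circles)),
        start = BiocGenerics::start(circles) - 1L,
        end = BiocGenerics::end(circles),
        name = mcols(circles)$circle_id,
        score = mcols(circles)$copy_number,
        strand = ".")
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
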