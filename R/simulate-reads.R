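#' Simulate paired-end reads from circular templates
#'
#' Emulates sequencing of a rolling-circle-amplified circle library.
#' Fragments are drawn on the infinite concatemer coordinate system of each
#' circle: a fragment starts at a uniform offset on the circle and may run
#' past the junction, so mates whose span crosses a multiple of the circle
#' length carry the junction. Mates face inward (FR). A configurable
#' fraction of pairs is drawn from the linear genome instead, standing in
#' for genomic contamination and exercising false-positive rejection.
#' Substitution errors are applied i.i.d. per base.
#'
#' Circles shorter than half the read length are skipped with a warning:
#' every mate from such a circle would cross the junction more than once
#' and can never satisfy the two-part split-read signature. Reads up to one
#' extra wrap (circle length < read length <= 2x circle length) are
#' simulated; they produce split alignments whose parts overlap on the
#' genome and pairs without any intact anchor mate, which is exactly why
#' short circles require shorter (re-sliced) reads to be called.
#'
#' @param genome Named `DNAStringSet`.
#' @param circles `GRanges` from [simulateCircles()] (metadata
#'   `circle_id`, `copy_number`).
#' @param readLength Read length (bp) of both mates.
#' @param fragmentMean,fragmentSd Fragment (insert) length model, bp;
#'   `fragmentMean` must exceed `readLength`. Draws below `readLength` are
#'   clamped up.
#' @param coverage Per-circle sequencing depth (fold); pairs per circle =
#'   `round(coverage * length * copy_number / (2 * readLength))`.
#' @param errorRate Per-base substitution probability in `[0, 0.1)`.
#' @param backgroundFraction Fraction of pairs drawn from the linear
#'   genome, in `[0, 1]`.
#' @param qualityDecay Optional `list(start =, rate =)`: Phred quality
#'   drops linearly by `rate` per cycle after position `start` (floor Q2),
#'   mimicking late-cycle quality decay; default is constant Q30.
#' @param seed Integer seed; identical inputs and seed give byte-identical
#'   output.
#' @return A [SimulatedReads-class] object.
#' @export
#' @examples
#' genome <- simulateGenome(1, 50000, seed = 1)
#' circles <- simulateCircles(genome, n = 20, seed = 2)
#' reads <- simulateReads(genome, circles, readLength = 100, coverage = 20,
#'                        seed = 3)
#' reads
simulateReads <- function(genome, circles, readLength = 150L,
                          fragmentMean = 300, fragmentSd = 30,
                          coverage = 50, errorRate = 0,
                          backgroundFraction = 0, qualityDecay = NULL,
                          seed = 1L) {
    stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
    readLength <- as.integer(readLength)
    if (fragmentMean <= readLength)
        stop("'fragmentMean' must exceed 'readLength'")
    if (errorRate < 0 || errorRate >= 0.1)
        stop("'errorRate' must lie in [0, 0.1)")
    if (backgroundFraction < 0 || backgroundFraction > 1)
        stop("'backgroundFraction' must lie in [0, 1]")
    lens <- genomeLengths(genome)

    cw <- if (length(circles)) BiocGenerics::width(circles) else integer(0)
    usable <- cw * 2L >= readLength
    if (length(circles) && any(!usable)) {
        warning(sum(!usable), " circle(s) skipped: read length ", readLength,
                " exceeds twice the circle length (",
                paste(utils::head(mcols(circles)$circle_id[!usable], 5),
                      collapse = ", "), ")")
    }
    circ <- circles[usable]
    cw <- cw[usable]
    cn <- if (length(circ)) mcols(circ)$copy_number else integer(0)

    pairsPer <- if (length(circ))
        as.integer(round(coverage * cw * cn / (2 * readLength))) else integer(0)
    nCirc <- sum(pairsPer)
    if (backgroundFraction >= 1) {
        nBg <- max(nCirc, 1L)
        pairsPer[] <- 0L
        nCirc <- 0L
    } else {
        nBg <- as.integer(round(nCirc * backgroundFraction /
                                    (1 - backgroundFraction)))
    }
    nTot <- nCirc + nBg

    sim <- withSeed(seed, {
        ## --- unified template table: one row per pair --------------------
        ## a circle pair lives on a circular template of length L;
        ## a background pair on a linear pseudo-template of length F.
        ci <- rep.int(seq_along(pairsPer), pairsPer)
        F_ <- pmax(readLength,
                   as.integer(round(rnorm(nTot, fragmentMean, fragmentSd))))
        src <- rep(c("circle", "background"), c(nCirc, nBg))
        tstrand <- sample(c("+", "-"), nTot, replace = TRUE)

        chrom <- character(nTot); ts <- integer(nTot); te <- integer(nTot)
        L <- integer(nTot); f <- integer(nTot); cid <- rep(NA_character_, nTot)
        if (nCirc) {
            idx <- seq_len(nCirc)
            chrom[idx] <- as.character(seqnames(circ))[ci]
            ts[idx] <- BiocGenerics::start(circ)[ci]
            te[idx] <- BiocGenerics::end(circ)[ci]
            L[idx] <- cw[ci]
            f[idx] <- as.integer(floor(runif(nCirc) * L[idx]))
            cid[idx] <- mcols(circ)$circle_id[ci]
        }
        if (nBg) {
            idx <- nCirc + seq_len(nBg)
            bgChrom <- sample(names(lens), nBg, replace = TRUE,
                              prob = as.numeric(lens))
            maxp <- lens[bgChrom] - F_[idx] + 1L
            if (any(maxp < 1L))
                stop("fragment longer than a chromosome; enlarge the genome")
            p <- as.integer(floor(runif(nBg) * maxp)) + 1L
            chrom[idx] <- bgChrom
            ts[idx] <- p
            te[idx] <- p + F_[idx] - 1L
            L[idx] <- F_[idx]
            f[idx] <- 0L
        }

        ## --- mate sequences ----------------------------------------------
        ## template sequence repeated enough times to cover f + F
        reps <- as.integer(ceiling((f + F_) / L))
        key <- paste(chrom, ts, te, tstrand, reps)
        ukey <- !duplicated(key)
        tmplCache <- new.env(parent = emptyenv())
        gchar <- stats::setNames(as.character(genome), names(genome))
        for (i in which(ukey)) {
            s <- substr(gchar[[chrom[i]]], ts[i], te[i])
            if (tstrand[i] == "-") s <- revcompChar(s)
            assign(key[i], paste(rep(s, reps[i]), collapse = ""),
                   envir = tmplCache)
        }
        tmpl <- vapply(key, function(k) get(k, envir = tmplCache),
                       character(1), USE.NAMES = FALSE)
        m1 <- substring(tmpl, f + 1L, f + readLength)
        m2 <- revcompChar(substring(tmpl, f + F_ - readLength + 1L, f + F_))

        ## --- sequencing errors -------------------------------------------
        if (errorRate > 0) {
            m1 <- injectErrors(m1, errorRate)
            m2 <- injectErrors(m2, errorRate)
        }

        a2 <- (f + F_ - readLength) %% L
        list(m1 = m1, m2 = m2,
             truth = DataFrame(
                 read_id = sprintf("sim%06d", seq_len(nTot)),
                 source = src, circle_id = cid, chrom = chrom,
                 tmpl_start = ts, tmpl_end = te, tmpl_strand = tstrand,
                 frag_offset = f, frag_length = F_,
                 m1_crosses = src == "circle" & (f + readLength) > L,
                 m2_crosses = src == "circle" & (a2 + readLength) > L))
    })

    qual <- qualityString(readLength, qualityDecay)
    mk <- function(x) {
        s <- DNAStringSet(x)
        names(s) <- sim$truth$read_id
        QualityScaledDNAStringSet(s, PhredQuality(rep(qual, length(x))))
    }
    new("SimulatedReads",
        mate1 = mk(sim$m1), mate2 = mk(sim$m2), truth = sim$truth,
        readLength = readLength,
        params = list(fragmentMean = fragmentMean, fragmentSd = fragmentSd,
                      coverage = coverage, errorRate = errorRate,
                      backgroundFraction = backgroundFraction,
                      qualityDecay = qualityDecay, seed = seed))
}

# i.i.d. substitution errors on a character vector of reads
injectErrors <- function(reads, rate) {
    n <- length(reads)
    if (!n) return(reads)
    rl <- nchar(reads[1])
    nerr <- rbinom(n, rl, rate)
    hit <- which(nerr > 0)
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
        pos <- sample.int(rl, nerr[i])
        chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
        for (p in pos) {
            chars[p] <- sample(setdiff(bases, chars[p]), 1L)
        }
        reads[i] <- paste(chars, collapse = "")
    }
    reads
}

qualityString <- function(readLength, qualityDecay) {
    q <- rep(30L, readLength)
    if (!is.null(qualityDecay)) {
        stopifnot(is.list(qualityDecay),
                  all(c("start", "rate") %in% names(qualityDecay)))
        pos <- seq_len(readLength)
        dec <- pmax(0, pos - qualityDecay$start) * qualityDecay$rate
        q <- pmax(2L, as.integer(round(30 - dec)))
    }
    rawToChar(as.raw(q + 33L))
}

#' Write simulated reads as paired FASTQ
#'
#' @param reads A [SimulatedReads-class] object.
#' @param prefix Output prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @return Character vector of the two paths, invisibly.
#' @export
writeReadsFastq <- function(reads, prefix) {
    p1 <- paste0(prefix, "_1.fastq")
    p2 <- paste0(prefix, "_2.fastq")
    writeXStringSet(reads@mate1, p1, format = "fastq",
                    qualities = quality(reads@mate1))
    writeXStringSet(reads@mate2, p2, format = "fastq",
                    qualities = quality(reads@mate2))
    invisible(c(p1, p2))
}

#' Write the simulation truth table as TSV
#'
#' @param reads A [SimulatedReads-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(reads, path) {
    write.table(as.data.frame(reads@truth), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
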