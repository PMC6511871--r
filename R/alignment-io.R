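#' Read paired-end alignments from SAM or BAM
#'
#' Loads every record (primary, supplementary and secondary) into a flat
#' segment table, one row per alignment record, with the soft-clip
#' geometry pre-computed so downstream split-read logic never re-parses
#' CIGAR strings. SAM input is converted through [Rsamtools::asBam()];
#' records violating the SAM specification (e.g. CIGAR query length not
#' matching the sequence) raise an error naming the offending read.
#'
#' @param path A `.sam` or `.bam` file.
#' @return `DataFrame` with one row per record: `qname`, `mate` (1 or 2),
#'   `chrom`, `start`, `end` (1-based reference interval), `strand`,
#'   `mapq`, `cigar`, `clipLeft`/`clipRight` (soft clips in SEQ
#'   orientation), `alignedWidth`, `qwidth`, `supplementary`, `secondary`,
#'   `sa` (SA tag or `NA`).
#' @export
#' @examples
#' genome <- simulateGenome(1, 50000, seed = 1)
#' circles <- simulateCircles(genome, n = 5, seed = 2)
#' reads <- simulateReads(genome, circles, readLength = 100, coverage = 10,
#'                        seed = 3)
#' sam <- tempfile(fileext = ".sam")
#' writeSam(oracleAlign(reads, genome), sam)
#' segs <- readAlignments(sam)
#' head(segs)
readAlignments <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        validateSamText(path)
        dest <- tempfile(fileext = "")
        bam <- tryCatch(
            Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE),
            error = function(e) stop("failed to parse '", path, "': ",
                                     conditionMessage(e), call. = FALSE))
    }
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "mapq", "seq"),
        tag = "SA",
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    gal <- tryCatch(
        GenomicAlignments::readGAlignments(bam, use.names = FALSE,
                                           param = param),
        error = function(e) stop("failed to read alignments from '", path,
                                 "': ", conditionMessage(e), call. = FALSE))
    md <- S4Vectors::mcols(gal)
    flag <- md$flag
    cigar <- GenomicAlignments::cigar(gal)
    # SAM spec: CIGAR query length must equal the stored sequence length
    seqw <- Biostrings::width(md$seq)
    cigw <- cigarQueryLength(cigar)
    bad <- seqw > 0L & cigw != seqw
    if (any(bad))
        stop("malformed record for read '", md$qname[which(bad)[1]],
             "': CIGAR query length ", cigw[which(bad)[1]],
             " != sequence length ", seqw[which(bad)[1]], call. = FALSE)
    clips <- cigarClips(cigar)
    sa <- md$SA
    if (is.null(sa)) sa <- rep(NA_character_, length(gal))
    out <- DataFrame(
        qname = md$qname,
        mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                      ifelse(bitwAnd(flag, 128L) > 0L, 2L, NA_integer_)),
        chrom = as.character(GenomeInfoDb::seqnames(gal)),
        start = BiocGenerics::start(gal),
        end = BiocGenerics::end(gal),
        strand = as.character(BiocGenerics::strand(gal)),
        mapq = md$mapq,
        cigar = cigar,
        clipLeft = clips$left,
        clipRight = clips$right,
        alignedWidth = cigarAlignedWidth(cigar),
        qwidth = cigarQueryLength(cigar),
        supplementary = bitwAnd(flag, 2048L) > 0L,
        secondary = bitwAnd(flag, 256L) > 0L,
        sa = as.character(sa))
    metadata(out) <- list(seqlengths = GenomeInfoDb::seqlengths(gal))
    out
}

# Up-front structural validation of SAM text: samtools silently drops
# records that violate the specification, but a malformed record should
# be an error naming the read, not a silent loss.
validateSamText <- function(path) {
    lines <- readLines(path, warn = FALSE)
    body <- lines[!startsWith(lines, "@")]
    if (!length(body)) return(invisible(TRUE))
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L))
        stop("malformed SAM record (fewer than 11 fields) for read '",
             fields[[which(nf < 11L)[1]]][1], "' in ", path, call. = FALSE)
    qname <- vapply(fields, `[`, character(1), 1L)
    cig <- vapply(fields, `[`, character(1), 6L)
    sq <- vapply(fields, `[`, character(1), 10L)
    check <- cig != "*" & sq != "*"
    if (any(check)) {
        cw <- cigarQueryLength(cig[check])
        bad <- cw != nchar(sq[check])
        if (any(bad)) {
            i <- which(check)[which(bad)[1]]
            stop("malformed SAM record for read '", qname[i],
                 "': CIGAR query length ", cigarQueryLength(cig[i]),
                 " != sequence length ", nchar(sq[i]), call. = FALSE)
        }
    }
    invisible(TRUE)
}

#' Re-slice reads to a shorter length
#'
#' Truncates every mate to its first `targetLength` bases (5'-anchored),
#' qualities included; the read count is unchanged. On real libraries this
#' removes unreliable late cycles; it also lets circles shorter than the
#' read length be called, because a shorter junctional read can fit both
#' split parts and an intact anchor mate on a small circle.
#'
#' @param x A [SimulatedReads-class] object.
#' @param targetLength New read length; must be positive and no longer
#'   than the current read length.
#' @return Object of the same kind with truncated reads (for
#'   `SimulatedReads`, junction-crossing truth flags are recomputed for
#'   the new length).
#' @export
#' @examples
#' genome <- simulateGenome(1, 50000, seed = 1)
#' circles <- simulateCircles(genome, n = 5, seed = 2)
#' reads <- simulateReads(genome, circles, readLength = 150, coverage = 10,
#'                        seed = 3)
#' readLength(resliceReads(reads, 75))
setGeneric("resliceReads", function(x, targetLength)
    standardGeneric("resliceReads"))

#' @rdname resliceReads
#' @export
setMethod("resliceReads", "SimulatedReads", function(x, targetLength) {
    targetLength <- as.integer(targetLength)
    if (is.na(targetLength) || targetLength <= 0L)
        stop("'targetLength' must be a positive integer")
    if (targetLength > x@readLength)
        stop("'targetLength' (", targetLength,
             ") exceeds the current read length (", x@readLength, ")")
    trim <- function(qs) {
        QualityScaledDNAStringSet(
            subseq(as(qs, "DNAStringSet"), 1L, targetLength),
            PhredQuality(subseq(quality(qs), 1L, targetLength)))
    }
    tr <- x@truth
    isC <- tr$source == "circle"
    L <- tr$tmpl_end - tr$tmpl_start + 1L
    L[!isC] <- tr$frag_length[!isC]
    a2 <- (tr$frag_offset + tr$frag_length - targetLength) %% L
    tr$m1_crosses <- isC & (tr$frag_offset + targetLength) > L
    tr$m2_crosses <- isC & (a2 + targetLength) > L
    new("SimulatedReads", mate1 = trim(x@mate1), mate2 = trim(x@mate2),
        truth = tr, readLength = targetLength, params = x@params)
})

#' Re-slice FASTQ files on disk
#'
#' File-level counterpart of [resliceReads()]: reads paired FASTQ,
#' truncates sequence and quality to the first `targetLength` bases, and
#' writes paired FASTQ.
#'
#' @param inPaths Character vector of the two input FASTQ paths.
#' @param targetLength New read length.
#' @param outPaths Character vector of the two output paths.
#' @return `outPaths`, invisibly.
#' @export
resliceFastq <- function(inPaths, targetLength, outPaths) {
    stopifnot(length(inPaths) == 2L, length(outPaths) == 2L)
    targetLength <- as.integer(targetLength)
    if (is.na(targetLength) || targetLength <= 0L)
        stop("'targetLength' must be a positive integer")
    for (i in 1:2) {
        # muffle the benign metadata-column note Biostrings emits when it
        # coerces FASTQ input
        qs <- withCallingHandlers(
            Biostrings::readQualityScaledDNAStringSet(inPaths[i]),
            warning = function(w) {
                if (grepl("metadata columns", conditionMessage(w)))
                    invokeRestart("muffleWarning")
            })
        if (targetLength > min(Biostrings::width(qs)))
            stop("'targetLength' exceeds the current read length")
        out <- IRanges::narrow(qs, 1L, targetLength)
        writeXStringSet(out, outPaths[i], format = "fastq",
                        qualities = quality(out))
    }
    invisible(outPaths)
}

#' Assemble candidate (anchor, split-read) pairs
#'
#' Pairs alignment records by read name and keeps only pairs in which
#' exactly one mate is split into exactly two parts (one primary plus one
#' supplementary record) while the other mate — the anchor — is a single
#' uniquely mapped full-length record with `mapq >= mapqMin` and no
#' secondary hits. Everything else is dropped with a categorized counter:
#' `no-split` (no junction evidence), `unpaired`, `both-split`,
#' `multi-split` (more than two parts, not a single circular junction),
#' `anchor-split` (the would-be anchor is clipped or split itself),
#' `low-mapq` (anchor below threshold or with secondary hits), and
#' `duplicate` (identical coordinates and CIGARs to an emitted pair,
#' collapsed by default because rolling-circle amplification makes
#' duplicate pairs likely and they would inflate junction support).
#'
#' @param segments `DataFrame` from [readAlignments()].
#' @param mapqMin Minimum anchor mapping quality (uniqueness proxy).
#' @param collapseDuplicates Collapse duplicate pairs?
#' @return List with `pairs` (`DataFrame`, one row per candidate pair),
#'   `counters` (named integer) and `nInputPairs`.
#' @export
assembleSplitPairs <- function(segments, mapqMin = 20L,
                               collapseDuplicates = TRUE) {
    seg <- as.data.frame(segments)
    counters <- c("no-split" = 0L, "unpaired" = 0L, "both-split" = 0L,
                  "multi-split" = 0L, "anchor-split" = 0L,
                  "low-mapq" = 0L, "duplicate" = 0L)
    emptyPairs <- DataFrame(
        qname = character(0), anchor_chrom = character(0),
        anchor_start = integer(0), anchor_end = integer(0),
        anchor_strand = character(0), anchor_mapq = integer(0),
        anchor_cigar = character(0),
        left_chrom = character(0), left_start = integer(0),
        left_end = integer(0), left_strand = character(0),
        left_alnw = integer(0), left_qstart = integer(0),
        left_cigar = character(0),
        right_chrom = character(0), right_start = integer(0),
        right_end = integer(0), right_strand = character(0),
        right_alnw = integer(0), right_qstart = integer(0),
        right_cigar = character(0))
    if (nrow(seg) == 0L)
        return(list(pairs = emptyPairs, counters = counters,
                    nInputPairs = 0L))
    if (anyNA(seg$mate))
        stop("unpaired (non paired-end) records present in input")

    hasSec <- seg$secondary
    secTab <- unique(seg[hasSec, c("qname", "mate")])
    seg <- seg[!hasSec, , drop = FALSE]

    ## order records within each mate by reference coordinate
    o <- order(seg$qname, seg$mate, seg$chrom, seg$start, seg$end)
    seg <- seg[o, , drop = FALSE]
    key <- paste0(seg$qname, "\r", seg$mate)
    gid <- cumsum(!duplicated(key))
    nrec <- tabulate(gid)
    first <- which(!duplicated(key))

    mateTab <- data.frame(
        qname = seg$qname[first], mate = seg$mate[first],
        gid = gid[first], n = nrec,
        stringsAsFactors = FALSE)
    mateTab$hasSecondary <- paste0(mateTab$qname, "\r", mateTab$mate) %in%
        paste0(secTab$qname, "\r", secTab$mate)
    fullClip <- seg$clipLeft[first] == 0L & seg$clipRight[first] == 0L
    mateTab$class <- ifelse(mateTab$n >= 3L, "multi",
                     ifelse(mateTab$n == 2L, "split2",
                     ifelse(fullClip, "full", "clipped")))
    mateTab$mapq <- seg$mapq[first]
    mateTab$chrom <- seg$chrom[first]
    mateTab$start <- seg$start[first]
    mateTab$end <- seg$end[first]
    mateTab$strand <- seg$strand[first]
    mateTab$cigar <- seg$cigar[first]

    ## two-part split details: rows are coordinate-sorted within the mate,
    ## so within a split2 group row 1 = left part, row 2 = right part
    rows2 <- which(gid %in% mateTab$gid[mateTab$class == "split2"])
    if (length(rows2)) {
        s2 <- seg[rows2, , drop = FALSE]
        leftIx <- seq(1L, nrow(s2), by = 2L)
        rightIx <- leftIx + 1L
        ## query offsets kept in SEQ (reference-forward) orientation: in
        ## that frame a deletion's parts are colinear and a circular
        ## junction's are inverted, on either strand
        qstart <- function(df) df$clipLeft
        splitTab <- data.frame(
            gid = gid[rows2][leftIx],
            left_chrom = s2$chrom[leftIx], left_start = s2$start[leftIx],
            left_end = s2$end[leftIx], left_strand = s2$strand[leftIx],
            left_alnw = s2$alignedWidth[leftIx],
            left_qstart = qstart(s2[leftIx, ]),
            left_cigar = s2$cigar[leftIx],
            right_chrom = s2$chrom[rightIx], right_start = s2$start[rightIx],
            right_end = s2$end[rightIx], right_strand = s2$strand[rightIx],
            right_alnw = s2$alignedWidth[rightIx],
            right_qstart = qstart(s2[rightIx, ]),
            right_cigar = s2$cigar[rightIx],
            stringsAsFactors = FALSE)
    } else {
        splitTab <- NULL
    }

    ## pair-level classification
    qn <- unique(mateTab$qname)
    m1 <- mateTab[match(paste0(qn, "\r1"),
                        paste0(mateTab$qname, "\r", mateTab$mate)), ]
    m2 <- mateTab[match(paste0(qn, "\r2"),
                        paste0(mateTab$qname, "\r", mateTab$mate)), ]
    nInput <- length(qn)

    isSplitish <- function(cl) !is.na(cl) & cl %in% c("split2", "multi")
    s1 <- isSplitish(m1$class); s2c <- isSplitish(m2$class)
    fate <- rep(NA_character_, nInput)
    fate[is.na(m1$class) | is.na(m2$class)] <- "unpaired"
    und <- is.na(fate)
    fate[und & s1 & s2c] <- "both-split"
    und <- is.na(fate)
    fate[und & !s1 & !s2c] <- "no-split"
    und <- is.na(fate)
    splitIsM1 <- s1
    splitClass <- ifelse(splitIsM1, m1$class, m2$class)
    anchorClass <- ifelse(splitIsM1, m2$class, m1$class)
    anchorMapq <- ifelse(splitIsM1, m2$mapq, m1$mapq)
    anchorSec <- ifelse(splitIsM1, m2$hasSecondary, m1$hasSecondary)
    fate[und & splitClass == "multi"] <- "multi-split"
    und <- is.na(fate)
    fate[und & anchorClass != "full"] <- "anchor-split"
    und <- is.na(fate)
    fate[und & (anchorSec | anchorMapq < mapqMin)] <- "low-mapq"
    emit <- is.na(fate)

    for (nm in names(counters))
        counters[nm] <- sum(fate == nm, na.rm = TRUE)

    if (!any(emit)) {
        return(list(pairs = emptyPairs, counters = counters,
                    nInputPairs = nInput))
    }

    anchor <- ifelse(splitIsM1, m2$gid, m1$gid)[emit]
    splitg <- ifelse(splitIsM1, m1$gid, m2$gid)[emit]
    aRow <- mateTab[match(anchor, mateTab$gid), ]
    sRow <- splitTab[match(splitg, splitTab$gid), ]
    pairs <- DataFrame(
        qname = qn[emit],
        anchor_chrom = aRow$chrom, anchor_start = aRow$start,
        anchor_end = aRow$end, anchor_strand = aRow$strand,
        anchor_mapq = aRow$mapq, anchor_cigar = aRow$cigar,
        left_chrom = sRow$left_chrom, left_start = sRow$left_start,
        left_end = sRow$left_end, left_strand = sRow$left_strand,
        left_alnw = sRow$left_alnw, left_qstart = sRow$left_qstart,
        left_cigar = sRow$left_cigar,
        right_chrom = sRow$right_chrom, right_start = sRow$right_start,
        right_end = sRow$right_end, right_strand = sRow$right_strand,
        right_alnw = sRow$right_alnw, right_qstart = sRow$right_qstart,
        right_cigar = sRow$right_cigar)

    if (collapseDuplicates && nrow(pairs) > 1L) {
        dupKey <- paste(pairs$anchor_chrom, pairs$anchor_start,
                        pairs$anchor_cigar, pairs$anchor_strand,
                        pairs$left_chrom, pairs$left_start, pairs$left_cigar,
                        pairs$right_chrom, pairs$right_start,
                        pairs$right_cigar)
        dup <- duplicated(dupKey)
        counters["duplicate"] <- sum(dup)
        pairs <- pairs[!dup, , drop = FALSE]
    }
    list(pairs = pairs, counters = counters, nInputPairs = nInput)
}
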