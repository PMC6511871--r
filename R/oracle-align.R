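#' Oracle-align simulated reads
#'
#' Computes exact SAM alignments for a [SimulatedReads-class] object from
#' its truth table instead of searching: positions follow from the known
#' template, fragment offset and strand of every pair. Mates that do not
#' cross a circle junction yield one full-length-match record; mates that
#' cross yield one record per junction part, the longest part as the
#' primary (the remainder soft-clipped) and each other part of at least
#' `minPart` aligned bases as a supplementary record, cross-referenced
#' through `SA` tags. Parts shorter than `minPart` are left as bare soft
#' clips with no supplementary record, mirroring how a seed-based aligner
#' drops sub-seed split segments. Substitution errors do not move
#' alignments, so this stands in for a BWA-MEM-style aligner on synthetic
#' data while remaining exactly right.
#'
#' @param reads A [SimulatedReads-class] object.
#' @param genome Named `DNAStringSet` the reads were simulated from (used
#'   for header lengths; sequences themselves come from the reads).
#' @param minPart Minimum aligned length (bp) of a split part for it to be
#'   reported as a supplementary record.
#' @param sortByCoord Sort records by (chromosome, position)? Header `SO`
#'   is set accordingly.
#' @param mapq Mapping quality written on every record.
#' @return A `DataFrame` of SAM records (one row per alignment record)
#'   with the header stored in `metadata()`; pass to [writeSam()].
#' @export
#' @examples
#' genome <- simulateGenome(1, 50000, seed = 1)
#' circles <- simulateCircles(genome, n = 5, seed = 2)
#' reads <- simulateReads(genome, circles, readLength = 100, coverage = 10,
#'                        seed = 3)
#' sam <- oracleAlign(reads, genome)
#' head(sam$cigar)
oracleAlign <- function(reads, genome, minPart = 20L, sortByCoord = TRUE,
                        mapq = 60L) {
    stopifnot(is(reads, "SimulatedReads"))
    lens <- genomeLengths(genome)
    tr <- reads@truth
    n <- nrow(tr)
    r <- reads@readLength
    empty <- DataFrame(qname = character(0), flag = integer(0),
                       rname = character(0), pos = integer(0),
                       mapq = integer(0), cigar = character(0),
                       rnext = character(0), pnext = integer(0),
                       tlen = integer(0), seq = character(0),
                       qual = character(0), tags = character(0))
    if (n == 0L) {
        metadata(empty) <- list(seqlengths = lens, sorted = sortByCoord)
        return(empty)
    }

    ## one row per mate
    L <- rep(tr$frag_length, 2L)          # background: template = fragment
    isC <- rep(tr$source == "circle", 2L)
    L[isC] <- rep(tr$tmpl_end - tr$tmpl_start + 1L, 2L)[isC]
    mate <- rep(1:2, each = n)
    f <- rep(tr$frag_offset, 2L)
    F_ <- rep(tr$frag_length, 2L)
    a <- ifelse(mate == 1L, f, (f + F_ - r) %% L)
    sigma <- rep(tr$tmpl_strand, 2L)
    s0 <- rep(tr$tmpl_start, 2L) - 1L
    e0 <- rep(tr$tmpl_end, 2L)
    e0[!isC] <- s0[!isC] + F_[!isC]       # background pseudo-template span
    chrom <- rep(tr$chrom, 2L)
    st <- ifelse(mate == 1L, sigma, c("+" = "-", "-" = "+")[sigma])
    readChar <- c(as.character(reads@mate1), as.character(reads@mate2))
    qualChar <- c(as.character(quality(reads@mate1)),
                  as.character(quality(reads@mate2)))

    ## decompose each mate span [a, a+r) at multiples of L (up to 3 parts)
    parts <- do.call(rbind, lapply(0:2, function(j) {
        tsU <- pmax(a, j * L)
        teU <- pmin(a + r, (j + 1L) * L)
        keep <- teU > tsU
        if (!any(keep)) return(NULL)
        data.frame(mrow = which(keep),
                   tp = (tsU - j * L)[keep], tq = (teU - j * L)[keep],
                   u = (tsU - a)[keep], v = (teU - a)[keep])
    }))
    parts <- parts[order(parts$mrow, parts$u), ]
    mr <- parts$mrow
    plus <- sigma[mr] == "+"
    gs <- ifelse(plus, s0[mr] + parts$tp, e0[mr] - parts$tq)   # 0-based
    ge <- ifelse(plus, s0[mr] + parts$tq, e0[mr] - parts$tp)
    qs <- ifelse(plus, parts$u, r - parts$v)                   # SEQ orient
    qlen <- parts$v - parts$u

    ## primary = longest part (ties: earliest in SEQ order)
    ord <- order(mr, -qlen, qs)
    firstOf <- !duplicated(mr[ord])
    isPrimary <- logical(nrow(parts))
    isPrimary[ord[firstOf]] <- TRUE
    emit <- isPrimary | qlen >= minPart

    pe <- parts[emit, , drop = FALSE]
    mrE <- mr[emit]; gsE <- gs[emit]; geE <- ge[emit]
    qsE <- qs[emit]; qlE <- qlen[emit]; prim <- isPrimary[emit]
    cig <- paste0(ifelse(qsE > 0L, paste0(qsE, "S"), ""),
                  qlE, "M",
                  ifelse(r - qsE - qlE > 0L,
                         paste0(r - qsE - qlE, "S"), ""))
    stE <- st[mrE]

    ## SA tags: other emitted parts of the same mate, in SEQ order
    saPiece <- paste0(chrom[mrE], ",", gsE + 1L, ",", stE, ",", cig, ",",
                      mapq, ",0;")
    tags <- character(length(mrE))
    byMate <- split(seq_along(mrE), mrE)
    for (idx in byMate) {
        if (length(idx) < 2L) next
        for (i in idx)
            tags[i] <- paste0("SA:Z:",
                              paste(saPiece[setdiff(idx, i)],
                                    collapse = ""))
    }

    ## primary position of each mate (for RNEXT/PNEXT of the other mate)
    primPos <- integer(2L * n)
    primPos[mrE[prim]] <- gsE[prim] + 1L
    otherRow <- ifelse(mate[mrE] == 1L, mrE + n, mrE - n)

    flag <- 1L + 2L +
        ifelse(mate[mrE] == 1L, 64L, 128L) +
        ifelse(stE == "-", 16L, 0L) +
        ifelse(st[otherRow] == "-", 32L, 0L) +
        ifelse(prim, 0L, 2048L)

    seqF <- ifelse(stE == "+", readChar[mrE], revcompChar(readChar[mrE]))
    qualF <- ifelse(stE == "+", qualChar[mrE],
                    vapply(qualChar[mrE], function(x)
                        paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                        character(1), USE.NAMES = FALSE))

    out <- DataFrame(
        qname = rep(tr$read_id, 2L)[mrE],
        flag = flag,
        rname = chrom[mrE],
        pos = gsE + 1L,
        mapq = as.integer(mapq),
        cigar = cig,
        rnext = "=",
        pnext = primPos[otherRow],
        tlen = 0L,
        seq = seqF,
        qual = qualF,
        tags = tags)
    if (sortByCoord) {
        ch <- factor(out$rname, levels = names(lens))
        out <- out[order(ch, out$pos), ]
    }
    metadata(out) <- list(seqlengths = lens, sorted = sortByCoord)
    out
}

#' Write SAM records to a file
#'
#' Emits a minimal spec-conformant SAM: `@HD` (with sort order), one `@SQ`
#' per chromosome, and the records produced by [oracleAlign()].
#'
#' @param sam `DataFrame` from [oracleAlign()].
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
writeSam <- function(sam, path) {
    md <- metadata(sam)
    lens <- md$seqlengths
    hd <- c(paste0("@HD\tVN:1.6\tSO:",
                   if (isTRUE(md$sorted)) "coordinate" else "unsorted"),
            paste0("@SQ\tSN:", names(lens), "\tLN:", as.integer(lens)),
            "@PG\tID:oracleAlign\tPN:microDNAseq")
    body <- paste(sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq,
                  sam$cigar, sam$rnext, sam$pnext, sam$tlen, sam$seq,
                  sam$qual, sep = "\t")
    hasTag <- nzchar(sam$tags)
    body[hasTag] <- paste(body[hasTag], sam$tags[hasTag], sep = "\t")
    writeLines(c(hd, body), path)
    invisible(path)
}
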