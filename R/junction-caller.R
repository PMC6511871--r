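#' Apply the circular-junction rules to candidate split pairs
#'
#' A candidate pair supports a circle if and only if: (a) both split parts
#' and the anchor lie on one chromosome; (b) both split parts have at
#' least `minPart` aligned bases; (c) the split parts share a strand;
#' (d) the anchor maps to the opposite strand; (e) the anchor lies between
#' the split parts' reference intervals, i.e. inside the span they
#' delimit; and (f) the query order of the parts is inverted relative to
#' their reference order: in the aligned (reference-forward, SEQ)
#' orientation the query-earlier part maps to the *right* reference
#' interval — the signature a ligated circle junction produces on either
#' strand, whereas colinear order is the signature of a deletion or
#' linear artifact and is rejected. An accepted pair calls
#' the circle `[leftmost base of the left part, rightmost base of the
#' right part]`.
#'
#' @param pairs `DataFrame` of candidate pairs from
#'   [assembleSplitPairs()].
#' @param minPart Minimum aligned length (bp) of each split part.
#' @param minCircleLength Minimum called circle length (bp).
#' @return `DataFrame` with one row per input pair: `qname`, `accepted`,
#'   `reason` (`NA` when accepted, otherwise one of `diff-chrom`,
#'   `short-part`, `split-strand-mismatch`, `anchor-strand`,
#'   `colinear-split`, `not-flanked`, `short-circle`), and for accepted
#'   pairs the call coordinates `chrom`, `start`, `end` (1-based,
#'   inclusive) plus `evidence_strand` (strand of the split read).
#' @export
callJunctions <- function(pairs, minPart = 20L, minCircleLength = 50L) {
    n <- nrow(pairs)
    reason <- rep(NA_character_, n)
    flag <- function(cond, why) {
        reason[is.na(reason) & cond] <<- why
    }
    sameChrom <- pairs$left_chrom == pairs$right_chrom &
        pairs$left_chrom == pairs$anchor_chrom
    flag(!sameChrom, "diff-chrom")
    flag(pairs$left_alnw < minPart | pairs$right_alnw < minPart,
         "short-part")
    flag(pairs$left_strand != pairs$right_strand, "split-strand-mismatch")
    flag(pairs$anchor_strand == pairs$left_strand, "anchor-strand")
    ## circular signature: the query-earlier part is the right ref part
    flag(pairs$left_qstart <= pairs$right_qstart, "colinear-split")
    flag(pairs$anchor_start < pairs$left_start |
             pairs$anchor_end > pairs$right_end, "not-flanked")
    start <- pairs$left_start
    end <- pairs$right_end
    flag(end - start + 1L < minCircleLength, "short-circle")
    acc <- is.na(reason)
    DataFrame(qname = pairs$qname,
              accepted = acc,
              reason = reason,
              chrom = ifelse(acc, pairs$left_chrom, NA_character_),
              start = ifelse(acc, start, NA_integer_),
              end = ifelse(acc, end, NA_integer_),
              evidence_strand = ifelse(acc, pairs$left_strand,
                                       NA_character_))
}

#' Deduplicate junction calls into a unique call table
#'
#' Calls identical on (chrom, start, end) — or within `mergeTolerance` bp
#' of a cluster's seed call on both edges — are merged; support is summed
#' and, for tolerance > 0, the representative coordinates are the
#' support-weighted mode (ties to the smallest coordinates). Output order
#' is deterministic: (chrom, start, end).
#'
#' @param calls `DataFrame`/`data.frame` with columns `chrom`, `start`,
#'   `end` and optionally `support` (default 1 per row) and
#'   `evidence_strand`.
#' @param mergeTolerance Non-negative merge tolerance in bp; 0 (default)
#'   keeps base-pair-exact identity.
#' @return `data.frame` with `chrom`, `start`, `end`, `support`,
#'   `strand_evidence` (collapsed summary such as `"+:3,-:2"`).
#' @export
deduplicateCalls <- function(calls, mergeTolerance = 0L) {
    if (mergeTolerance < 0) stop("'mergeTolerance' must be >= 0")
    calls <- as.data.frame(calls)
    if (nrow(calls) == 0L) {
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), support = integer(0),
                          strand_evidence = character(0),
                          stringsAsFactors = FALSE))
    }
    if (is.null(calls$support)) calls$support <- 1L
    if (is.null(calls$evidence_strand))
        calls$evidence_strand <- NA_character_
    o <- order(calls$chrom, calls$start, calls$end)
    calls <- calls[o, , drop = FALSE]

    ## cluster: new cluster when outside tolerance of the cluster seed
    cl <- integer(nrow(calls))
    cl[1] <- 1L
    seedS <- calls$start[1]; seedE <- calls$end[1]; seedC <- calls$chrom[1]
    for (i in seq_len(nrow(calls))[-1]) {
        if (calls$chrom[i] == seedC &&
            abs(calls$start[i] - seedS) <= mergeTolerance &&
            abs(calls$end[i] - seedE) <= mergeTolerance) {
            cl[i] <- cl[i - 1L]
        } else {
            cl[i] <- cl[i - 1L] + 1L
            seedS <- calls$start[i]; seedE <- calls$end[i]
            seedC <- calls$chrom[i]
        }
    }
    merged <- lapply(split(seq_len(nrow(calls)), cl), function(ix) {
        sub <- calls[ix, , drop = FALSE]
        agg <- stats::aggregate(support ~ start + end, data = sub, FUN = sum)
        best <- agg[order(-agg$support, agg$start, agg$end)[1], ]
        coords <- c(best$start, best$end)
        strands <- table(sub$evidence_strand[!is.na(sub$evidence_strand)])
        data.frame(chrom = sub$chrom[1], start = coords[1],
                   end = coords[2], support = sum(sub$support),
                   strand_evidence = if (length(strands))
                       paste(names(strands), as.integer(strands),
                             sep = ":", collapse = ",") else NA_character_,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, merged)
    out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Run the full microDNA junction caller
#'
#' End-to-end composition: read alignments, assemble candidate
#' (anchor, split-read) pairs, apply the junction rules, and deduplicate
#' into a unique call set with per-call split-read support.
#'
#' @param input A SAM/BAM path, or a segment `DataFrame` from
#'   [readAlignments()].
#' @param mapqMin Minimum anchor mapping quality.
#' @param minPart Minimum aligned length (bp) of each split part.
#' @param minCircleLength Minimum called circle length (bp).
#' @param mergeTolerance Dedup merge tolerance (bp); 0 = base-pair exact.
#' @param minSupport Drop calls with fewer supporting pairs (default 0:
#'   keep everything).
#' @param collapseDuplicates Collapse duplicate read pairs before calling.
#' @return A [CallSet-class].
#' @export
#' @examples
#' genome <- simulateGenome(1, 50000, seed = 1)
#' circles <- simulateCircles(genome, n = 10, seed = 2)
#' reads <- simulateReads(genome, circles, readLength = 100, coverage = 30,
#'                        seed = 3)
#' sam <- tempfile(fileext = ".sam")
#' writeSam(oracleAlign(reads, genome), sam)
#' runCaller(sam)
runCaller <- function(input, mapqMin = 20L, minPart = 20L,
                      minCircleLength = 50L, mergeTolerance = 0L,
                      minSupport = 0L, collapseDuplicates = TRUE) {
    segments <- if (is.character(input)) readAlignments(input) else input
    asm <- assembleSplitPairs(segments, mapqMin = mapqMin,
                              collapseDuplicates = collapseDuplicates)
    verdicts <- callJunctions(asm$pairs, minPart = minPart,
                              minCircleLength = minCircleLength)
    counters <- asm$counters
    if (nrow(verdicts)) {
        rej <- table(verdicts$reason[!verdicts$accepted])
        if (length(rej)) {
            add <- stats::setNames(as.integer(rej), names(rej))
            counters <- c(counters, add)
        }
    }
    accepted <- verdicts[verdicts$accepted, , drop = FALSE]
    dedup <- deduplicateCalls(accepted, mergeTolerance = mergeTolerance)
    dedup <- dedup[dedup$support >= minSupport, , drop = FALSE]
    gr <- if (nrow(dedup)) {
        g <- GRanges(dedup$chrom, IRanges(dedup$start, dedup$end))
        mcols(g)$call_id <- sprintf("call%05d", seq_len(nrow(dedup)))
        mcols(g)$support <- dedup$support
        mcols(g)$strand_evidence <- dedup$strand_evidence
        sl <- metadata(segments)$seqlengths
        if (!is.null(sl) && all(seqlevels(g) %in% names(sl)))
            seqlengths(g) <- sl[seqlevels(g)]
        g
    } else {
        g <- GRanges()
        mcols(g)$call_id <- character(0)
        mcols(g)$support <- integer(0)
        mcols(g)$strand_evidence <- character(0)
        g
    }
    new("CallSet",
        calls = gr,
        nInputPairs = asm$nInputPairs,
        nSupportingPairs = as.integer(nrow(accepted)),
        dropCounts = counters,
        params = list(mapqMin = mapqMin, minPart = minPart,
                      minCircleLength = minCircleLength,
                      mergeTolerance = mergeTolerance,
                      minSupport = minSupport,
                      collapseDuplicates = collapseDuplicates))
}

#' Write a CallSet to disk
#'
#' Writes three text artifacts: a BED6+1 of the calls (0-based half-open;
#' `score` is the support capped at 1000 per BED convention, column 7 the
#' uncapped support), a TSV of drop/rejection counters, and a JSON
#' provenance record of the caller parameters and counts.
#'
#' @param callSet A [CallSet-class].
#' @param prefix Output path prefix; writes `<prefix>.bed`,
#'   `<prefix>.rejections.tsv`, `<prefix>.provenance.json`.
#' @return Character vector of paths, invisibly.
#' @export
writeCallSet <- function(callSet, prefix) {
    gr <- callSet@calls
    bed <- paste0(prefix, ".bed")
    df <- data.frame(
        chrom = as.character(seqnames(gr)),
        start = BiocGenerics::start(gr) - 1L,
        end = BiocGenerics::end(gr),
        name = mcols(gr)$call_id,
        score = pmin(mcols(gr)$support, 1000L),
        strand = ".",
        support = mcols(gr)$support)
    write.table(df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    rejTsv <- paste0(prefix, ".rejections.tsv")
    write.table(data.frame(reason = names(callSet@dropCounts),
                           n = as.integer(callSet@dropCounts)),
                rejTsv, sep = "\t", quote = FALSE, row.names = FALSE)
    prov <- paste0(prefix, ".provenance.json")
    jsonlite::write_json(
        list(params = callSet@params,
             n_input_pairs = callSet@nInputPairs,
             n_supporting_pairs = callSet@nSupportingPairs,
             n_calls = length(gr),
             drop_counts = as.list(callSet@dropCounts)),
        prov, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(c(bed, rejTsv, prov))
}
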