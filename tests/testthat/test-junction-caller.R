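# A constructed candidate pair matching the 400 bp circle chr1:1001-1400
# (1-based): split parts [1001,1050] and [1301,1400] with the query-later
# part on the left (inverted order), anchor [1151,1300] on the other
# strand, inside the parts' span.
constructedPair <- function(...) {
    base <- list(
        qname = "p1",
        anchor_chrom = "chr1", anchor_start = 1151L, anchor_end = 1300L,
        anchor_strand = "-", anchor_mapq = 60L, anchor_cigar = "150M",
        left_chrom = "chr1", left_start = 1001L, left_end = 1050L,
        left_strand = "+", left_alnw = 50L, left_qstart = 100L,
        left_cigar = "100S50M",
        right_chrom = "chr1", right_start = 1301L, right_end = 1400L,
        right_strand = "+", right_alnw = 100L, right_qstart = 0L,
        right_cigar = "100M50S")
    mods <- list(...)
    base[names(mods)] <- mods
    do.call(S4Vectors::DataFrame, base)
}

test_that("the circular-junction geometry is accepted with exact coordinates", {
    v <- callJunctions(constructedPair())
    expect_true(v$accepted)
    expect_identical(v$chrom, "chr1")
    expect_identical(v$start, 1001L)
    expect_identical(v$end, 1400L)
})

test_that("each geometric/polarity violation is rejected with its reason", {
    reject <- function(pair, why) {
        v <- callJunctions(pair)
        expect_false(v$accepted)
        expect_identical(v$reason, why)
    }
    reject(constructedPair(anchor_chrom = "chr2"), "diff-chrom")
    reject(constructedPair(left_alnw = 10L), "short-part")
    reject(constructedPair(left_strand = "-"), "split-strand-mismatch")
    reject(constructedPair(anchor_strand = "+"), "anchor-strand")
    # colinear query order = deletion signature, not a circle
    reject(constructedPair(left_qstart = 0L, right_qstart = 100L),
           "colinear-split")
    # anchor outside the parts' span
    reject(constructedPair(anchor_start = 1501L, anchor_end = 1650L),
           "not-flanked")
    reject(constructedPair(right_start = 1021L, right_end = 1040L,
                           anchor_start = 1005L, anchor_end = 1039L),
           "short-circle")
})

test_that("deduplication merges exact and near-identical calls correctly", {
    calls <- data.frame(chrom = "chr1",
                        start = c(rep(1001L, 54), rep(1001L, 3)),
                        end = c(rep(1400L, 54), rep(1401L, 3)),
                        support = 1L)
    d0 <- deduplicateCalls(calls, mergeTolerance = 0)
    expect_identical(nrow(d0), 2L)
    expect_identical(d0$support, c(54L, 3L))
    d1 <- deduplicateCalls(calls, mergeTolerance = 1)
    expect_identical(nrow(d1), 1L)
    expect_identical(d1$support, 57L)
    # representative is the support-weighted mode
    expect_identical(d1$end, 1400L)
    empty <- deduplicateCalls(data.frame(), mergeTolerance = 0)
    expect_identical(nrow(empty), 0L)
})

test_that("caller is exact and complete on a noise-free oracle library", {
    lib <- stdLibrary()
    cs <- runCaller(lib$sam)
    truthKeys <- grKey(lib$circles)
    callKeys <- grKey(junctionCalls(cs))
    # soundness: no call outside the planted truth
    expect_identical(sum(!(callKeys %in% truthKeys)), 0L)
    # completeness: every circle with >= 1 eligible pair is called exactly
    eligible <- eligibleCirclesFromTruth(truthTable(lib$reads), r = 150)
    ids <- S4Vectors::mcols(lib$circles)$circle_id
    expect_true(all(truthKeys[ids %in% eligible] %in% callKeys))
    # support conservation
    expect_identical(sum(S4Vectors::mcols(junctionCalls(cs))$support),
                     nSupportingPairs(cs))
})

test_that("a background-only library yields an empty call set", {
    genome <- simulateGenome(1, 50000, gc = 0.45, seed = 71)
    circles <- simulateCircles(genome, n = 10, seed = 72)
    reads <- simulateReads(genome, circles, readLength = 100,
                           coverage = 20, backgroundFraction = 1,
                           seed = 73)
    f <- tempfile(fileext = ".sam")
    writeSam(oracleAlign(reads, genome), f)
    cs <- runCaller(f)
    expect_length(junctionCalls(cs), 0)
    expect_identical(nSupportingPairs(cs), 0L)
})

test_that("raising mapq or minPart thresholds never increases the call count", {
    lib <- noisyLibrary()
    segs <- readAlignments(lib$sam)
    nCalls <- function(...) length(junctionCalls(runCaller(segs, ...)))
    base <- nCalls()
    expect_lte(nCalls(minPart = 30L), base)
    expect_lte(nCalls(minPart = 45L), nCalls(minPart = 30L))
    expect_lte(nCalls(mapqMin = 61L), base)
    expect_identical(nCalls(mapqMin = 61L), 0L)
    expect_lte(nCalls(minSupport = 2L), base)
})

test_that("relabeling all strands leaves call coordinates unchanged", {
    lib <- noisyLibrary()
    flipped <- tempfile(fileext = ".sam")
    flipSamStrands(lib$sam, flipped)
    cs1 <- runCaller(lib$sam)
    cs2 <- runCaller(flipped)
    expect_identical(grKey(junctionCalls(cs1)), grKey(junctionCalls(cs2)))
    expect_identical(S4Vectors::mcols(junctionCalls(cs1))$support,
                     S4Vectors::mcols(junctionCalls(cs2))$support)
})

test_that("re-slicing rescues a circle shorter than the read length", {
    genome <- simulateGenome(1, 50000, gc = 0.45, seed = 81)
    small <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20001, 20120))
    S4Vectors::mcols(small)$circle_id <- "small120"
    S4Vectors::mcols(small)$copy_number <- 1L
    big <- simulateCircles(genome, n = 10,
                           lengthModel = defaultLengthModel(400, 20, 1),
                           seed = 82)
    circles <- c(big, small)
    reads <- simulateReads(genome, circles, readLength = 150,
                           coverage = 50, errorRate = 0, seed = 83)
    f150 <- tempfile(fileext = ".sam")
    writeSam(oracleAlign(reads, genome), f150)
    cs150 <- runCaller(f150)
    key <- "chr1 20001 20120"
    expect_false(key %in% grKey(junctionCalls(cs150)))
    r75 <- resliceReads(reads, 75)
    f75 <- tempfile(fileext = ".sam")
    writeSam(oracleAlign(r75, genome), f75)
    cs75 <- runCaller(f75)
    expect_true(key %in% grKey(junctionCalls(cs75)))
})

test_that("the caller is byte-reproducible end to end", {
    lib <- noisyLibrary()
    p1 <- tempfile(); p2 <- tempfile()
    writeCallSet(runCaller(lib$sam), p1)
    writeCallSet(runCaller(lib$sam), p2)
    expect_identical(readLines(paste0(p1, ".bed")),
                     readLines(paste0(p2, ".bed")))
    bed <- read.table(paste0(p1, ".bed"), sep = "\t")
    gr <- junctionCalls(runCaller(lib$sam))
    expect_identical(bed$V2, BiocGenerics::start(gr) - 1L)  # 0-based BED
    expect_identical(bed$V7, S4Vectors::mcols(gr)$support)
})
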