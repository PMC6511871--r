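# Shared synthetic fixtures and independent truth-side oracles.
# Everything is generated in code at test time; nothing is read from disk.

# lazily built, memoized fixtures (kept small so the suite stays fast)
.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (!exists(name, envir = .fixtureCache))
        assign(name, builder(), envir = .fixtureCache)
    get(name, envir = .fixtureCache)
}

# standard oracle-aligned library: 100 kb genome, 200 circles, 50x, no noise
stdLibrary <- function() {
    fixture("std", function() {
        genome <- simulateGenome(1, 100000, gc = 0.45, seed = 101)
        circles <- simulateCircles(genome, n = 200, seed = 102)
        reads <- simulateReads(genome, circles, readLength = 150,
                               coverage = 50, errorRate = 0, seed = 103)
        sam <- tempfile(fileext = ".sam")
        writeSam(oracleAlign(reads, genome), sam)
        list(genome = genome, circles = circles, reads = reads, sam = sam)
    })
}

# small noisy library with linear background
noisyLibrary <- function() {
    fixture("noisy", function() {
        genome <- simulateGenome(1, 100000, gc = 0.45, seed = 201)
        circles <- simulateCircles(genome, n = 60, seed = 202)
        reads <- simulateReads(genome, circles, readLength = 100,
                               coverage = 30, errorRate = 0.005,
                               backgroundFraction = 0.2, seed = 203)
        sam <- tempfile(fileext = ".sam")
        writeSam(oracleAlign(reads, genome), sam)
        list(genome = genome, circles = circles, reads = reads, sam = sam)
    })
}

# Equal-abundance library for closed-form complexity comparisons:
# 50 circles of ~300 bp at 10x, 100 bp reads, no noise.
complexityLibrary <- function() {
    fixture("cxlib", function() {
        genome <- simulateGenome(1, 100000, gc = 0.45, seed = 91)
        circles <- simulateCircles(
            genome, n = 50,
            lengthModel = defaultLengthModel(300, 15, 1), seed = 92)
        reads <- simulateReads(genome, circles, readLength = 100,
                               coverage = 10, errorRate = 0, seed = 93)
        sam <- tempfile(fileext = ".sam")
        writeSam(oracleAlign(reads, genome), sam)
        segs <- readAlignments(sam)
        # per-junction support, computed once for the closed form
        asm <- assembleSplitPairs(segs, collapseDuplicates = FALSE)
        v <- callJunctions(asm$pairs)
        acc <- as.data.frame(v[v$accepted, ])
        supp <- as.integer(table(paste(acc$chrom, acc$start, acc$end)))
        list(genome = genome, circles = circles, segs = segs,
             support = supp, nPairs = length(unique(segs$qname)))
    })
}

# Exact mean and SD of the unique-junction count when d of N pairs are
# drawn without replacement and junction i is supported by m[i] disjoint
# pairs: P(i seen) = 1 - C(N-m_i,d)/C(N,d); the variance adds the pairwise
# joint-miss terms C(N-m_i-m_j,d)/C(N,d).
hypergeomUniqueMoments <- function(m, N, d) {
    q <- exp(lchoose(N - m, d) - lchoose(N, d))          # P(miss i)
    p <- 1 - q
    qq <- exp(lchoose(N - outer(m, m, "+"), d) - lchoose(N, d))
    pij <- 1 - outer(q, q, "+") + qq                     # P(both seen), i != j
    cov <- pij - outer(p, p)
    diag(cov) <- 0
    v <- sum(p * q) + sum(cov)
    list(mean = sum(p), sd = sqrt(max(v, 0)))
}

# "chrom start end" keys
grKey <- function(gr) {
    paste(as.character(GenomeInfoDb::seqnames(gr)),
          BiocGenerics::start(gr), BiocGenerics::end(gr))
}

# Independent eligibility oracle, computed purely from truth-table
# geometry (modular arithmetic on fragment offsets), not from the caller:
# a pair is eligible evidence for its circle when exactly one mate crosses
# the junction exactly once with both parts >= minPart aligned bases and
# the other mate does not cross at all.
eligibleCirclesFromTruth <- function(truth, r, minPart = 20,
                                     minCircle = 50) {
    tr <- as.data.frame(truth)
    tr <- tr[tr$source == "circle", , drop = FALSE]
    L <- tr$tmpl_end - tr$tmpl_start + 1
    a1 <- tr$frag_offset
    a2 <- (tr$frag_offset + tr$frag_length - r) %% L
    ncross <- function(a) (a + r - 1) %/% L
    partsOK <- function(a) pmin(L - a, a + r - L) >= minPart
    e1 <- ncross(a1) == 1 & partsOK(a1) & ncross(a2) == 0
    e2 <- ncross(a2) == 1 & partsOK(a2) & ncross(a1) == 0
    ok <- (e1 | e2) & L >= minCircle
    unique(tr$circle_id[ok])
}

# flip every strand label (+ <-> -) in a SAM file: xor flag bits 0x10/0x20
flipSamStrands <- function(inSam, outSam) {
    lines <- readLines(inSam)
    isBody <- !startsWith(lines, "@")
    fields <- strsplit(lines[isBody], "\t")
    flipped <- vapply(fields, function(f) {
        f[2] <- as.character(bitwXor(as.integer(f[2]), 48L))
        paste(f, collapse = "\t")
    }, character(1))
    writeLines(c(lines[!isBody], flipped), outSam)
    outSam
}
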