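test_that("uniformly placed calls show fold ~1 for a 10% feature class", {
    genome <- simulateGenome(1, 100000, gc = 0.45, seed = 111)
    feats <- simulateFeatures(genome, "exon", n = 5, width = 2000,
                              seed = 112)
    calls <- simulateCircles(genome, n = 1000, seed = 113)
    er <- featureEnrichment(calls, feats, genome, nPlacements = 200,
                            seed = 114)
    tab <- enrichmentTable(er)
    # single run: within 4 binomial SDs of fold 1
    p <- tab$expected
    tol <- 4 * sqrt(p * (1 - p) / 1000) / p
    expect_lt(abs(tab$fold - 1), tol)
    expect_true(tab$lo <= 1 && 1 <= tab$hi)
})

test_that("a class covering the whole genome gives fold exactly 1", {
    genome <- simulateGenome(1, 100000, gc = 0.45, seed = 111)
    all <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
    S4Vectors::mcols(all)$class <- "everything"
    calls <- simulateCircles(genome, n = 100, seed = 115)
    er <- featureEnrichment(calls, all, genome, nPlacements = 100,
                            seed = 116)
    tab <- enrichmentTable(er)
    expect_identical(tab$observed, 1)
    expect_identical(tab$expected, 1)
    expect_identical(tab$fold, 1)
})

test_that("a planted start-point bias is recovered as overlap-fold enrichment", {
    genome <- simulateGenome(1, 100000, gc = 0.45, seed = 121)
    feats <- simulateFeatures(genome, "exon", n = 5, width = 2000,
                              seed = 122)
    calls <- simulateCircles(genome, n = 1000,
                             featureBias = list(features = feats,
                                                fold = c(exon = 4)),
                             seed = 123)
    er <- featureEnrichment(calls, feats, genome, nPlacements = 300,
                            seed = 124)
    tab <- enrichmentTable(er)
    # brute-force enumeration of the expected overlap fold on this genome:
    # start-point weight 4 inside exons, 1 outside; a call of width w
    # overlaps an exon iff its start falls in [exon start - w + 1, end]
    w <- BiocGenerics::width(calls)
    enumFold <- local({
        glen <- 100000
        inEx <- rep(FALSE, glen)
        for (i in seq_along(feats))
            inEx[BiocGenerics::start(feats)[i]:BiocGenerics::end(feats)[i]] <-
                TRUE
        weight <- ifelse(inEx, 4, 1)
        pOv <- function(wi, wt) {
            ov <- rep(FALSE, glen)
            for (i in seq_along(feats)) {
                lo <- max(1, BiocGenerics::start(feats)[i] - wi + 1)
                ov[lo:BiocGenerics::end(feats)[i]] <- TRUE
            }
            sum(wt[ov]) / sum(wt)
        }
        wu <- sort(unique(w))
        biased <- vapply(wu, pOv, numeric(1), wt = weight)
        unif <- vapply(wu, pOv, numeric(1), wt = rep(1, glen))
        tabw <- table(factor(w, levels = wu))
        sum(biased * tabw) / sum(unif * tabw)
    })
    expect_gt(tab$fold, 1.5)                      # clearly enriched
    expect_lt(abs(tab$fold - enumFold) / enumFold, 0.25)
    expect_true(tab$lo <= enumFold && enumFold <= tab$hi)
})

test_that("per-base enrichment agrees with per-call on saturated classes", {
    genome <- simulateGenome(1, 100000, gc = 0.45, seed = 111)
    all <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
    S4Vectors::mcols(all)$class <- "everything"
    calls <- simulateCircles(genome, n = 50, seed = 117)
    er <- featureEnrichment(calls, all, genome, nPlacements = 100,
                            seed = 118, perBase = TRUE)
    expect_identical(enrichmentTable(er)$fold, 1)
})

test_that("enrichment rejects empty call sets and tiny placement counts", {
    genome <- simulateGenome(1, 100000, gc = 0.45, seed = 111)
    feats <- simulateFeatures(genome, "exon", n = 2, width = 500,
                              seed = 119)
    empty <- GenomicRanges::GRanges()
    expect_error(featureEnrichment(empty, feats, genome), "empty")
    calls <- simulateCircles(genome, n = 10, seed = 120)
    expect_error(featureEnrichment(calls, feats, genome,
                                   nPlacements = 10), "100")
})

test_that("the nucleosome-spaced mixture yields 180 bp periodicity", {
    genome <- simulateGenome(1, 100000, gc = 0.45, seed = 131)
    circles <- simulateCircles(genome, n = 2000, seed = 132)
    lp <- lengthProfile(circles)
    expect_false(is.na(periodicity(lp)))
    expect_lte(abs(periodicity(lp) - 180), 20)
    modes <- lengthModes(lp)
    expect_true(any(abs(modes - 180) <= 30))
    expect_true(any(abs(modes - 360) <= 30))
})

test_that("degenerate length distributions report no periodicity", {
    # all lengths equal: single mode, undetermined periodicity
    lpEq <- lengthProfile(rep(300L, 200))
    expect_identical(lengthModes(lpEq), 300)
    expect_true(is.na(periodicity(lpEq)))
    # uniform lengths: flat spectrum, no significant peak
    lens <- withr::with_seed(1, sample(200:1000, 2000, replace = TRUE))
    lpU <- lengthProfile(lens)
    expect_true(is.na(periodicity(lpU)))
    # too few calls
    lpFew <- lengthProfile(rep(c(180L, 360L), 10))
    expect_true(is.na(periodicity(lpFew)))
})

test_that("GC is counted exactly and matches a naive per-base oracle", {
    genome <- Biostrings::DNAStringSet(
        c(chr1 = paste(rep("ATGC", 100), collapse = "")))
    call <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 400))
    gp <- gcProfile(call, genome)
    expect_identical(gcFractions(gp), 0.5)
    # naive per-character oracle on random calls
    g2 <- simulateGenome(1, 20000, gc = 0.45, seed = 141)
    calls <- simulateCircles(g2, n = 200, seed = 142)
    gp2 <- gcProfile(calls, g2)
    gchar <- as.character(g2[["chr1"]])
    naive <- vapply(seq_along(calls), function(i) {
        s <- strsplit(substr(gchar, BiocGenerics::start(calls)[i],
                             BiocGenerics::end(calls)[i]), "")[[1]]
        sum(s %in% c("G", "C")) / sum(s %in% c("A", "C", "G", "T"))
    }, numeric(1))
    expect_equal(gcFractions(gp2), naive)
    # generator-level property: mean GC tracks the genome's GC
    expect_lt(abs(gp2@mean - 0.45), 0.02)
})

test_that("ambiguous-only calls follow the onAllN policy", {
    genome <- Biostrings::DNAStringSet(
        c(chr1 = paste0(paste(rep("ACGT", 50), collapse = ""),
                        paste(rep("N", 100), collapse = ""))))
    calls <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(1, 201), c(100, 300)))
    expect_error(gcProfile(calls, genome), "ambiguous")
    expect_warning(gp <- gcProfile(calls, genome, onAllN = "exclude"),
                   "excluded")
    expect_length(gcFractions(gp), 1)
    bad <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 10))
    expect_error(gcProfile(bad, genome), "chrX")
})

test_that("feature BED round-trips through the class-label reader", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t1000\t2000\texon\t0\t.",
                 "chr1\t5000\t5500\tCpG-island\t0\t."), bed)
    gr <- readFeaturesBed(bed)
    expect_identical(BiocGenerics::start(gr), c(1001L, 5001L))  # 1-based
    expect_identical(BiocGenerics::end(gr), c(2000L, 5500L))
    expect_identical(S4Vectors::mcols(gr)$class, c("exon", "CpG-island"))
    noName <- tempfile(fileext = ".bed")
    writeLines("chr1\t10\t20", noName)
    expect_error(readFeaturesBed(noName), "name column")
})

test_that("characterization plots build without error", {
    genome <- simulateGenome(1, 20000, gc = 0.45, seed = 141)
    calls <- simulateCircles(genome, n = 200, seed = 142)
    lp <- lengthProfile(calls)
    gp <- gcProfile(calls, genome)
    expect_s3_class(plotLengthProfile(lp), "ggplot")
    expect_s3_class(plotGCProfile(gp), "ggplot")
    cmp <- data.frame(label = c("A", "B"), mean = c(10, 5), sd = c(1, 1))
    expect_s3_class(plotComplexity(cmp), "ggplot")
})
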