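#' Simulate a toy reference genome
#'
#' Draws i.i.d. bases with P(G) + P(C) = `gc` (split equally between G and
#' C, and between A and T), giving a small stand-in for a real reference
#' against which circles, reads and alignments can be simulated with known
#' ground truth.
#'
#' @param nChroms Number of chromosomes.
#' @param chromLength Length of each chromosome in bp (>= 10000).
#' @param gc Target GC fraction, strictly between 0 and 1 (0 and 1 are
#'   allowed as degenerate boundary cases for testing).
#' @param seed Integer seed; the same inputs and seed give a byte-identical
#'   genome.
#' @return A named `DNAStringSet` (`chr1`, `chr2`, ...).
#' @export
#' @examples
#' genome <- simulateGenome(1, 20000, gc = 0.45, seed = 7)
#' Biostrings::letterFrequency(genome, "GC", as.prob = TRUE)
simulateGenome <- function(nChroms = 1L, chromLength = 100000L, gc = 0.45,
                           seed = 1L) {
    if (!is.numeric(gc) || length(gc) != 1L || is.na(gc) || gc < 0 || gc > 1)
        stop("'gc' must be a single value in [0, 1]")
    if (!is.numeric(chromLength) || chromLength < 10000)
        stop("'chromLength' must be at least 10000 bp")
    if (!is.numeric(nChroms) || nChroms < 1)
        stop("'nChroms' must be a positive count")
    nChroms <- as.integer(nChroms)
    chromLength <- as.integer(chromLength)
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- withSeed(seed, {
        vapply(seq_len(nChroms), function(i) {
            paste(sample(names(probs), chromLength, replace = TRUE,
                         prob = probs), collapse = "")
        }, character(1))
    })
    out <- DNAStringSet(seqs)
    names(out) <- paste0("chr", seq_len(nChroms))
    out
}

#' Write a reference genome to FASTA
#'
#' Thin wrapper over [Biostrings::writeXStringSet()] kept for symmetry with
#' the other writers; output is deterministic for a fixed genome.
#'
#' @param genome Named `DNAStringSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
    stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
    writeXStringSet(genome, filepath = path, format = "fasta")
    invisible(path)
}
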