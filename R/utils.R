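# Internal helpers shared across the simulator, aligner and caller.

#' Run an expression under a local RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's
#' `.Random.seed` afterwards, so library functions are reproducible without
#' clobbering the session RNG.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else {
            assign(".Random.seed", old, envir = globalenv())
        }
    })
    set.seed(as.integer(seed))
    expr
}

# Deterministic child seed derivation; keeps results < 2^31 so they remain
# valid R integers.
childSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647L)
}

# --- CIGAR arithmetic -------------------------------------------------------
# Only M/I/S/D/N/=/X are handled; that covers everything the oracle aligner
# emits and everything BWA-MEM-style split alignments contain.

cigarOps <- function(cigar) {
    lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
    ops  <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
    Map(function(l, o) list(len = as.integer(l), op = o), lens, ops)
}

# query length consumed (M/I/S/=/X)
cigarQueryLength <- function(cigar) {
    vapply(cigarOps(cigar), function(x) {
        sum(x$len[x$op %in% c("M", "I", "S", "=", "X")])
    }, integer(1))
}

# leading / trailing soft clip lengths in SEQ orientation
cigarClips <- function(cigar) {
    left <- rep(0L, length(cigar))
    hasL <- grepl("^[0-9]+S", cigar)
    left[hasL] <- as.integer(sub("^([0-9]+)S.*", "\\1", cigar[hasL]))
    right <- rep(0L, length(cigar))
    hasR <- grepl("[0-9]+S$", cigar)
    right[hasR] <- as.integer(sub(".*?([0-9]+)S$", "\\1", cigar[hasR]))
    data.frame(left = left, right = right)
}

# aligned (non-clipped) query width
cigarAlignedWidth <- function(cigar) {
    vapply(cigarOps(cigar), function(x) {
        sum(x$len[x$op %in% c("M", "I", "=", "X")])
    }, integer(1))
}

# reference width
cigarRefWidth <- function(cigar) {
    vapply(cigarOps(cigar), function(x) {
        sum(x$len[x$op %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
}

# fast reverse complement on plain character vectors
revcompChar <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# named integer chromosome lengths from a DNAStringSet or named vector
genomeLengths <- function(genome) {
    if (is(genome, "DNAStringSet")) {
        stats::setNames(Biostrings::width(genome), names(genome))
    } else if (is.numeric(genome) && !is.null(names(genome))) {
        stats::setNames(as.integer(genome), names(genome))
    } else {
        stop("'genome' must be a named DNAStringSet or a named length vector")
    }
}
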