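# ggplot2 panels mirroring the standard microDNA characterization figures.

#' Bar chart of library complexity with SD error bars
#'
#' @param comparison `data.frame` from [compareComplexity()].
#' @return A ggplot object.
#' @export
plotComplexity <- function(comparison) {
    stopifnot(all(c("label", "mean", "sd") %in% colnames(comparison)))
    ggplot2::ggplot(comparison,
                    ggplot2::aes(x = .data$label, y = .data$mean)) +
        ggplot2::geom_col(fill = "grey35") +
        ggplot2::geom_errorbar(
            ggplot2::aes(ymin = .data$mean - .data$sd,
                         ymax = .data$mean + .data$sd), width = 0.2) +
        ggplot2::labs(x = NULL, y = "unique junctions per subsample",
                      title = "Library complexity at matched depth") +
        ggplot2::theme_classic()
}

#' Fold-enrichment bar chart with placement intervals
#'
#' @param x An [EnrichmentResult-class].
#' @return A ggplot object.
#' @export
plotEnrichment <- function(x) {
    df <- as.data.frame(enrichmentTable(x))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$fold)) +
        ggplot2::geom_col(fill = "grey35") +
        ggplot2::geom_errorbar(
            ggplot2::aes(ymin = .data$lo, ymax = .data$hi), width = 0.2) +
        ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
        ggplot2::labs(x = NULL, y = "fold over random expectation",
                      title = "Feature enrichment of calls") +
        ggplot2::theme_classic()
}

#' Length histogram of a call set
#'
#' @param x A [LengthProfile-class].
#' @return A ggplot object.
#' @export
plotLengthProfile <- function(x) {
    ggplot2::ggplot(x@histogram,
                    ggplot2::aes(x = .data$mid, y = .data$count)) +
        ggplot2::geom_col(width = x@binWidth, fill = "grey35") +
        ggplot2::geom_vline(xintercept = x@modes, linetype = "dotted",
                            colour = "red3") +
        ggplot2::labs(x = "circle length (bp)", y = "calls",
                      title = if (is.na(x@periodicity))
                          "Call length distribution"
                      else sprintf("Call length distribution (period %d bp)",
                                   round(x@periodicity))) +
        ggplot2::theme_classic()
}

#' GC-content histogram of a call set
#'
#' @param x A [GCProfile-class].
#' @param binwidth Histogram bin width on the GC-fraction axis.
#' @return A ggplot object.
#' @export
plotGCProfile <- function(x, binwidth = 0.02) {
    ggplot2::ggplot(data.frame(gc = x@gc), ggplot2::aes(x = .data$gc)) +
        ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35") +
        ggplot2::geom_vline(xintercept = x@mean, colour = "red3") +
        ggplot2::labs(x = "GC fraction", y = "calls",
                      title = sprintf("GC content (mean %.3f)", x@mean)) +
        ggplot2::theme_classic()
}

#' @importFrom ggplot2 .data
NULL
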