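#' Plot a per-chromosome statistic track
#'
#' Simple base-graphics track of one windowed statistic along a chromosome,
#' with the significance threshold as a horizontal line.
#'
#' @param ws windowed statistics GRanges.
#' @param chrom chromosome to plot.
#' @param stat statistic column (default \code{"ZHp"}).
#' @param threshold optional horizontal threshold value.
#' @param ... passed to \code{plot}.
#' @return Invisibly, NULL.
#' @export
plotStatTrack <- function(ws, chrom, stat = "ZHp", threshold = NULL, ...) {
    sel <- as.character(seqnames(ws)) == chrom
    x <- (start(ws)[sel] + end(ws)[sel]) / 2 / 1e6
    y <- mcols(ws)[[stat]][sel]
    graphics::plot(x, y, pch = 16, cex = 0.4, col = "grey30",
                   xlab = paste(chrom, "position (Mb)"), ylab = stat, ...)
    if (!is.null(threshold))
        graphics::abline(h = threshold, col = "red", lty = 2)
    invisible(NULL)
}
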