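# Copy-number masking: GC-correct per-sample read depth in 1-kb windows,
# convert to copy-number calls, intersect the diploid windows of all samples
# into a mask, and discard sweep regions overlapping non-diploid sequence.

#' GC-correct read depth
#'
#' Median-ratio correction per sample: windows are binned by GC fraction
#' (bins of width 1 percentage point) and each window's depth is scaled by
#' global median depth / median depth of its GC bin.  Bins with fewer than
#' \code{minBin} windows fall back to the global median (no correction).
#'
#' @param depth depth data.frame from \code{\link{readDepthTable}} or
#'   \code{\link{generateDepth}} (columns \code{sample}, \code{chrom},
#'   \code{start}, \code{end}, \code{depth}, \code{gc}); multiple samples
#'   are corrected independently.
#' @param minBin minimum windows per GC bin for correction (default 100).
#' @return \code{depth} with an added \code{corrected} column.
#' @export
gcCorrect <- function(depth, minBin = 100) {
    dt <- data.table::as.data.table(depth)
    dt[, bin := pmin(floor(gc * 100), 99L)]
    corr <- function(d, g) {
        gmed <- stats::median(d)
        if (gmed == 0) stop("no coverage: global median depth is 0")
        bmed <- stats::ave(d, g, FUN = stats::median)
        nbin <- stats::ave(d, g, FUN = length)
        fac <- ifelse(nbin >= minBin & bmed > 0, gmed / bmed, 1)
        d * fac
    }
    dt[, corrected := corr(depth, bin), by = sample]
    dt[, bin := NULL]
    as.data.frame(dt)
}

#' Copy-number estimates and calls from corrected depth
#'
#' CN estimate = 2 * corrected depth / genome-wide mean corrected depth of
#' the sample; the call is the nearest whole number (e.g. estimates in
#' (1.5, 2.5) call CN = 2), with exact half-points resolved to the lower
#' call and estimates below 0.5 calling CN = 0.
#'
#' @param depth data.frame with a \code{corrected} column (from
#'   \code{\link{gcCorrect}}); uncorrected input is GC-corrected first.
#' @param minBin passed to \code{\link{gcCorrect}} when correction is needed.
#' @return \code{depth} with added \code{cnEst} and \code{cnCall} columns.
#' @export
estimateCn <- function(depth, minBin = 100) {
    if (is.null(depth$corrected)) depth <- gcCorrect(depth, minBin)
    dt <- data.table::as.data.table(depth)
    dt[, cnEst := {
        mu <- mean(corrected)
        if (mu <= 0) stop("no coverage for sample ", sample[1])
        2 * corrected / mu
    }, by = sample]
    # nearest integer with exact halves going down (conservative for masking)
    dt[, cnCall := pmax(0L, as.integer(ceiling(cnEst - 0.5)))]
    as.data.frame(dt)
}

#' Intersect per-sample diploid windows into a mask
#'
#' The diploid mask is the set of depth windows where the CN call is exactly
#' 2 in every analyzed sample; adjacent retained windows are merged into
#' maximal intervals.
#'
#' @param cn data.frame from \code{\link{estimateCn}} covering all samples
#'   (identical window tiling required).
#' @return GRanges of the diploid mask.
#' @export
buildDiploidMask <- function(cn) {
    dt <- data.table::as.data.table(cn)
    if (nrow(dt) == 0 || length(unique(dt$sample)) == 0)
        stop("empty sample set")
    nSamp <- length(unique(dt$sample))
    counts <- dt[, .(nOk = sum(cnCall == 2L), nTot = .N), by = .(chrom, start, end)]
    if (any(counts$nTot != nSamp))
        stop("window tiling differs between samples")
    keep <- counts[nOk == nSamp]
    if (nrow(keep) == 0) return(GRanges())
    reduce(GRanges(keep$chrom, IRanges(keep$start + 1L, keep$end)),
           min.gapwidth = 1L)
}

#' Filter sweep regions against the diploid mask
#'
#' A region is discarded when its overlap with non-diploid sequence (the
#' complement of the mask within the genome) exceeds
#' \code{maxNonDiploidFrac} of its length; the default 0 discards on any
#' overlap.
#'
#' @param regions sweep region GRanges.
#' @param mask diploid mask GRanges from \code{\link{buildDiploidMask}}.
#' @param spec the \linkS4class{GenomeSpec} both live on.
#' @param maxNonDiploidFrac maximum tolerated non-diploid overlap fraction
#'   (default 0).
#' @return list with GRanges elements \code{retained} and \code{discarded};
#'   their union is the input.
#' @export
filterRegionsByMask <- function(regions, mask, spec, maxNonDiploidFrac = 0) {
    si <- asSeqinfo(spec)
    genome <- GRanges(spec@chrom, IRanges(1L, as.integer(spec@length)),
                      seqinfo = si)
    mask2 <- GenomicRanges::trim(GRanges(as.character(seqnames(mask)),
                                         IRanges(start(mask), end(mask)),
                                         seqinfo = si))
    nonDiploid <- GenomicRanges::setdiff(genome, mask2)
    if (length(regions) == 0)
        return(list(retained = regions, discarded = regions[0]))
    ovl <- numeric(length(regions))
    hits <- findOverlaps(GRanges(as.character(seqnames(regions)),
                                 IRanges(start(regions), end(regions))),
                         nonDiploid)
    if (length(hits)) {
        w <- width(pintersect(GRanges(as.character(seqnames(regions)),
                                      IRanges(start(regions), end(regions)))[queryHits(hits)],
                              nonDiploid[subjectHits(hits)]))
        agg <- rowsum(w, queryHits(hits))
        ovl[as.integer(rownames(agg))] <- agg[, 1]
    }
    frac <- ovl / width(regions)
    discard <- frac > maxNonDiploidFrac
    list(retained = regions[!discard], discarded = regions[discard])
}
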