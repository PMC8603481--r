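# Resampling enrichment tests: size-matched random-region overlap with gene
# sets, and gene-subsampling permutation for differential-expression overlap.
# Empirical p values are plain proportions of null draws at or above the
# observed fraction, as in the source analyses (no +1 correction); p = 0 is
# reported as "< 1/replicates".

#' Draw one size-matched random region set
#'
#' One region per requested length, placed uniformly on the genome
#' (chromosomes weighted by placeable length), mutually non-overlapping and
#' never clipped at chromosome ends; placement is by rejection sampling with
#' a per-region attempt cap.
#'
#' @param lengths region lengths in bp (the multiset to match).
#' @param spec a \linkS4class{GenomeSpec}.
#' @param excluded optional GRanges the sampled regions must avoid.
#' @param maxTries rejection-sampling attempts per region before error
#'   (default 1000).
#' @return GRanges of \code{length(lengths)} non-overlapping regions.
#' @export
sampleMatchedRegions <- function(lengths, spec, excluded = NULL,
                                 maxTries = 1000) {
    stopifnot(is(spec, "GenomeSpec"))
    if (sum(lengths) > genomeLength(spec))
        stop("requested lengths exceed genome length")
    exDf <- NULL
    if (!is.null(excluded) && length(excluded))
        exDf <- data.frame(chrom = as.character(seqnames(excluded)),
                           start = start(excluded), end = end(excluded))
    drawn <- .sampleRegionsInternal(sort(lengths, decreasing = TRUE),
                                    spec@chrom, spec@length, exDf, maxTries)
    GRanges(drawn$chrom, IRanges(drawn$start, drawn$end),
            seqinfo = asSeqinfo(spec))
}

# numeric-only sampler shared by the public function and the replicate loop
.sampleRegionsInternal <- function(lengths, chroms, chromLens, exDf, maxTries) {
    k <- length(lengths)
    outChrom <- character(k)
    outStart <- numeric(k)
    outEnd <- numeric(k)
    for (r in seq_len(k)) {
        len <- lengths[r]
        room <- pmax(chromLens - len + 1, 0)
        if (sum(room) == 0) stop("genome too constrained: no chromosome fits length ", len)
        placed <- FALSE
        for (tr in seq_len(maxTries)) {
            ci <- sample.int(length(chroms), 1L, prob = room)
            s <- floor(runif(1, 0, room[ci])) + 1
            e <- s + len - 1
            ok <- TRUE
            if (r > 1) {
                same <- which(outChrom[seq_len(r - 1)] == chroms[ci])
                if (length(same) &&
                    any(outStart[same] <= e & outEnd[same] >= s)) ok <- FALSE
            }
            if (ok && !is.null(exDf)) {
                ex <- exDf[exDf$chrom == chroms[ci], , drop = FALSE]
                if (nrow(ex) && any(ex$start <= e & ex$end >= s)) ok <- FALSE
            }
            if (ok) {
                outChrom[r] <- chroms[ci]
                outStart[r] <- s
                outEnd[r] <- e
                placed <- TRUE
                break
            }
        }
        if (!placed)
            stop("genome too constrained: could not place region of ",
                 len, " bp in ", maxTries, " attempts")
    }
    data.frame(chrom = outChrom, start = outStart, end = outEnd,
               stringsAsFactors = FALSE)
}

#' Fraction of regions or genes qualifying against a gene set
#'
#' Region mode: the fraction of regions overlapping (>= 1 bp) at least one
#' qualifying gene.  Gene mode: the fraction of distinct genes overlapped by
#' the regions that belong to the set.  Qualifying genes are the members of
#' \code{geneSet}, or the protein-coding genes when \code{geneSet} is NULL.
#'
#' @param regions GRanges of regions.
#' @param annotation gene annotation GRanges (\code{gene_id}, \code{coding}).
#' @param geneSet character vector of member gene ids, or NULL for the
#'   protein-coding flag.
#' @param mode \code{"region"} or \code{"gene"}.
#' @return The fraction (0 with a warning for gene mode with no genes
#'   overlapped).
#' @export
regionGeneSetFraction <- function(regions, annotation, geneSet = NULL,
                                  mode = c("region", "gene")) {
    mode <- match.arg(mode)
    qual <- if (is.null(geneSet)) annotation$coding
            else annotation$gene_id %in% geneSet
    hits <- findOverlaps(regions, annotation, minoverlap = 1L)
    if (mode == "region") {
        if (length(regions) == 0) return(0)
        hitQual <- unique(queryHits(hits)[qual[subjectHits(hits)]])
        length(hitQual) / length(regions)
    } else {
        genes <- unique(subjectHits(hits))
        if (length(genes) == 0) {
            warning("no genes overlapped by regions; gene-mode fraction is 0")
            return(0)
        }
        mean(qual[genes])
    }
}

#' Empirical p value from a resampled null
#'
#' The plain proportion of null fractions at or above (direction
#' \code{"greater"}) the observed fraction.  A p of 0 is annotated
#' \code{"< 1/replicates"} in the label.
#'
#' @param observed observed fraction.
#' @param null numeric vector of null fractions.
#' @param direction only \code{"greater"} is meaningful for enrichment.
#' @return list with \code{p} (numeric) and \code{label} (character).
#' @export
empiricalP <- function(observed, null, direction = "greater") {
    if (length(null) == 0) stop("empty null")
    if (direction != "greater") stop("unknown direction: ", direction)
    p <- mean(null >= observed)
    label <- if (p == 0) sprintf("< %g", 1 / length(null)) else format(p)
    list(p = p, label = label)
}

#' Size-matched region resampling enrichment test
#'
#' Compares the observed gene-set fraction of the sweep regions with the
#' fractions of \code{replicates} random size-matched non-overlapping region
#' sets placed uniformly on the genome.
#'
#' @param regions sweep region GRanges.
#' @param annotation gene annotation GRanges.
#' @param geneSet member gene ids, or NULL for protein-coding.
#' @param spec a \linkS4class{GenomeSpec}.
#' @param mode fraction mode, \code{"gene"} or \code{"region"}.
#' @param replicates null replicates (default 1000).
#' @param seed RNG seed.
#' @param excluded optional GRanges excluded from random placement.
#' @param testName label for the result row.
#' @return One-row data.frame: \code{test}, \code{mode}, \code{observed},
#'   \code{nullMean}, \code{nullSd}, \code{p}, \code{pLabel},
#'   \code{replicates}, \code{seed}; the null fractions are in
#'   \code{attr(, "null")}.
#' @export
runGeneSetEnrichment <- function(regions, annotation, geneSet, spec,
                                 mode = c("gene", "region"),
                                 replicates = 1000, seed = 1L,
                                 excluded = NULL, testName = "geneset") {
    mode <- match.arg(mode)
    observed <- regionGeneSetFraction(regions, annotation, geneSet, mode)
    lens <- sort(width(regions), decreasing = TRUE)
    exDf <- NULL
    if (!is.null(excluded) && length(excluded))
        exDf <- data.frame(chrom = as.character(seqnames(excluded)),
                           start = start(excluded), end = end(excluded))
    # per-chromosome gene tables sorted by start, for fast overlap counting
    ann <- data.frame(chrom = as.character(seqnames(annotation)),
                      start = start(annotation), end = end(annotation),
                      qual = if (is.null(geneSet)) annotation$coding
                             else annotation$gene_id %in% geneSet)
    byChrom <- split(ann, ann$chrom)
    byChrom <- lapply(byChrom, function(d) d[order(d$start), , drop = FALSE])
    maxLen <- if (nrow(ann)) max(ann$end - ann$start + 1) else 0
    set.seed(as.integer(seed))
    null <- vapply(seq_len(replicates), function(r) {
        rr <- .sampleRegionsInternal(lens, spec@chrom, spec@length, exDf, 1000)
        .fastFraction(rr, byChrom, maxLen, mode)
    }, numeric(1))
    res <- empiricalP(observed, null)
    out <- data.frame(test = testName, mode = mode, observed = observed,
                      nullMean = mean(null), nullSd = stats::sd(null),
                      p = res$p, pLabel = res$label,
                      replicates = as.integer(replicates),
                      seed = as.integer(seed), stringsAsFactors = FALSE)
    attr(out, "null") <- null
    out
}

# fraction of a sampled region set, via sorted per-chromosome gene tables
.fastFraction <- function(rr, byChrom, maxLen, mode) {
    hitReg <- 0L
    genesQual <- logical(0)
    geneKeys <- character(0)
    for (i in seq_len(nrow(rr))) {
        d <- byChrom[[rr$chrom[i]]]
        if (is.null(d) || nrow(d) == 0) next
        s <- rr$start[i]; e <- rr$end[i]
        lo <- findInterval(s - maxLen - 0.5, d$start)
        hi <- findInterval(e - 0.5, d$start)
        if (hi <= lo) next
        idx <- seq(lo + 1L, hi)
        idx <- idx[d$end[idx] >= s]
        if (!length(idx)) next
        hitReg <- hitReg + as.integer(any(d$qual[idx]))
        geneKeys <- c(geneKeys, paste0(rr$chrom[i], ":", idx))
        genesQual <- c(genesQual, d$qual[idx])
    }
    if (mode == "region") {
        if (nrow(rr) == 0) return(0)
        hitReg / nrow(rr)
    } else {
        if (!length(geneKeys)) return(0)
        dup <- duplicated(geneKeys)
        mean(genesQual[!dup])
    }
}

#' Differential-expression overlap permutation test
#'
#' For each tissue, compares the fraction of selection genes called
#' differentially expressed with the DE fraction of random same-size gene
#' draws from the tissue's full expression universe.
#'
#' @param selectionGenes gene ids under selection.
#' @param deTable data.frame with columns \code{tissue}, \code{gene},
#'   \code{de} (logical), one row per gene per tissue.
#' @param replicates subsampling replicates (default 10000).
#' @param seed RNG seed.
#' @return data.frame with one row per tissue (columns as in
#'   \code{\link{runGeneSetEnrichment}} plus \code{tissue} and
#'   \code{nGenes}).
#' @export
deOverlapTest <- function(selectionGenes, deTable, replicates = 10000,
                          seed = 1L) {
    selectionGenes <- unique(selectionGenes)
    out <- list()
    set.seed(as.integer(seed))
    for (tis in unique(deTable$tissue)) {
        uni <- deTable[deTable$tissue == tis, , drop = FALSE]
        sel <- intersect(selectionGenes, uni$gene)
        dropped <- length(selectionGenes) - length(sel)
        if (dropped > 0)
            warning(dropped, " selection gene(s) absent from the ", tis,
                    " expression universe dropped")
        if (length(sel) == 0)
            stop("no selection genes in the ", tis, " expression universe")
        de <- uni$de
        obs <- mean(de[match(sel, uni$gene)])
        m <- length(sel)
        null <- vapply(seq_len(replicates), function(r)
            mean(de[sample.int(nrow(uni), m)]), numeric(1))
        res <- empiricalP(obs, null)
        out[[tis]] <- data.frame(test = "de_overlap", tissue = tis,
                                 nGenes = m, observed = obs,
                                 nullMean = mean(null),
                                 nullSd = stats::sd(null), p = res$p,
                                 pLabel = res$label,
                                 replicates = as.integer(replicates),
                                 seed = as.integer(seed),
                                 stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}
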