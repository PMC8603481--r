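# Candidate sweep region calling: flag outlier windows against the neutral
# thresholds, require Hp support plus at least one of pi / Tajima's D, and
# collapse adjacent candidate windows into regions.

#' Flag outlier windows against neutral thresholds
#'
#' A window is flagged for a statistic when its raw value lies strictly below
#' the threshold.  Windows excluded by the SNP-count filter are never
#' flagged, and windows with missing D cannot be D-flagged.
#'
#' @param ws windowed statistics GRanges (after \code{\link{filterMinSnps}}).
#' @param thresholds a \linkS4class{ThresholdSet} derived from the same
#'   population.
#' @return \code{ws} with logical columns \code{outHp}, \code{outPi},
#'   \code{outD}.
#' @export
flagOutliers <- function(ws, thresholds) {
    stopifnot(is(thresholds, "ThresholdSet"))
    if (is.null(mcols(ws)$retained))
        stop("run filterMinSnps() first")
    thr <- rawThresholds(thresholds)
    ret <- mcols(ws)$retained
    flag <- function(x, t) ret & !is.na(x) & x < t
    mcols(ws)$outHp <- flag(mcols(ws)$Hp, thr["Hp"])
    mcols(ws)$outPi <- flag(mcols(ws)$pi, thr["pi"])
    mcols(ws)$outD <- flag(mcols(ws)$D, thr["D"])
    ws
}

#' Collapse candidate windows into sweep regions
#'
#' Candidate windows are those flagged by Hp and by at least one of pi or D
#' (\code{mode = "window"}, the default).  Candidate windows whose intervals
#' overlap or are book-ended merge into one region spanning their union;
#' windows removed by the SNP-count filter break adjacency (they cannot
#' bridge two candidate runs).  With \code{mode = "region"} the co-support is
#' required anywhere within the merged region rather than within each
#' window: regions are built from Hp-flagged windows and kept if any member
#' is pi- or D-flagged.
#'
#' @param ws flagged windowed statistics from \code{\link{flagOutliers}}.
#' @param population population id stored in the region names.
#' @param mode co-support rule, \code{"window"} or \code{"region"}.
#' @return GRanges of disjoint sorted regions with metadata columns
#'   \code{population}, \code{nWindows}, \code{minZHp}, \code{supportHp},
#'   \code{supportPi}, \code{supportD}.
#' @export
callRegions <- function(ws, population = "pop", mode = c("window", "region")) {
    mode <- match.arg(mode)
    m <- mcols(ws)
    if (is.null(m$outHp)) stop("run flagOutliers() first")
    cand <- if (mode == "window") m$outHp & (m$outPi | m$outD) else m$outHp
    empty <- GRanges(seqinfo = seqinfo(ws))
    if (!any(cand)) return(.regionMcols(empty, character(0)))
    ord <- order(as.factor(seqnames(ws)), start(ws))
    wso <- ws[ord]
    mo <- mcols(wso)
    cando <- cand[ord]
    excl <- !mo$retained
    idx <- which(cando)
    chr <- as.character(seqnames(wso))
    regions <- list()
    cur <- NULL   # list(chrom, start, end, members)
    for (i in idx) {
        gapIdx <- if (!is.null(cur) && i - cur$last >= 2L)
            seq(cur$last + 1L, i - 1L) else integer(0)
        if (!is.null(cur) && chr[i] == cur$chrom &&
            start(wso)[i] <= cur$end + 1L && !any(excl[gapIdx])) {
            cur$end <- max(cur$end, end(wso)[i])
            cur$members <- c(cur$members, i)
            cur$last <- i
        } else {
            if (!is.null(cur)) regions[[length(regions) + 1L]] <- cur
            cur <- list(chrom = chr[i], start = start(wso)[i],
                        end = end(wso)[i], members = i, last = i)
        }
    }
    regions[[length(regions) + 1L]] <- cur
    gr <- GRanges(vapply(regions, `[[`, character(1), "chrom"),
                  IRanges(vapply(regions, `[[`, numeric(1), "start"),
                          vapply(regions, `[[`, numeric(1), "end")),
                  seqinfo = seqinfo(ws))
    memb <- lapply(regions, `[[`, "members")
    supPi <- vapply(memb, function(ii) any(mo$outPi[ii]), logical(1))
    supD <- vapply(memb, function(ii) any(mo$outD[ii]), logical(1))
    minZ <- vapply(memb, function(ii) {
        z <- mo$ZHp[ii]
        if (all(is.na(z))) NA_real_ else min(z, na.rm = TRUE)
    }, numeric(1))
    nwin <- lengths(memb)
    if (mode == "region") {
        keep <- supPi | supD
        gr <- gr[keep]; supPi <- supPi[keep]; supD <- supD[keep]
        minZ <- minZ[keep]; nwin <- nwin[keep]
    }
    mcols(gr) <- DataFrame(population = population, nWindows = nwin,
                           minZHp = minZ, supportHp = TRUE,
                           supportPi = supPi, supportD = supD)
    sort(gr)
}

.regionMcols <- function(gr, population) {
    mcols(gr) <- DataFrame(population = character(0), nWindows = integer(0),
                           minZHp = numeric(0), supportHp = logical(0),
                           supportPi = logical(0), supportD = logical(0))
    gr
}

#' Attach overlapping genes to sweep regions
#'
#' A gene is attached when its interval overlaps the region by at least 1 bp
#' (half-open boundary abutment does not count as overlap).
#'
#' @param regions sweep region GRanges.
#' @param annotation gene annotation GRanges with a \code{gene_id} column.
#' @return \code{regions} with a \code{genes} CharacterList column.
#' @export
annotateRegionGenes <- function(regions, annotation) {
    hits <- findOverlaps(regions, annotation, minoverlap = 1L)
    gl <- rep(list(character(0)), length(regions))
    if (length(hits)) {
        sp <- split(annotation$gene_id[subjectHits(hits)], queryHits(hits))
        gl[as.integer(names(sp))] <- sp
    }
    mcols(regions)$genes <- IRanges::CharacterList(gl)
    regions
}

#' Cross-population sharing of sweep regions
#'
#' For every region of every population, lists the other populations with at
#' least 1 bp of overlapping called region.
#'
#' @param regionList named list of per-population region GRanges (>= 2
#'   entries).
#' @return data.frame with columns \code{population}, \code{chrom},
#'   \code{start}, \code{end}, \code{sharedWith} (comma-separated, possibly
#'   empty).
#' @export
sharedRegions <- function(regionList) {
    if (length(regionList) < 2) stop("need regions from >= 2 populations")
    pops <- names(regionList)
    if (is.null(pops)) stop("regionList must be named by population")
    out <- list()
    for (p in pops) {
        gr <- regionList[[p]]
        if (length(gr) == 0) next
        shared <- rep("", length(gr))
        for (q in setdiff(pops, p)) {
            ov <- suppressWarnings(
                overlapsAny(gr, regionList[[q]], minoverlap = 1L))
            shared[ov] <- ifelse(nchar(shared[ov]) > 0,
                                 paste(shared[ov], q, sep = ","), q)
        }
        out[[p]] <- data.frame(population = p,
                               chrom = as.character(seqnames(gr)),
                               start = start(gr) - 1L, end = end(gr),
                               sharedWith = shared, stringsAsFactors = FALSE)
    }
    if (length(out) == 0)
        return(data.frame(population = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          sharedWith = character(0)))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}
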