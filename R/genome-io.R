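# Readers and writers for the external formats the pipeline touches.
# In memory everything is GRanges (1-based closed, the Bioconductor
# convention); BED (0-based half-open) and GFF (1-based closed) are converted
# at the file boundary.

#' Read a chromosome-length table
#'
#' Two-column TSV (chromosome, length in bp), no header.
#'
#' @param path file path.
#' @return A \linkS4class{GenomeSpec}.
#' @export
readGenomeSpec <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("chrom", "length"),
                             colClasses = c("character", "numeric"))
    genomeSpec(tab$chrom, tab$length)
}

#' Write a chromosome-length table
#'
#' @param spec a \linkS4class{GenomeSpec}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenomeSpec <- function(spec, path) {
    utils::write.table(data.frame(spec@chrom, format(spec@length, scientific = FALSE, trim = TRUE)),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a population VCF into a VariantTable
#'
#' Admits biallelic SNP records only; multi-allelic records and indels are
#' skipped with a message reporting the skip count.  Allele counts are tallied
#' over the requested samples; half-missing diploid genotypes (e.g.
#' \code{./1}) are treated as fully missing.
#'
#' @param path VCF 4.x file (gzip accepted).
#' @param samples character vector of sample ids to tally; default all
#'   samples in the header.
#' @param population population id to record; defaults to the file name.
#' @return A \linkS4class{VariantTable}.
#' @export
readPopulationVcf <- function(path, samples = NULL, population = NULL) {
    if (is.null(population))
        population <- sub("\\.vcf(\\.gz)?$", "", basename(path))
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    have <- colnames(v@gt)[-1]
    if (is.null(samples)) samples <- have
    absent <- setdiff(samples, have)
    if (length(absent))
        stop("sample(s) not present in VCF header: ", paste(absent, collapse = ", "))
    fix <- v@fix
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    nSkip <- sum(!snp)
    if (nSkip > 0)
        message(nSkip, " non-biallelic-SNP record(s) skipped")
    gt <- v@gt[snp, samples, drop = FALSE]
    # strip any per-genotype annotations beyond GT
    gt <- sub(":.*$", "", gt)
    gt[is.na(gt)] <- "./."
    a1 <- substr(gt, 1L, 1L)
    a2 <- substr(gt, 3L, 3L)
    bad <- !(a1 %in% c("0", "1") & a2 %in% c("0", "1"))
    if (any(bad)) {
        ok1 <- a1 %in% c("0", "1", ".")
        ok2 <- a2 %in% c("0", "1", ".")
        mal <- !(ok1 & ok2) & !(a1 == "." | a2 == ".")
        if (any(mal)) {
            idx <- which(rowSums(matrix(mal, nrow = nrow(gt))) > 0)[1]
            stop("malformed genotype in record ", idx, " of admitted SNPs")
        }
    }
    miss <- (a1 == ".") | (a2 == ".")  # half-missing treated as fully missing
    altCt <- (a1 == "1") + (a2 == "1")
    refCt <- (a1 == "0") + (a2 == "0")
    altCt[miss] <- 0L
    refCt[miss] <- 0L
    dim(miss) <- dim(gt)
    dim(altCt) <- dim(gt)
    dim(refCt) <- dim(gt)
    sites <- data.frame(
        chrom = fix[snp, "CHROM"],
        pos = as.integer(fix[snp, "POS"]),
        refCount = as.integer(rowSums(refCt)),
        altCount = as.integer(rowSums(altCt)),
        missingCount = as.integer(2L * rowSums(miss)),
        stringsAsFactors = FALSE)
    variantTable(population, length(samples), sites)
}

#' Read intervals from BED or GFF
#'
#' BED input is 0-based half-open; GFF 1-based closed.  Both are returned as
#' GRanges (1-based closed).  Empty files yield an empty GRanges.
#'
#' @param path file path.
#' @param dialect \code{"bed"} or \code{"gff"}; default guessed from the
#'   file extension.
#' @return A \link[GenomicRanges]{GRanges}; BED name/score columns are kept
#'   when present.
#' @export
readIntervals <- function(path, dialect = c("auto", "bed", "gff")) {
    dialect <- match.arg(dialect)
    if (dialect == "auto") {
        dialect <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
            "gff" else "bed"
    }
    info <- file.info(path)
    if (!is.na(info$size) && info$size == 0)
        return(GRanges())
    gr <- if (dialect == "bed") rtracklayer::import(path, format = "BED")
          else rtracklayer::import(path, format = "GFF")
    if (any(start(gr) > end(gr)))
        stop("interval with start >= end at record ",
             which(start(gr) > end(gr))[1])
    unname(gr)
}

#' Read a gene annotation
#'
#' Accepts BED6 (name = gene id, score = 1 for protein-coding, 0 otherwise)
#' or GFF3 gene features carrying \code{ID} (or \code{Name}) and a
#' \code{biotype}/\code{gene_biotype} attribute.  Gene ids must be unique.
#'
#' @param path file path.
#' @param dialect as in \code{\link{readIntervals}}.
#' @return GRanges with mcols \code{gene_id} (character) and \code{coding}
#'   (logical).
#' @export
readGeneAnnotation <- function(path, dialect = c("auto", "bed", "gff")) {
    gr <- readIntervals(path, dialect)
    m <- mcols(gr)
    if ("ID" %in% names(m) || "Name" %in% names(m)) {
        gid <- if ("ID" %in% names(m)) m$ID else m$Name
        bio <- if ("biotype" %in% names(m)) m$biotype
               else if ("gene_biotype" %in% names(m)) m$gene_biotype
               else "protein_coding"
        coding <- bio == "protein_coding"
    } else if ("name" %in% names(m)) {
        gid <- m$name
        coding <- if ("score" %in% names(m)) !is.na(m$score) & m$score > 0
                  else rep(TRUE, length(gr))
    } else stop("cannot find gene identifiers in ", path)
    if (anyDuplicated(gid)) stop("gene identifiers must be unique")
    mcols(gr) <- DataFrame(gene_id = as.character(gid), coding = as.logical(coding))
    names(gr) <- gr$gene_id
    gr
}

#' Read gene-set membership lists
#'
#' Two-column TSV: set name, gene id.  Genes not present in \code{annotation}
#' (when given) are dropped with a warning.
#'
#' @param path TSV path.
#' @param annotation optional gene annotation GRanges for validation.
#' @return Named list of character vectors of gene ids.
#' @export
readGeneSets <- function(path, annotation = NULL) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("set", "gene"),
                             colClasses = "character")
    sets <- split(tab$gene, tab$set)
    if (!is.null(annotation)) {
        known <- annotation$gene_id
        sets <- lapply(sets, function(g) {
            unknown <- setdiff(g, known)
            if (length(unknown))
                warning(length(unknown), " gene(s) not in annotation dropped")
            intersect(g, known)
        })
    }
    lapply(sets, unique)
}

#' Read per-tissue differential-expression call tables
#'
#' Three-column TSV with header: tissue, gene, de (0/1 or TRUE/FALSE).
#'
#' @param path TSV path.
#' @return data.frame with columns \code{tissue}, \code{gene}, \code{de}
#'   (logical).
#' @export
readDeTable <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    stopifnot(all(c("tissue", "gene", "de") %in% names(tab)))
    tab$de <- as.logical(as.integer(tab$de))
    tab
}

#' Read a per-sample read-depth track
#'
#' bedGraph-like TSV with columns chrom, start (0-based), end, depth, gc.
#' Windows must tile each chromosome contiguously at a fixed size (the last
#' window of a chromosome may be shorter) and must not overlap.
#'
#' @param path TSV path.
#' @param sample sample id to record; defaults to the file name.
#' @param windowSize expected window size in bp (default 1000).
#' @return data.frame with columns \code{sample}, \code{chrom}, \code{start}
#'   (0-based), \code{end}, \code{depth}, \code{gc}.
#' @export
readDepthTable <- function(path, sample = NULL, windowSize = 1000) {
    if (is.null(sample))
        sample <- sub("\\.(tsv|txt|bedgraph)(\\.gz)?$", "", basename(path))
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("chrom", "start", "end", "depth", "gc"),
                             colClasses = c("character", rep("numeric", 4)))
    if (any(tab$depth < 0)) stop("negative depth")
    if (any(tab$gc < 0 | tab$gc > 1)) stop("gc fraction outside [0, 1]")
    for (ch in unique(tab$chrom)) {
        w <- tab[tab$chrom == ch, ]
        w <- w[order(w$start), ]
        if (any(w$end <= w$start)) stop("empty depth window on ", ch)
        if (nrow(w) > 1) {
            if (any(w$start[-1] < w$end[-nrow(w)]))
                stop("overlapping depth windows on ", ch)
            if (any(w$start[-1] != w$end[-nrow(w)]))
                stop("non-tiling depth windows on ", ch)
        }
        wsz <- w$end - w$start
        if (nrow(w) > 1 && any(wsz[-nrow(w)] != windowSize))
            stop("depth windows are not ", windowSize, " bp on ", ch)
        if (wsz[nrow(w)] > windowSize)
            stop("depth windows are not ", windowSize, " bp on ", ch)
        if (w$start[1] != 0) stop("depth windows do not start at 0 on ", ch)
    }
    cbind(sample = sample, tab[order(tab$chrom, tab$start), ],
          stringsAsFactors = FALSE, row.names = NULL)
}

#' Write intervals as BED
#'
#' Output is BED (0-based half-open), sorted by (chromosome, start).  A
#' \code{name} metadata column becomes BED column 4 and \code{score} column 5.
#'
#' @param gr a GRanges.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRegionsBed <- function(gr, path) {
    gr <- sort(gr)
    out <- data.frame(chrom = as.character(seqnames(gr)),
                      start = format(start(gr) - 1L, scientific = FALSE, trim = TRUE),
                      end = format(end(gr), scientific = FALSE, trim = TRUE),
                      stringsAsFactors = FALSE)
    m <- mcols(gr)
    if ("name" %in% names(m)) {
        out$name <- as.character(m$name)
        if ("score" %in% names(m)) out$score <- m$score
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write windowed statistics as TSV
#'
#' One row per window with 0-based half-open coordinates and the statistic
#' columns of \code{\link{windowedStats}}.
#'
#' @param ws windowed statistics GRanges.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeWindowStats <- function(ws, path) {
    df <- as.data.frame(ws)
    df$start <- df$start - 1L
    df$width <- NULL
    df$strand <- NULL
    names(df)[names(df) == "seqnames"] <- "chrom"
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) signif(x, 10))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
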