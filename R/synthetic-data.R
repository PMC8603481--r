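# Synthetic data generation: neutral genomes from the coalescent simulator
# (independent 20-kb tiles, diploid samples), planted hard sweeps (haplotype
# replacement) and segregating deletions, GC-biased Poisson read depth, gene
# annotations with controllable gene-set and differential-expression
# enrichment, and a ground-truth manifest sufficient to regenerate the
# dataset.
#
# The simulated VCF is modeled as called against a diverged reference
# genome: at divergence sites (density `divergence` per bp) every haplotype
# carries the alternate allele, so the VCF contains records that are fixed
# non-reference within the population, exactly as real population VCFs do.
# These records keep swept windows above the SNP-count filter and give them
# zero pool heterozygosity, which is how a real caller sees a completed
# sweep.

#' Simulate a neutral population
#'
#' Draws haplotypes tile by tile from the coalescent simulator (tiles are
#' independent: no linkage across tiles), pairs them into diploids, and adds
#' reference-divergence sites at which all haplotypes carry the alternate
#' allele.
#'
#' @param spec a \linkS4class{GenomeSpec}.
#' @param model a \linkS4class{DemographicModel}.
#' @param nDiploid diploid sample count (default 20).
#' @param seed RNG seed.
#' @param divergence reference divergence per bp (default 0.005): density of
#'   population-fixed non-reference records.
#' @param tileLength independent simulation tile length in bp (default
#'   20000).
#' @param population population id.
#' @return A \code{PopulationSim} object (list with tiles of haplotype
#'   matrices, divergence sites, and empty sweep/deletion records).
#' @export
simulatePopulation <- function(spec, model, nDiploid = 20L, seed = 1L,
                               divergence = 0.005, tileLength = 20000,
                               population = "synthpop") {
    stopifnot(is(spec, "GenomeSpec"), is(model, "DemographicModel"))
    n <- 2L * as.integer(nDiploid)
    set.seed(as.integer(seed))
    tiles <- list()
    for (ci in seq_along(spec@chrom)) {
        chrom <- spec@chrom[ci]
        len <- spec@length[ci]
        starts <- seq(1, len, by = tileLength)
        for (s in starts) {
            e <- min(s + tileLength - 1, len)
            tl <- e - s + 1
            sim <- simulateWindow(model, tl, haplotypes = TRUE, n = n)
            S <- length(sim$counts)
            pos <- if (S > 0) s - 1L + sort(sample.int(tl, S)) else integer(0)
            # rows = sites, cols = haplotypes
            hap <- if (S > 0) t(sim$haplotypes) else
                matrix(0L, nrow = 0, ncol = n)
            nFix <- rpois(1L, divergence * tl)
            fixPos <- if (nFix > 0) {
                avail <- setdiff(seq_len(tl), pos - (s - 1L))
                s - 1L + sort(sample(avail, min(nFix, length(avail))))
            } else integer(0)
            tiles[[length(tiles) + 1L]] <-
                list(chrom = chrom, start = s, end = e, pos = as.integer(pos),
                     hap = hap, fixedPos = as.integer(fixPos))
        }
    }
    structure(list(spec = spec, model = model, nDiploid = as.integer(nDiploid),
                   population = population, tileLength = tileLength,
                   divergence = divergence, seed = as.integer(seed),
                   tiles = tiles, sweeps = list(), deletions = list()),
              class = "PopulationSim")
}

#' @export
print.PopulationSim <- function(x, ...) {
    nSeg <- sum(vapply(x$tiles, function(t) length(t$pos), integer(1)))
    nFix <- sum(vapply(x$tiles, function(t) length(t$fixedPos), integer(1)))
    cat("PopulationSim", sQuote(x$population), "-", x$nDiploid, "diploids,",
        length(x$tiles), "tiles,", nSeg, "segregating +", nFix,
        "reference-fixed sites,", length(x$sweeps), "sweep(s),",
        length(x$deletions), "deletion(s)\n")
    invisible(x)
}

.popHapCount <- function(pop) 2L * pop$nDiploid

.checkInterval <- function(pop, chrom, start, end) {
    ci <- match(chrom, pop$spec@chrom)
    if (is.na(ci)) stop("unknown chromosome: ", chrom)
    if (start < 1 || end > pop$spec@length[ci] || start >= end)
        stop("interval outside genome: ", chrom, ":", start, "-", end)
}

#' Plant a hard sweep
#'
#' Within the interval, a fraction \code{f} of haplotypes (rounded to a
#' count) is replaced by copies of one randomly chosen template haplotype.
#' Sites left with no alternate allele are removed; sites fixed for the
#' alternate allele remain as population-fixed records, as a variant caller
#' against a diverged reference would report them.
#'
#' @param pop a \code{PopulationSim}.
#' @param chrom,start,end sweep interval (1-based closed).
#' @param f sweep completeness in (0, 1]: fraction of haplotypes replaced.
#' @return The modified \code{PopulationSim}; the sweep (with template and
#'   replaced haplotypes) is appended to \code{pop$sweeps}.
#' @export
plantSweep <- function(pop, chrom, start, end, f = 1) {
    stopifnot(inherits(pop, "PopulationSim"))
    if (f <= 0 || f > 1) stop("completeness f must be in (0, 1]")
    .checkInterval(pop, chrom, start, end)
    n <- .popHapCount(pop)
    template <- sample.int(n, 1L)
    nRep <- round(f * n)
    replaced <- if (nRep > 0) sample.int(n, nRep) else integer(0)
    for (ti in seq_along(pop$tiles)) {
        tl <- pop$tiles[[ti]]
        if (tl$chrom != chrom || tl$end < start || tl$start > end) next
        inside <- tl$pos >= start & tl$pos <= end
        if (!any(inside)) next
        hap <- tl$hap
        hap[inside, replaced] <- rep(hap[inside, template, drop = FALSE],
                                     times = length(replaced))
        keep <- rowSums(hap) > 0L | !inside
        tl$hap <- hap[keep, , drop = FALSE]
        tl$pos <- tl$pos[keep]
        pop$tiles[[ti]] <- tl
    }
    pop$sweeps[[length(pop$sweeps) + 1L]] <-
        list(chrom = chrom, start = start, end = end, f = f,
             template = template, replaced = sort(replaced))
    pop
}

#' Plant a segregating deletion
#'
#' Each haplotype carries the deletion with probability \code{q}.  Deleted
#' haplotypes contribute no alleles inside the interval: heterozygous
#' carriers appear homozygous for the retained haplotype's allele, and
#' samples with both haplotypes deleted have missing genotypes.  Carrier
#' read depth over the interval scales by CN/2 in
#' \code{\link{generateDepth}}.
#'
#' @param pop a \code{PopulationSim}.
#' @param chrom,start,end deletion interval (1-based closed).
#' @param q per-haplotype deletion frequency in (0, 1).
#' @return The modified \code{PopulationSim}; the deletion (with the deleted
#'   haplotype index set and per-sample copy numbers) is appended to
#'   \code{pop$deletions}.
#' @export
plantDeletion <- function(pop, chrom, start, end, q = 0.9) {
    stopifnot(inherits(pop, "PopulationSim"))
    if (q <= 0 || q >= 1) stop("carrier frequency q must be in (0, 1)")
    .checkInterval(pop, chrom, start, end)
    n <- .popHapCount(pop)
    delHap <- runif(n) < q
    cn <- 2L - (delHap[seq(1, n, by = 2)] + delHap[seq(2, n, by = 2)])
    pop$deletions[[length(pop$deletions) + 1L]] <-
        list(chrom = chrom, start = start, end = end, q = q,
             delHap = delHap, sampleCn = as.integer(cn),
             carriers = which(cn < 2L))
    pop
}

# deletion state of every haplotype at a vector of positions on one
# chromosome: returns n x length(pos) logical matrix
.deletionMask <- function(pop, chrom, pos) {
    n <- .popHapCount(pop)
    del <- matrix(FALSE, nrow = n, ncol = length(pos))
    for (d in pop$deletions) {
        if (d$chrom != chrom) next
        inside <- pos >= d$start & pos <= d$end
        if (any(inside)) del[d$delHap, inside] <- TRUE
    }
    del
}

# assemble per-chromosome apparent genotype data: positions, per-sample
# genotype strings (optional) and apparent allele counts, honouring deletions
.apparentChrom <- function(pop, chrom, genotypes = TRUE) {
    n <- .popHapCount(pop)
    nd <- pop$nDiploid
    posL <- list(); hapL <- list()
    for (tl in pop$tiles) {
        if (tl$chrom != chrom) next
        if (length(tl$pos)) {
            posL[[length(posL) + 1L]] <- tl$pos
            hapL[[length(hapL) + 1L]] <- tl$hap
        }
        if (length(tl$fixedPos)) {
            posL[[length(posL) + 1L]] <- tl$fixedPos
            hapL[[length(hapL) + 1L]] <-
                matrix(1L, nrow = length(tl$fixedPos), ncol = n)
        }
    }
    if (!length(posL))
        return(list(pos = integer(0),
                    gt = matrix(character(0), 0, nd),
                    ref = integer(0), alt = integer(0), miss = integer(0)))
    pos <- unlist(posL)
    hap <- do.call(rbind, hapL)
    o <- order(pos)
    pos <- pos[o]
    hap <- hap[o, , drop = FALSE]
    del <- t(.deletionMask(pop, chrom, pos))   # sites x haplotypes
    i1 <- seq(1L, n, by = 2L)
    i2 <- seq(2L, n, by = 2L)
    a <- hap[, i1, drop = FALSE]
    b <- hap[, i2, drop = FALSE]
    d1 <- del[, i1, drop = FALSE]
    d2 <- del[, i2, drop = FALSE]
    bothDel <- d1 & d2
    # apparent per-sample allele pair: deleted haplotype's allele replaced by
    # the retained one; both deleted -> missing
    aApp <- ifelse(d1 & !d2, b, a)
    bApp <- ifelse(d2 & !d1, a, b)
    altC <- ifelse(bothDel, 0L, aApp + bApp)
    refC <- ifelse(bothDel, 0L, 2L - aApp - bApp)
    missC <- ifelse(bothDel, 2L, 0L)
    keep <- rowSums(altC) >= 1L   # a caller emits no record without alt evidence
    gt <- NULL
    if (genotypes) {
        gt <- matrix(paste0(aApp, "/", bApp), nrow = nrow(hap), ncol = nd)
        gt[bothDel] <- "./."
        gt <- gt[keep, , drop = FALSE]
    }
    list(pos = pos[keep], gt = gt,
         ref = as.integer(rowSums(refC))[keep],
         alt = as.integer(rowSums(altC))[keep],
         miss = as.integer(rowSums(missC))[keep])
}

#' Sample ids of a PopulationSim
#' @param pop a \code{PopulationSim}.
#' @return character vector like \code{s01 ... s20}.
#' @export
sampleIds <- function(pop) {
    sprintf("s%02d", seq_len(pop$nDiploid))
}

#' Write a PopulationSim as VCF
#'
#' Emits a minimal valid VCF 4.2 with GT-only genotypes, one record per
#' apparent biallelic SNP (sites with no apparent alternate allele are not
#' emitted, as in real callsets).
#'
#' @param pop a \code{PopulationSim}.
#' @param path output path (plain text).
#' @return \code{path}, invisibly.
#' @export
writeVcf <- function(pop, path) {
    stopifnot(inherits(pop, "PopulationSim"))
    ids <- sampleIds(pop)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##contig=<ID=%s,length=%d>", pop$spec@chrom,
                         as.integer(pop$spec@length)),
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
               con)
    for (chrom in pop$spec@chrom) {
        ap <- .apparentChrom(pop, chrom)
        if (!length(ap$pos)) next
        lines <- do.call(paste, c(list(chrom, ap$pos, ".", "A", "G", ".",
                                       "PASS", ".", "GT"),
                                  lapply(seq_len(ncol(ap$gt)),
                                         function(j) ap$gt[, j]),
                                  list(sep = "\t")))
        writeLines(lines, con)
    }
    invisible(path)
}

#' VariantTable of a PopulationSim without a VCF round trip
#'
#' Produces exactly the table \code{\link{readPopulationVcf}} would return
#' for the VCF written by \code{\link{writeVcf}}.
#'
#' @param pop a \code{PopulationSim}.
#' @return A \linkS4class{VariantTable}.
#' @export
asVariantTable <- function(pop) {
    stopifnot(inherits(pop, "PopulationSim"))
    out <- list()
    for (chrom in pop$spec@chrom) {
        ap <- .apparentChrom(pop, chrom, genotypes = FALSE)
        if (!length(ap$pos)) next
        out[[chrom]] <- data.frame(chrom = chrom, pos = ap$pos,
                                   refCount = ap$ref, altCount = ap$alt,
                                   missingCount = ap$miss,
                                   stringsAsFactors = FALSE)
    }
    sites <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
             else data.frame(chrom = character(0), pos = integer(0),
                             refCount = integer(0), altCount = integer(0),
                             missingCount = integer(0))
    variantTable(pop$population, pop$nDiploid, sites)
}

#' Generate per-sample read-depth tracks
#'
#' Per 1000-bp window: a shared GC fraction drawn from Beta(42, 58) (mean
#' 0.42, roughly the mammalian genome-wide distribution), and an observed
#' read count that is Poisson around
#' \code{coverage * windowSize / readLength * bias(gc) * CN/2}, i.e. the
#' expected number of \code{readLength}-bp reads giving fold-coverage
#' \code{coverage} at the diploid state, modulated by the unimodal quadratic
#' bias \code{max(0.05, 1 - biasStrength * (gc - 0.45)^2)} (normalized to 1
#' at its mode).  Copy-number variants (including the deletions of a
#' \code{PopulationSim}) scale the expectation by CN/2.
#'
#' @param spec a \linkS4class{GenomeSpec}.
#' @param samples character vector of sample ids.
#' @param coverage mean fold coverage at the diploid state (default 60,
#'   chosen so Poisson read-count noise at the 1-kb window scale has a
#'   negligible diploid miscall rate).
#' @param seed RNG seed.
#' @param cnvs optional data.frame (\code{sample}, \code{chrom},
#'   \code{start}, \code{end}, \code{cn}) of planted copy-number variants.
#' @param windowSize depth window size (default 1000 bp).
#' @param readLength read length in bp (default 150); together with
#'   \code{coverage} it sets the Poisson scale (200 reads per 1-kb window at
#'   the defaults).
#' @param biasStrength curvature of the GC bias (default 3; 0 = flat).
#' @param gcMode GC fraction at which the bias peaks (default 0.45).
#' @return data.frame with columns \code{sample}, \code{chrom},
#'   \code{start} (0-based), \code{end}, \code{depth}, \code{gc}.
#' @export
generateDepth <- function(spec, samples, coverage = 60, seed = 1L,
                          cnvs = NULL, windowSize = 1000, readLength = 150,
                          biasStrength = 3, gcMode = 0.45) {
    stopifnot(is(spec, "GenomeSpec"))
    if (coverage <= 0) stop("coverage must be positive")
    set.seed(as.integer(seed))
    wins <- list()
    for (ci in seq_along(spec@chrom)) {
        len <- spec@length[ci]
        s0 <- seq(0, len - 1, by = windowSize)
        wins[[ci]] <- data.frame(chrom = spec@chrom[ci], start = s0,
                                 end = pmin(s0 + windowSize, len))
    }
    wins <- do.call(rbind, wins)
    gcv <- rbeta(nrow(wins), 42, 58)
    bias <- pmax(0.05, 1 - biasStrength * (gcv - gcMode)^2)
    out <- list()
    for (sm in samples) {
        cn <- rep(2, nrow(wins))
        if (!is.null(cnvs) && nrow(cnvs)) {
            cc <- cnvs[cnvs$sample == sm, , drop = FALSE]
            for (i in seq_len(nrow(cc)))
                cn[wins$chrom == cc$chrom[i] & wins$start >= cc$start[i] - 1 &
                   wins$end <= cc$end[i]] <- cc$cn[i]
        }
        lam <- coverage / readLength * (wins$end - wins$start) * bias * cn / 2
        out[[sm]] <- data.frame(sample = sm, wins,
                                depth = rpois(nrow(wins), lam), gc = gcv,
                                stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Planted copy-number variants of a PopulationSim
#'
#' Expands the deletions into the per-sample CNV table consumed by
#' \code{\link{generateDepth}}.
#'
#' @param pop a \code{PopulationSim}.
#' @return data.frame (\code{sample}, \code{chrom}, \code{start},
#'   \code{end}, \code{cn}), one row per carrier per deletion.
#' @export
deletionCnvs <- function(pop) {
    ids <- sampleIds(pop)
    out <- list()
    for (d in pop$deletions) {
        if (!length(d$carriers)) next
        out[[length(out) + 1L]] <-
            data.frame(sample = ids[d$carriers], chrom = d$chrom,
                       start = d$start, end = d$end,
                       cn = d$sampleCn[d$carriers], stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(sample = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          cn = integer(0)))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Generate a gene annotation, gene sets and DE tables
#'
#' Genes are placed uniformly (lengths log-normal, median 20 kb); baseline
#' set membership is Bernoulli(p0), and genes overlapping a sweep interval
#' have their membership odds multiplied by the set's multiplier (multiplier
#' 1 = calibration null).  Per-tissue differential-expression flags are
#' generated the same way.
#'
#' @param spec a \linkS4class{GenomeSpec}.
#' @param nGenes gene count (default 600).
#' @param sweepIntervals GRanges of sweep intervals (or NULL).
#' @param setP0 named baseline membership probabilities (default
#'   \code{c(omim = 0.2, gwas = 0.15)}).
#' @param setMultiplier named odds multipliers for genes overlapping sweeps
#'   (default all 1).
#' @param tissues tissue names for DE tables.
#' @param deP0 baseline DE probability per tissue (default 0.15).
#' @param deMultiplier DE odds multiplier for sweep-overlapping genes.
#' @param codingProb probability a gene is protein-coding (default 0.9).
#' @param seed RNG seed.
#' @return list with \code{annotation} (GRanges), \code{geneSets} (named
#'   list), \code{deTable} (data.frame) and \code{truth} (the parameters).
#' @export
generateAnnotationAndSets <- function(spec, nGenes = 600,
                                      sweepIntervals = NULL,
                                      setP0 = c(omim = 0.2, gwas = 0.15),
                                      setMultiplier = NULL,
                                      tissues = c("brain", "liver", "spleen"),
                                      deP0 = 0.15, deMultiplier = 1,
                                      codingProb = 0.9, seed = 1L) {
    stopifnot(is(spec, "GenomeSpec"))
    if (!is.null(setMultiplier) && any(setMultiplier < 1))
        stop("odds multipliers must be >= 1")
    if (is.null(setMultiplier))
        setMultiplier <- setNames(rep(1, length(setP0)), names(setP0))
    set.seed(as.integer(seed))
    if (nGenes == 0) {
        ann <- GRanges(seqinfo = asSeqinfo(spec))
        mcols(ann) <- DataFrame(gene_id = character(0), coding = logical(0))
        return(list(annotation = ann,
                    geneSets = lapply(setP0, function(x) character(0)),
                    deTable = data.frame(tissue = character(0),
                                         gene = character(0), de = logical(0)),
                    truth = list(nGenes = 0)))
    }
    glen <- pmax(500, round(rlnorm(nGenes, log(20000), 0.6)))
    chromIdx <- sample.int(length(spec@chrom), nGenes, replace = TRUE,
                           prob = spec@length)
    glen <- pmin(glen, spec@length[chromIdx] - 1)
    gstart <- floor(runif(nGenes, 0, spec@length[chromIdx] - glen)) + 1
    o <- order(chromIdx, gstart)
    chromIdx <- chromIdx[o]; gstart <- gstart[o]; glen <- glen[o]
    ann <- GRanges(spec@chrom[chromIdx], IRanges(gstart, gstart + glen - 1),
                   seqinfo = asSeqinfo(spec))
    mcols(ann) <- DataFrame(gene_id = sprintf("g%04d", seq_len(nGenes)),
                            coding = runif(nGenes) < codingProb)
    names(ann) <- ann$gene_id
    inSweep <- if (is.null(sweepIntervals) || length(sweepIntervals) == 0)
        rep(FALSE, nGenes) else overlapsAny(ann, sweepIntervals, minoverlap = 1L)
    memberProb <- function(p0, mult) {
        odds <- p0 / (1 - p0) * ifelse(inSweep, mult, 1)
        odds / (1 + odds)
    }
    geneSets <- lapply(names(setP0), function(sn) {
        p <- memberProb(setP0[[sn]], setMultiplier[[sn]])
        ann$gene_id[runif(nGenes) < p]
    })
    names(geneSets) <- names(setP0)
    deTable <- do.call(rbind, lapply(tissues, function(tis) {
        p <- memberProb(deP0, deMultiplier)
        data.frame(tissue = tis, gene = ann$gene_id,
                   de = runif(nGenes) < p, stringsAsFactors = FALSE)
    }))
    list(annotation = ann, geneSets = geneSets, deTable = deTable,
         truth = list(nGenes = nGenes, setP0 = as.list(setP0),
                      setMultiplier = as.list(setMultiplier), deP0 = deP0,
                      deMultiplier = deMultiplier, tissues = tissues,
                      seed = as.integer(seed)))
}

#' Write a gene annotation as GFF3
#'
#' @param annotation gene annotation GRanges.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneAnnotation <- function(annotation, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    if (length(annotation)) {
        bio <- ifelse(annotation$coding, "protein_coding", "lincRNA")
        writeLines(paste(as.character(seqnames(annotation)), "sweepscan",
                         "gene", start(annotation), end(annotation), ".",
                         "+", ".",
                         sprintf("ID=%s;biotype=%s", annotation$gene_id, bio),
                         sep = "\t"), con)
    }
    invisible(path)
}

#' Generate a complete synthetic dataset on disk
#'
#' Emits every input the pipeline reads - chromosome table, population VCF,
#' per-sample depth tracks, gene annotation (GFF3), gene-set TSV, DE TSV, a
#' ready-to-run pipeline config - plus a ground-truth manifest (JSON) that
#' records all generator parameters, planted features and the master seed.
#'
#' @param dir output directory (created).
#' @param spec a \linkS4class{GenomeSpec}; default 5 chromosomes of 2 Mb.
#' @param msText demographic model command; default the Indian
#'   M. m. castaneus-style bottleneck-then-expansion model.
#' @param nDiploid diploid samples (default 20).
#' @param divergence reference divergence per bp (default 0.005).
#' @param coverage mean read depth (default 30).
#' @param sweeps data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{f}) of sweeps to plant, or NULL.
#' @param deletions data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{q}) of deletions to plant, or NULL.
#' @param nGenes,setMultiplier,deMultiplier,tissues passed to
#'   \code{\link{generateAnnotationAndSets}}.
#' @param seed master seed; every RNG stream derives from it.
#' @return The manifest, invisibly.
#' @export
generateDataset <- function(dir,
                            spec = genomeSpec(paste0("chr", 1:5), rep(2e6, 5)),
                            msText = "-t 1230 -eN 0.368975226 0.406795355 -eN 0.233061222 0.640302075",
                            nDiploid = 20L, divergence = 0.005, coverage = 60,
                            sweeps = NULL, deletions = NULL, nGenes = 600,
                            setMultiplier = NULL, deMultiplier = 1,
                            tissues = c("brain", "liver", "spleen"),
                            seed = 1L) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "depth"), showWarnings = FALSE)
    model <- parseMsCommand(msText, sampleSize = 2L * nDiploid)
    pop <- simulatePopulation(spec, model, nDiploid, seed = seed,
                              divergence = divergence)
    set.seed(as.integer(seed) + 1L)
    if (!is.null(sweeps))
        for (i in seq_len(nrow(sweeps)))
            pop <- plantSweep(pop, sweeps$chrom[i], sweeps$start[i],
                              sweeps$end[i], sweeps$f[i])
    if (!is.null(deletions))
        for (i in seq_len(nrow(deletions)))
            pop <- plantDeletion(pop, deletions$chrom[i], deletions$start[i],
                                 deletions$end[i], deletions$q[i])
    writeGenomeSpec(spec, file.path(dir, "genome.tsv"))
    writeVcf(pop, file.path(dir, paste0(pop$population, ".vcf")))
    ids <- sampleIds(pop)
    depth <- generateDepth(spec, ids, coverage, seed = as.integer(seed) + 2L,
                           cnvs = deletionCnvs(pop))
    for (sm in ids) {
        d <- depth[depth$sample == sm, c("chrom", "start", "end", "depth", "gc")]
        utils::write.table(cbind(d[1:4], gc = sprintf("%.4f", d$gc)),
                           file.path(dir, "depth", paste0(sm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
    }
    sweepGr <- if (!is.null(sweeps))
        GRanges(sweeps$chrom, IRanges(sweeps$start, sweeps$end)) else NULL
    sets <- generateAnnotationAndSets(spec, nGenes = nGenes,
                                      sweepIntervals = sweepGr,
                                      setMultiplier = setMultiplier,
                                      deMultiplier = deMultiplier,
                                      tissues = tissues,
                                      seed = as.integer(seed) + 3L)
    writeGeneAnnotation(sets$annotation, file.path(dir, "genes.gff3"))
    setTab <- do.call(rbind, lapply(names(sets$geneSets), function(sn)
        if (length(sets$geneSets[[sn]]))
            data.frame(set = sn, gene = sets$geneSets[[sn]]) else NULL))
    if (is.null(setTab)) setTab <- data.frame(set = character(0), gene = character(0))
    utils::write.table(setTab, file.path(dir, "genesets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(tissue = sets$deTable$tissue,
                                  gene = sets$deTable$gene,
                                  de = as.integer(sets$deTable$de)),
                       file.path(dir, "de.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- list(
        population = pop$population, seed = as.integer(seed),
        genome = list(chrom = spec@chrom, length = spec@length),
        model = msCommand(model), nDiploid = nDiploid,
        divergence = divergence, coverage = coverage,
        tileLength = pop$tileLength,
        sweeps = lapply(pop$sweeps, function(s)
            s[c("chrom", "start", "end", "f", "template")]),
        deletions = lapply(pop$deletions, function(d)
            list(chrom = d$chrom, start = d$start, end = d$end, q = d$q,
                 carriers = ids[d$carriers],
                 carrierCn = d$sampleCn[d$carriers])),
        genes = sets$truth)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    config <- list(
        genome = "genome.tsv",
        window = 20000, step = 10000, min_snps = 50,
        null = list(sims = 10000, seed = as.integer(seed) + 4L),
        cn = list(window = 1000, max_nondiploid_frac = 0),
        enrichment = list(replicates = 1000, de_replicates = 10000,
                          seed = as.integer(seed) + 5L,
                          gene_annotation = "genes.gff3",
                          gene_sets = "genesets.tsv", de_tables = "de.tsv"),
        populations = list(list(id = pop$population,
                                vcf = paste0(pop$population, ".vcf"),
                                ms_command = msCommand(model),
                                diploid_count = nDiploid,
                                depth_dir = "depth")),
        outdir = "out")
    yaml::write_yaml(config, file.path(dir, "config.yaml"))
    invisible(manifest)
}
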