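# Pipeline orchestration: a declarative YAML/JSON config drives the stages
# scan -> null -> call -> cnfilter -> enrich, each resumable from its on-disk
# artifacts.  All seeds are explicit in the config; every stage logs
# parameters and counts and records input digests in a run manifest.

#' Read and validate a pipeline configuration
#'
#' YAML (or JSON) with fields: \code{genome}, \code{window}, \code{step},
#' \code{min_snps}, \code{null} (\code{sims}, \code{seed}), \code{cn}
#' (\code{window}, \code{max_nondiploid_frac}), \code{enrichment}
#' (\code{replicates}, \code{de_replicates}, \code{seed},
#' \code{gene_annotation}, \code{gene_sets}, \code{de_tables}),
#' \code{populations} (list of \code{id}, \code{vcf}, optional
#' \code{samples}, \code{ms_command}, \code{diploid_count},
#' \code{depth_dir}), \code{outdir}.  Relative paths resolve against the
#' config file's directory.  Every referenced input path must exist.
#'
#' @param path config file path.
#' @return The config as a named list with absolute paths and a
#'   \code{baseDir} element.
#' @export
readPipelineConfig <- function(path) {
    cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
           else yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    cfg$baseDir <- base
    res <- function(p) {
        if (is.null(p)) return(NULL)
        ifelse(grepl("^/", p), p, file.path(base, p))
    }
    cfg$genome <- res(cfg$genome)
    if (!file.exists(cfg$genome)) stop("genome table not found: ", cfg$genome)
    cfg$window <- cfg$window %||% 20000
    cfg$step <- cfg$step %||% 10000
    cfg$min_snps <- cfg$min_snps %||% 50
    cfg$null$sims <- cfg$null$sims %||% 10000
    if (is.null(cfg$null$seed)) stop("null.seed must be set explicitly")
    cfg$cn$window <- cfg$cn$window %||% 1000
    cfg$cn$max_nondiploid_frac <- cfg$cn$max_nondiploid_frac %||% 0
    if (!is.null(cfg$enrichment)) {
        if (is.null(cfg$enrichment$seed))
            stop("enrichment.seed must be set explicitly")
        cfg$enrichment$replicates <- cfg$enrichment$replicates %||% 1000
        cfg$enrichment$de_replicates <- cfg$enrichment$de_replicates %||% 10000
        for (f in c("gene_annotation", "gene_sets", "de_tables")) {
            cfg$enrichment[[f]] <- res(cfg$enrichment[[f]])
            if (!is.null(cfg$enrichment[[f]]) && !file.exists(cfg$enrichment[[f]]))
                stop(f, " not found: ", cfg$enrichment[[f]])
        }
    }
    for (i in seq_along(cfg$populations)) {
        p <- cfg$populations[[i]]
        if (is.null(p$id)) stop("population without id")
        p$vcf <- res(p$vcf)
        if (!file.exists(p$vcf)) stop("VCF not found for ", p$id, ": ", p$vcf)
        if (is.null(p$diploid_count)) stop(p$id, ": diploid_count must be set")
        if (!is.null(p$depth_dir)) {
            p$depth_dir <- res(p$depth_dir)
            if (!dir.exists(p$depth_dir))
                stop("depth_dir not found for ", p$id, ": ", p$depth_dir)
        }
        cfg$populations[[i]] <- p
    }
    cfg$outdir <- res(cfg$outdir %||% "out")
    cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.popCfg <- function(config, population) {
    ids <- vapply(config$populations, `[[`, character(1), "id")
    i <- match(population, ids)
    if (is.na(i)) stop("population not in config: ", population)
    config$populations[[i]]
}

.stageFile <- function(config, population, what) {
    file.path(config$outdir, paste0(population, ".", what))
}

.needStage <- function(config, population, what, stage) {
    f <- .stageFile(config, population, what)
    if (!file.exists(f))
        stop("missing artifact ", basename(f), ": run ", stage, " first")
    f
}

.logStage <- function(stage, ...) {
    message("[", stage, "] ", ...)
}

.digest <- function(path) unname(tools::md5sum(path))

.runManifest <- function(config, stage, inputs, outputs, extra = list()) {
    mf <- file.path(config$outdir, "run-manifest.json")
    runs <- if (file.exists(mf)) jsonlite::read_json(mf) else list()
    runs[[stage]] <- c(list(inputs = as.list(.digest(unlist(inputs))),
                            outputs = as.list(.digest(unlist(outputs)))),
                       extra)
    jsonlite::write_json(runs, mf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
}

#' Pipeline stage: windowed statistics scan
#'
#' Reads the population VCF, computes windowed Hp, pi, S, kbar and Tajima's
#' D, applies the SNP-count filter, Z-normalizes, and writes
#' \code{<pop>.windowstats.tsv}.
#'
#' @param config from \code{\link{readPipelineConfig}}.
#' @param population population id.
#' @return The windowed statistics GRanges, invisibly.
#' @export
runScan <- function(config, population) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    p <- .popCfg(config, population)
    spec <- readGenomeSpec(config$genome)
    vt <- readPopulationVcf(p$vcf, samples = unlist(p$samples),
                            population = population)
    if (nHaplotypes(vt) != 2L * p$diploid_count)
        stop("diploid_count disagrees with VCF samples for ", population)
    ws <- windowedStats(vt, makeWindows(spec, config$window, config$step))
    ws <- filterMinSnps(ws, config$min_snps)
    .logStage("scan", population, ": ", length(ws), " windows, ",
              attr(ws, "excluded"), " excluded by <", config$min_snps,
              " SNP filter")
    ws <- normalizeStats(ws)
    out <- .stageFile(config, population, "windowstats.tsv")
    writeWindowStats(ws, out)
    zb <- attr(ws, "zbase")
    jsonlite::write_json(lapply(zb, as.list),
                         .stageFile(config, population, "zbase.json"),
                         auto_unbox = TRUE, digits = NA)
    .runManifest(config, paste0("scan.", population), list(p$vcf, config$genome),
                 list(out), list(window = config$window, step = config$step,
                                 min_snps = config$min_snps,
                                 excluded = attr(ws, "excluded")))
    invisible(ws)
}

.readWindowStats <- function(path, spec) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                  seqinfo = asSeqinfo(spec))
    for (cl in setdiff(names(df), c("chrom", "start", "end")))
        mcols(gr)[[cl]] <- df[[cl]]
    gr
}

#' Pipeline stage: neutral null and thresholds
#'
#' Simulates the population's neutral null from its ms command (with
#' reference-fixed site ascertainment matched to the observed VCF) and
#' writes \code{<pop>.null.tsv} and \code{<pop>.thresholds.json}.
#'
#' @inheritParams runScan
#' @return The \linkS4class{ThresholdSet}, invisibly.
#' @export
runNull <- function(config, population) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    p <- .popCfg(config, population)
    if (is.null(p$ms_command)) stop("no ms_command for ", population)
    wsFile <- .needStage(config, population, "windowstats.tsv", "scan")
    spec <- readGenomeSpec(config$genome)
    ws <- .readWindowStats(wsFile, spec)
    zb <- jsonlite::read_json(.stageFile(config, population, "zbase.json"),
                              simplifyVector = TRUE)
    attr(ws, "zbase") <- lapply(zb, unlist)
    model <- parseMsCommand(p$ms_command, sampleSize = 2L * p$diploid_count)
    vt <- readPopulationVcf(p$vcf, samples = unlist(p$samples),
                            population = population)
    fixedRate <- estimateFixedSiteRate(vt, config$window)
    null <- buildNull(model, config$window, config$null$sims,
                      seed = config$null$seed, fixedPerWindow = fixedRate,
                      population = population)
    thr <- deriveThresholds(null, ws)
    .logStage("null", population, ": ", config$null$sims, " simulations, ",
              sprintf("fixed/window %.1f", fixedRate))
    nullFile <- .stageFile(config, population, "null.tsv")
    utils::write.table(signif(nullStats(null), 10), nullFile, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    thrFile <- .stageFile(config, population, "thresholds.json")
    jsonlite::write_json(list(population = population,
                              raw = as.list(rawThresholds(thr)),
                              z = as.list(zThresholds(thr)),
                              nSims = thr@nSims,
                              seed = config$null$seed,
                              fixedPerWindow = fixedRate),
                         thrFile, auto_unbox = TRUE, digits = NA)
    .runManifest(config, paste0("null.", population), list(wsFile),
                 list(nullFile, thrFile),
                 list(sims = config$null$sims, seed = config$null$seed))
    invisible(thr)
}

.readThresholds <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    toNum <- function(x) {
        v <- vapply(x, function(e) if (is.null(e)) NA_real_ else as.numeric(e),
                    numeric(1))
        v
    }
    new("ThresholdSet", population = j$population,
        raw = toNum(j$raw), z = toNum(j$z), nSims = as.integer(j$nSims))
}

#' Pipeline stage: call candidate sweep regions
#'
#' Flags outlier windows against the thresholds, applies the Hp-plus-one-
#' other co-support rule, collapses adjacent candidate windows, annotates
#' genes, and writes \code{<pop>.regions.bed} (pre-CN-filter) and
#' \code{<pop>.region_genes.tsv}.
#'
#' @inheritParams runScan
#' @return The region GRanges, invisibly.
#' @export
runCall <- function(config, population) {
    p <- .popCfg(config, population)
    wsFile <- .needStage(config, population, "windowstats.tsv", "scan")
    thrFile <- .needStage(config, population, "thresholds.json", "null")
    spec <- readGenomeSpec(config$genome)
    ws <- .readWindowStats(wsFile, spec)
    thr <- .readThresholds(thrFile)
    ws <- flagOutliers(ws, thr)
    regions <- callRegions(ws, population)
    genesFile <- NULL
    if (!is.null(config$enrichment$gene_annotation)) {
        ann <- readGeneAnnotation(config$enrichment$gene_annotation)
        regions <- annotateRegionGenes(regions, ann)
        tab <- data.frame(
            population = population,
            chrom = rep(as.character(seqnames(regions)), lengths(regions$genes)),
            start = rep(start(regions) - 1L, lengths(regions$genes)),
            end = rep(end(regions), lengths(regions$genes)),
            gene = unlist(regions$genes))
        genesFile <- .stageFile(config, population, "region_genes.tsv")
        utils::write.table(tab, genesFile, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    .logStage("call", population, ": ", length(regions), " candidate region(s)")
    bed <- .stageFile(config, population, "regions.bed")
    out <- regions
    mcols(out) <- DataFrame(name = population,
                            score = ifelse(is.na(regions$minZHp), 0L,
                                           pmin(1000L, as.integer(round(-100 * regions$minZHp)))))
    writeRegionsBed(out, bed)
    .runManifest(config, paste0("call.", population), list(wsFile, thrFile),
                 c(list(bed), if (!is.null(genesFile)) list(genesFile)),
                 list(regions = length(regions)))
    invisible(regions)
}

.readRegionsBed <- function(path, spec) {
    info <- file.info(path)
    if (!is.na(info$size) && info$size == 0)
        return(GRanges(seqinfo = asSeqinfo(spec)))
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]), seqinfo = asSeqinfo(spec))
}

#' Pipeline stage: copy-number filter
#'
#' Builds per-sample GC-corrected copy-number calls from the depth tracks,
#' intersects the all-sample diploid mask, discards candidate regions
#' overlapping non-diploid sequence, and writes
#' \code{<pop>.regions.retained.bed}, \code{<pop>.regions.discarded.bed},
#' \code{<pop>.cn.tsv} and \code{diploid_mask.<pop>.bed}.
#'
#' @inheritParams runScan
#' @return list(retained, discarded) region GRanges, invisibly.
#' @export
runCnFilter <- function(config, population) {
    p <- .popCfg(config, population)
    bed <- .needStage(config, population, "regions.bed", "call")
    if (is.null(p$depth_dir)) stop("no depth_dir for ", population)
    spec <- readGenomeSpec(config$genome)
    regions <- .readRegionsBed(bed, spec)
    files <- list.files(p$depth_dir, pattern = "\\.tsv$", full.names = TRUE)
    if (!length(files)) stop("no depth tracks in ", p$depth_dir)
    depth <- do.call(rbind, lapply(files, readDepthTable,
                                   windowSize = config$cn$window))
    cn <- estimateCn(gcCorrect(depth))
    mask <- buildDiploidMask(cn)
    res <- filterRegionsByMask(regions, mask, spec,
                               config$cn$max_nondiploid_frac)
    .logStage("cnfilter", population, ": ", length(res$retained),
              " retained, ", length(res$discarded), " discarded")
    cnFile <- .stageFile(config, population, "cn.tsv")
    cnOut <- cn
    cnOut$corrected <- signif(cnOut$corrected, 8)
    cnOut$cnEst <- signif(cnOut$cnEst, 8)
    cnOut$gc <- signif(cnOut$gc, 6)
    utils::write.table(cnOut, cnFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    maskFile <- file.path(config$outdir, paste0("diploid_mask.", population, ".bed"))
    writeRegionsBed(mask, maskFile)
    retFile <- .stageFile(config, population, "regions.retained.bed")
    disFile <- .stageFile(config, population, "regions.discarded.bed")
    writeRegionsBed(res$retained, retFile)
    writeRegionsBed(res$discarded, disFile)
    .runManifest(config, paste0("cnfilter.", population),
                 c(list(bed), as.list(files)),
                 list(cnFile, maskFile, retFile, disFile),
                 list(retained = length(res$retained),
                      discarded = length(res$discarded)))
    invisible(res)
}

#' Pipeline stage: enrichment tests
#'
#' Runs the size-matched region resampling test for every configured gene
#' set (gene and region modes) plus protein-coding overlap, and the
#' gene-subsampling DE permutation test per tissue, on the CN-filtered
#' regions; writes \code{<pop>.enrichment.tsv}.
#'
#' @inheritParams runScan
#' @return The results data.frame, invisibly.
#' @export
runEnrich <- function(config, population) {
    if (is.null(config$enrichment)) stop("no enrichment block in config")
    retFile <- .needStage(config, population, "regions.retained.bed", "cnfilter")
    spec <- readGenomeSpec(config$genome)
    regions <- .readRegionsBed(retFile, spec)
    ann <- readGeneAnnotation(config$enrichment$gene_annotation)
    sets <- readGeneSets(config$enrichment$gene_sets, ann)
    en <- config$enrichment
    rows <- list()
    if (length(regions)) {
        rows$coding <- runGeneSetEnrichment(regions, ann, NULL, spec,
                                            mode = "region",
                                            replicates = en$replicates,
                                            seed = en$seed,
                                            testName = "protein_coding")
        for (sn in names(sets)) {
            for (md in c("gene", "region"))
                rows[[paste(sn, md)]] <-
                    runGeneSetEnrichment(regions, ann, sets[[sn]], spec,
                                         mode = md,
                                         replicates = en$replicates,
                                         seed = en$seed, testName = sn)
        }
    } else {
        .logStage("enrich", population, ": no regions; writing empty results")
    }
    res <- if (length(rows))
        do.call(rbind, c(lapply(rows, function(r) {
            r$tissue <- NA_character_; r$nGenes <- NA_integer_
            r[c("test", "mode", "tissue", "nGenes", "observed", "nullMean",
                "nullSd", "p", "pLabel", "replicates", "seed")]
        }), list(make.row.names = FALSE)))
        else NULL
    if (!is.null(en$de_tables) && length(regions)) {
        regions <- annotateRegionGenes(regions, ann)
        selGenes <- unique(unlist(regions$genes))
        if (length(selGenes)) {
            de <- readDeTable(en$de_tables)
            der <- deOverlapTest(selGenes, de, replicates = en$de_replicates,
                                 seed = en$seed)
            der$mode <- "gene"
            der <- der[c("test", "mode", "tissue", "nGenes", "observed",
                         "nullMean", "nullSd", "p", "pLabel", "replicates",
                         "seed")]
            res <- if (is.null(res)) der else rbind(res, der)
        }
    }
    if (is.null(res))
        res <- data.frame(test = character(0), mode = character(0),
                          tissue = character(0), nGenes = integer(0),
                          observed = numeric(0), nullMean = numeric(0),
                          nullSd = numeric(0), p = numeric(0),
                          pLabel = character(0), replicates = integer(0),
                          seed = integer(0))
    out <- .stageFile(config, population, "enrichment.tsv")
    resOut <- res
    for (cl in c("observed", "nullMean", "nullSd", "p"))
        resOut[[cl]] <- signif(resOut[[cl]], 8)
    utils::write.table(resOut, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    .runManifest(config, paste0("enrich.", population), list(retFile),
                 list(out), list(replicates = en$replicates, seed = en$seed))
    invisible(res)
}

#' Run every pipeline stage for every population
#'
#' @param config from \code{\link{readPipelineConfig}}.
#' @param enrich run the enrichment stage too (default TRUE when the config
#'   has an enrichment block).
#' @return Named list of per-population results, invisibly.
#' @export
runAll <- function(config, enrich = !is.null(config$enrichment)) {
    out <- list()
    for (p in config$populations) {
        runScan(config, p$id)
        runNull(config, p$id)
        runCall(config, p$id)
        res <- runCnFilter(config, p$id)
        if (enrich) runEnrich(config, p$id)
        out[[p$id]] <- res
    }
    invisible(out)
}
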