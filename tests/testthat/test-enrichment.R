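test_that("size-matched region sets honour lengths, bounds and non-overlap", {
    gs <- genomeSpec(c("chr1", "chr2"), c(1e7, 5e6))
    set.seed(3)
    r <- sampleMatchedRegions(20000, gs)
    expect_equal(width(r), 20000)
    expect_lte(end(r), chromLengths(gs)[as.character(seqnames(r))])
    expect_gte(start(r), 1)

    lens <- c(100000, 50000, 20000)
    for (i in 1:100) {
        rr <- sampleMatchedRegions(lens, gs)
        expect_setequal(width(rr), lens)
        expect_true(isDisjoint(rr))
    }

    expect_error(sampleMatchedRegions(2e7, gs), "exceed")
    # an exclusion track that blocks almost everything triggers the cap
    excl <- GRanges(c("chr1", "chr2"), IRanges(1, c(1e7 - 10, 5e6 - 10)))
    expect_error(sampleMatchedRegions(5000, gs, excluded = excl, maxTries = 50),
                 "constrained")
    # sampled regions avoid the excluded intervals when possible
    excl2 <- GRanges("chr1", IRanges(1, 1e7))
    set.seed(4)
    r2 <- replicate(20, as.character(seqnames(sampleMatchedRegions(1000, gs, excluded = excl2))))
    expect_true(all(r2 == "chr2"))
})

test_that("region- and gene-mode fractions follow their definitions", {
    ann <- GRanges("chr1", IRanges(seq(1, by = 10000, length.out = 10),
                                   width = 2000))
    mcols(ann) <- S4Vectors::DataFrame(gene_id = paste0("g", 1:10),
                                       coding = rep(c(TRUE, FALSE), 5))
    regions <- GRanges("chr1", IRanges(c(1, 30001), c(15000, 45000)))
    # every region overlaps a protein-coding gene
    expect_equal(regionGeneSetFraction(regions, ann, NULL, "region"), 1)
    # gene mode: 4 genes overlapped (g1, g2, g4, g5), 2 in the set
    expect_equal(regionGeneSetFraction(regions, ann, c("g1", "g4"), "gene"), 0.5)
    expect_equal(regionGeneSetFraction(regions, ann, paste0("g", 1:10), "gene"), 1)
    emptyReg <- GRanges("chr1", IRanges(5e6, 5e6 + 1000))
    expect_warning(f <- regionGeneSetFraction(emptyReg, ann, NULL, "gene"),
                   "no genes")
    expect_equal(f, 0)
})

test_that("empirical p is the plain proportion with conservative ties", {
    expect_equal(empiricalP(0.5, c(0.1, 0.2, 0.9))$p, 1 / 3)
    # saturation: observed equals every null value
    expect_equal(empiricalP(1, rep(1, 100))$p, 1)
    # observed above every null: p = 0 reported as < 1/replicates
    res <- empiricalP(0.9, runif(1000, 0, 0.5))
    expect_equal(res$p, 0)
    expect_equal(res$label, "< 0.001")
    # observed at the null median
    set.seed(8)
    null <- runif(10001)
    expect_lt(abs(empiricalP(median(null), null)$p - 0.5), 0.02)
    # one replicate: p in {0, 1}
    expect_true(empiricalP(0.5, 0.4)$p %in% c(0, 1))
    expect_true(empiricalP(0.5, 0.6)$p %in% c(0, 1))
})

test_that("the fast replicate fraction matches the GRanges implementation", {
    gs <- genomeSpec(c("chr1", "chr2"), c(2e6, 1e6))
    sets <- generateAnnotationAndSets(gs, nGenes = 200, seed = 13)
    ann <- sets$annotation
    byChrom <- split(data.frame(chrom = as.character(seqnames(ann)),
                                start = start(ann), end = end(ann),
                                qual = ann$gene_id %in% sets$geneSets$omim),
                     as.character(seqnames(ann)))
    byChrom <- lapply(byChrom, function(d) d[order(d$start), ])
    maxLen <- max(width(ann))
    set.seed(14)
    for (i in 1:25) {
        rr <- sweepscan:::.sampleRegionsInternal(c(80000, 40000, 20000),
                                                 gs@chrom, gs@length, NULL, 1000)
        gr <- GRanges(rr$chrom, IRanges(rr$start, rr$end))
        for (md in c("region", "gene")) {
            slow <- suppressWarnings(
                regionGeneSetFraction(gr, ann, sets$geneSets$omim, md))
            fast <- sweepscan:::.fastFraction(rr, byChrom, maxLen, md)
            expect_equal(fast, slow)
        }
    }
})

test_that("gene-set enrichment is reproducible and detects planted signal", {
    gs <- genomeSpec(paste0("chr", 1:5), rep(2e6, 5))
    regions <- GRanges(paste0("chr", 1:5), IRanges(500001, width = 150000))
    planted <- generateAnnotationAndSets(gs, nGenes = 600,
                                         sweepIntervals = regions,
                                         setMultiplier = c(omim = 4, gwas = 1),
                                         seed = 17)
    r1 <- runGeneSetEnrichment(regions, planted$annotation,
                               planted$geneSets$omim, gs,
                               replicates = 400, seed = 5)
    r2 <- runGeneSetEnrichment(regions, planted$annotation,
                               planted$geneSets$omim, gs,
                               replicates = 400, seed = 5)
    expect_identical(r1$p, r2$p)
    expect_identical(attr(r1, "null"), attr(r2, "null"))
    expect_lte(r1$p, 0.05)   # 4x planted odds are detectable
    rNull <- runGeneSetEnrichment(regions, planted$annotation,
                                  planted$geneSets$gwas, gs,
                                  replicates = 400, seed = 5)
    expect_gt(rNull$p, 0.05)
})

test_that("the DE permutation test matches its saturation and null contracts", {
    de <- data.frame(tissue = rep("liver", 50), gene = paste0("g", 1:50),
                     de = TRUE)
    res <- deOverlapTest(paste0("g", 1:10), de, replicates = 50, seed = 2)
    expect_equal(res$observed, 1)
    expect_equal(res$p, 1)   # every null fraction ties the observed

    de$de <- rep(c(TRUE, FALSE), 25)
    expect_warning(res2 <- deOverlapTest(c("g1", "g3", "gX"), de,
                                         replicates = 200, seed = 3),
                   "absent")
    expect_equal(res2$nGenes, 2L)
    expect_error(suppressWarnings(deOverlapTest("gZ", de, replicates = 10,
                                                seed = 1)),
                 "no selection genes")

    res3 <- deOverlapTest(paste0("g", 1:10), de, replicates = 200, seed = 4)
    res4 <- deOverlapTest(paste0("g", 1:10), de, replicates = 200, seed = 4)
    expect_identical(res3$p, res4$p)
})

test_that("threefold DE enrichment among selection genes is detected", {
    # 100 selection genes in a 1000-gene universe: adequately powered for the
    # p <= 0.01 detection bound
    pw <- vapply(1:20, function(i) {
        set.seed(900000 + i)
        genes <- sprintf("g%04d", 1:1000)
        sel <- sample(genes, 100)
        pSel <- (0.15 / 0.85 * 3) / (1 + 0.15 / 0.85 * 3)
        de <- data.frame(tissue = "t1", gene = genes,
                         de = ifelse(genes %in% sel, runif(1000) < pSel,
                                     runif(1000) < 0.15))
        deOverlapTest(sel, de, replicates = 2000, seed = 950000 + i)$p
    }, numeric(1))
    expect_gte(mean(pw <= 0.01), 0.80)
})

test_that("null-calibrated enrichment p values are roughly uniform", {
    # scaled-down calibration: independent annotations, observed regions drawn
    # by the same placement law, multiplier 1
    gs <- genomeSpec(paste0("chr", 1:5), rep(2e6, 5))
    set.seed(29)
    ps <- vapply(1:40, function(i) {
        sets <- generateAnnotationAndSets(gs, nGenes = 150, seed = 1000 + i)
        regions <- sampleMatchedRegions(rep(1e5, 4), gs)
        suppressWarnings(
            runGeneSetEnrichment(regions, sets$annotation,
                                 sets$geneSets$omim, gs, replicates = 100,
                                 seed = 2000 + i))$p
    }, numeric(1))
    expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.005)
})
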