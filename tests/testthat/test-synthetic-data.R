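test_that("neutral genomes are reproducible and match Watterson's expectation", {
    gs <- genomeSpec("chr1", 2e6)   # 100 tiles of 20 kb
    model <- demographicModel(theta = 10, sampleSize = 20, refLength = 20000)
    pop <- simulatePopulation(gs, model, nDiploid = 10, seed = 5, divergence = 0)
    S <- vapply(pop$tiles, function(t) length(t$pos), integer(1))
    a1 <- sum(1 / (1:19))
    expect_lt(abs(mean(S) - 10 * a1), 3 * sd(S) / sqrt(length(S)))

    # same seed: byte-identical VCF; zero theta: header only
    p1 <- withr::local_tempfile(fileext = ".vcf")
    p2 <- withr::local_tempfile(fileext = ".vcf")
    writeVcf(simulatePopulation(gs, model, 10, seed = 5, divergence = 0), p1)
    writeVcf(simulatePopulation(gs, model, 10, seed = 5, divergence = 0), p2)
    expect_identical(readLines(p1), readLines(p2))

    m0 <- demographicModel(theta = 0, sampleSize = 20, refLength = 20000)
    pop0 <- simulatePopulation(genomeSpec("chr1", 1e5), m0, 10, seed = 1,
                               divergence = 0)
    writeVcf(pop0, p1)
    expect_false(any(!startsWith(readLines(p1), "#")))
})

test_that("the VCF writer and reader are exact inverses", {
    gs <- genomeSpec(c("chr1", "chr2"), c(4e5, 2e5))
    pop <- simulatePopulation(gs, defaultTestModel(20), 10, seed = 8)
    set.seed(9)
    pop <- plantSweep(pop, "chr1", 100001, 200000, f = 0.9)
    pop <- plantDeletion(pop, "chr2", 50001, 150000, q = 0.7)
    p <- withr::local_tempfile(fileext = ".vcf")
    writeVcf(pop, p)
    vt <- readPopulationVcf(p, population = pop$population)
    expect_identical(siteTable(vt), siteTable(asVariantTable(pop)))
    expect_equal(nHaplotypes(vt), 20L)
})

test_that("complete sweeps silence within-population variation but keep fixed records", {
    gs <- genomeSpec("chr1", 6e5)
    pop <- simulatePopulation(gs, defaultTestModel(), 20, seed = 12)
    set.seed(13)
    pop <- plantSweep(pop, "chr1", 200001, 400000, f = 1)
    vt <- asVariantTable(pop)
    s <- siteTable(vt)
    inside <- s$pos >= 200001 & s$pos <= 400000
    n <- nHaplotypes(vt)
    # every record inside is fixed for the alternate allele (minor count 0)
    expect_true(all(s$altCount[inside] == n))
    # density: reference divergence plus the template's derived alleles
    expect_gt(sum(inside), 0.005 * 2e5 * 0.5)
    # flanks still segregate
    expect_true(any(s$altCount[!inside] < n))
})

test_that("partial sweeps depress windowed diversity inside the interval", {
    gs <- genomeSpec("chr1", 2e6)
    # haplotype replacement at completeness f leaves ~ (1 - f^2) of pairwise
    # diversity in expectation (0.19 at f = 0.9); per-seed ratios scatter
    # around that value
    piRatio <- vapply(1:8, function(seed) {
        pop <- simulatePopulation(gs, defaultTestModel(), 20, seed = seed)
        set.seed(seed + 100)
        pop <- plantSweep(pop, "chr1", 800001, 1200000, f = 0.9)
        ws <- windowedStats(asVariantTable(pop), makeWindows(gs))
        inside <- start(ws) >= 800001 & end(ws) <= 1200000
        mean(mcols(ws)$pi[inside]) / mean(mcols(ws)$pi[!inside])
    }, numeric(1))
    expect_lt(mean(piRatio), 0.22)
    expect_true(all(piRatio < 0.35))

    # f = 1/n leaves diversity essentially unchanged
    pop <- simulatePopulation(gs, defaultTestModel(), 20, seed = 3)
    vt0 <- asVariantTable(pop)
    set.seed(4)
    pop1 <- plantSweep(pop, "chr1", 800001, 1200000, f = 1 / 40)
    vt1 <- asVariantTable(pop1)
    expect_gt(nSites(vt1), 0.95 * nSites(vt0))
})

test_that("deletions alter genotype and depth channels with the same carriers", {
    gs <- genomeSpec("chr1", 4e5)
    pop <- simulatePopulation(gs, defaultTestModel(), 20, seed = 21)
    set.seed(22)
    pop <- plantDeletion(pop, "chr1", 100001, 300000, q = 0.9)
    d <- pop$deletions[[1]]
    homDel <- which(d$sampleCn == 0L)
    hetDel <- which(d$sampleCn == 1L)
    expect_gt(length(homDel), 0)

    p <- withr::local_tempfile(fileext = ".vcf")
    writeVcf(pop, p)
    v <- vcfR::read.vcfR(p, verbose = FALSE)
    pos <- as.integer(v@fix[, "POS"])
    inside <- pos >= 100001 & pos <= 300000
    gt <- sub(":.*", "", v@gt[, -1])
    gt[is.na(gt)] <- "./."   # vcfR reads missing genotypes as NA
    # hom-deleted samples: all interval genotypes missing
    for (sm in homDel)
        expect_true(all(gt[inside, sm] == "./."))
    # het carriers appear homozygous for the retained allele
    for (sm in hetDel)
        expect_true(all(gt[inside, sm] %in% c("0/0", "1/1")))

    # depth channel: same carriers, CN/2 scaling, near-zero for CN 0
    cnvs <- deletionCnvs(pop)
    expect_setequal(cnvs$sample, sampleIds(pop)[c(homDel, hetDel)])
    depth <- generateDepth(gs, sampleIds(pop), coverage = 60, seed = 23,
                           cnvs = cnvs)
    s0 <- sampleIds(pop)[homDel[1]]
    inDel <- depth$sample == s0 & depth$start >= 100000 & depth$end <= 300000
    expect_lt(mean(depth$depth[inDel]), 1)
    cn <- estimateCn(gcCorrect(depth))
    if (length(hetDel)) {
        s1 <- sampleIds(pop)[hetDel[1]]
        inDel1 <- cn$sample == s1 & cn$start >= 100000 & cn$end <= 300000
        expect_gte(mean(cn$cnCall[inDel1] == 1L), 0.9)
    }
})

test_that("generated depth matches its stated coverage and CN expectations", {
    gs <- genomeSpec("chr1", 1e7)   # 10,000 windows
    d <- generateDepth(gs, "s1", coverage = 60, seed = 33, biasStrength = 0)
    foldCov <- mean(d$depth) * 150 / 1000
    expect_lt(abs(foldCov - 60) / 60, 0.02)

    cnv <- data.frame(sample = "s1", chrom = "chr1", start = 2e6 + 1,
                      end = 3e6, cn = 4)
    d4 <- generateDepth(genomeSpec("chr1", 4e6), "s1", coverage = 60,
                        seed = 34, biasStrength = 0, cnvs = cnv)
    inside <- d4$start >= 2e6 & d4$end <= 3e6
    expect_lt(abs(mean(d4$depth[inside]) / mean(d4$depth[!inside]) - 2), 0.05)
})

test_that("gene-set enrichment planting follows the odds transform", {
    gs <- genomeSpec(paste0("chr", 1:5), rep(2e6, 5))
    sweep <- GRanges(paste0("chr", 1:5), IRanges(1, 1e6))  # half the genome
    sets <- generateAnnotationAndSets(gs, nGenes = 4000, sweepIntervals = sweep,
                                      setP0 = c(omim = 0.2),
                                      setMultiplier = c(omim = 3), seed = 41)
    inSweep <- overlapsAny(sets$annotation, sweep)
    member <- sets$annotation$gene_id %in% sets$geneSets$omim
    pIn <- mean(member[inSweep])
    pOut <- mean(member[!inSweep])
    expect_lt(abs(pIn - 0.429), 0.03)    # odds transform of 0.2 with x3
    expect_lt(abs(pOut - 0.2), 0.03)

    # multiplier 1: membership independent of sweep overlap
    setsNull <- generateAnnotationAndSets(gs, nGenes = 4000,
                                          sweepIntervals = sweep, seed = 42)
    memberN <- setsNull$annotation$gene_id %in% setsNull$geneSets$omim
    inN <- overlapsAny(setsNull$annotation, sweep)
    tab <- table(memberN, inN)
    expect_gt(chisq.test(tab)$p.value, 0.01)

    empty <- generateAnnotationAndSets(gs, nGenes = 0, seed = 1)
    expect_length(empty$annotation, 0)
    expect_true(all(lengths(empty$geneSets) == 0))
})

test_that("datasets regenerate bit-for-bit from the manifest parameters", {
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    args <- list(spec = genomeSpec(c("chr1", "chr2"), c(4e5, 4e5)),
                 nDiploid = 6L, nGenes = 60,
                 sweeps = data.frame(chrom = "chr1", start = 100001,
                                     end = 200000, f = 1),
                 seed = 77)
    m1 <- do.call(generateDataset, c(list(d1), args))
    m2 <- do.call(generateDataset, c(list(d2), args))
    for (f in c("synthpop.vcf", "genome.tsv", "genesets.tsv", "de.tsv",
                "genes.gff3", "manifest.json", file.path("depth", "s01.tsv")))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    expect_equal(m1$sweeps[[1]]$chrom, "chr1")
})
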