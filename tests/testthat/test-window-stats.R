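test_that("sliding windows cover the genome and clip at chromosome ends", {
    gs <- genomeSpec("chr1", 50000)
    w <- makeWindows(gs, 20000, 10000)
    expect_equal(start(w), c(1, 10001, 20001, 30001, 40001))
    expect_equal(end(w), c(20000, 30000, 40000, 50000, 50000))
    expect_equal(w$clipped, c(FALSE, FALSE, FALSE, FALSE, TRUE))

    w2 <- makeWindows(genomeSpec("chr1", 15000), 20000, 10000)
    expect_equal(start(w2), c(1, 10001))
    expect_equal(end(w2), c(15000, 15000))

    expect_error(makeWindows(gs, 20000, 25000), "step")
})

test_that("pool heterozygosity matches hand-evaluated values and its bounds", {
    expect_equal(poolHeterozygosity(8, 2), 0.32)
    expect_equal(poolHeterozygosity(c(9, 7), c(1, 3)), 2 * 16 * 4 / 400)
    expect_equal(poolHeterozygosity(c(5, 5, 5), c(5, 5, 5)), 0.5)
    expect_true(is.na(poolHeterozygosity(numeric(0), numeric(0))))
    expect_error(poolHeterozygosity(2, 8), "orient")

    # bounds, with equality at 0.5 iff summed counts are symmetric
    set.seed(5)
    for (i in 1:50) {
        k <- sample(30, 1)
        minor <- sample(0:10, k, replace = TRUE)
        major <- minor + sample(0:10, k, replace = TRUE)
        hp <- poolHeterozygosity(major, minor)
        if (sum(major) + sum(minor) == 0) next
        expect_gte(hp, 0)
        expect_lte(hp, 0.5)
        if (sum(major) == sum(minor)) expect_equal(hp, 0.5)
        else expect_lt(hp, 0.5)
    }
})

test_that("nucleotide diversity equals brute-force pairwise differences", {
    # n = 2 haplotypes differing at 3 sites
    res <- nucleotideDiversity(c(1, 1, 1), c(2, 2, 2), 20000)
    expect_equal(res$pi, 1.5e-4)
    # n = 4, one site with c = 2: 6 haplotype pairs, 4 discordant
    res <- nucleotideDiversity(2, 4, 1000)
    expect_equal(res$kbar, 2 * 2 * 2 / (4 * 3))
    hap <- matrix(c(1, 1, 0, 0), nrow = 1)
    expect_equal(res$kbar, bruteKbar(hap))
    # random windows, n <= 10: pi * L equals mean pairwise difference count
    set.seed(42)
    for (i in 1:25) {
        n <- 2 * sample(1:5, 1)
        S <- sample(1:50, 1)
        hap <- matrix(rbinom(S * n, 1, runif(1, 0.1, 0.9)), nrow = S)
        res <- nucleotideDiversity(rowSums(hap), rep(n, S), 1)
        expect_equal(res$kbar, bruteKbar(hap), tolerance = 1e-12)
    }
    expect_error(nucleotideDiversity(1, 1, 100), "fewer than 2")
    expect_equal(nucleotideDiversity(integer(0), integer(0), 100)$pi, 0)
})

test_that("Tajima's D matches an independent implementation of the constants", {
    expect_equal(tajimasD(16, 3.0, 10), oracleTajimaD(16, 3.0, 10),
                 tolerance = 1e-10)
    set.seed(9)
    for (i in 1:20) {
        n <- sample(4:60, 1)
        S <- sample(1:300, 1)
        kbar <- runif(1, 0, S)
        expect_equal(tajimasD(S, kbar, n), oracleTajimaD(S, kbar, n),
                     tolerance = 1e-10)
    }
    expect_true(is.na(tajimasD(0, 0, 10)))
    a1 <- sum(1 / (1:9))
    expect_equal(tajimasD(5, 5 / a1, 10), 0)
    expect_error(tajimasD(1, 1, 3), "too small")
})

test_that("windowed statistics assign SNPs to every containing window", {
    gs <- genomeSpec("chr1", 50000)
    w <- makeWindows(gs)
    vt <- variantTable("p", 4, data.frame(chrom = "chr1", pos = 15000L,
                                          refCount = 6L, altCount = 2L,
                                          missingCount = 0L))
    ws <- windowedStats(vt, w)
    expect_equal(mcols(ws)$nSNP, c(1L, 1L, 0L, 0L, 0L))

    # empty table: nSNP 0, Hp and D missing, pi 0
    vt0 <- variantTable("p", 4, data.frame(chrom = character(0),
                                           pos = integer(0),
                                           refCount = integer(0),
                                           altCount = integer(0),
                                           missingCount = integer(0)))
    ws0 <- windowedStats(vt0, w)
    expect_true(all(mcols(ws0)$nSNP == 0))
    expect_true(all(is.na(mcols(ws0)$Hp)))
    expect_true(all(is.na(mcols(ws0)$D)))
    expect_true(all(mcols(ws0)$pi == 0))
})

test_that("windowed pi agrees with the brute-force haplotype oracle", {
    set.seed(21)
    n <- 8
    S <- 50
    hap <- matrix(0L, nrow = S, ncol = n)
    for (s in seq_len(S)) {
        k <- sample(1:(n - 1), 1)
        hap[s, sample(n, k)] <- 1L
    }
    pos <- sort(sample(20000, S))
    vt <- vtFromHaplotypes(hap, pos)
    ws <- windowedStats(vt, makeWindows(genomeSpec("chr1", 20000)))
    expect_equal(mcols(ws)$kbar[1], bruteKbar(hap), tolerance = 1e-12)
    expect_equal(mcols(ws)$pi[1], bruteKbar(hap) / 20000, tolerance = 1e-12)
    expect_equal(mcols(ws)$S[1], S)

    # permutation invariance: statistics do not depend on site order
    perm <- sample(S)
    vt2 <- vtFromHaplotypes(hap[perm, ], sort(sample(20000, S)))
    ws2 <- windowedStats(vt2, makeWindows(genomeSpec("chr1", 20000)))
    for (cl in c("Hp", "pi", "S", "D"))
        expect_equal(mcols(ws2)[[cl]][1], mcols(ws)[[cl]][1], tolerance = 1e-12)
})

test_that("sites with missing genotypes feed Hp but not pi/S/D", {
    sites <- data.frame(chrom = "chr1", pos = c(100L, 200L),
                        refCount = c(6L, 5L), altCount = c(2L, 1L),
                        missingCount = c(0L, 2L))
    vt <- variantTable("p", 4, sites)
    ws <- windowedStats(vt, makeWindows(genomeSpec("chr1", 20000)))
    expect_equal(mcols(ws)$nSNP[1], 2L)          # both records counted
    expect_equal(mcols(ws)$S[1], 1L)             # only the complete site
    expect_equal(mcols(ws)$kbar[1], 2 * 2 * 6 / (8 * 7))
    expect_equal(mcols(ws)$Hp[1], poolHeterozygosity(c(6, 5), c(2, 1)))
})

test_that("the SNP-count filter excludes strictly below the threshold", {
    gr <- makeWs("chr1", c(1, 10001, 20001), c(20000, 30000, 40000),
                 nSNP = c(49L, 50L, 51L))
    f <- filterMinSnps(gr, 50)
    expect_equal(mcols(f)$retained, c(FALSE, TRUE, TRUE))
    expect_equal(attr(f, "excluded"), 1L)
    f0 <- filterMinSnps(gr, 0)
    expect_true(all(mcols(f0)$retained))
    expect_warning(filterMinSnps(gr, 1000), "all windows")
})

test_that("Z-normalization uses the population sd and centers retained windows", {
    gr <- makeWs("chr1", c(1, 10001, 20001), c(20000, 30000, 40000),
                 Hp = c(0.1, 0.2, 0.3), pi = c(0.001, 0.002, 0.003),
                 D = c(-1, 0, 1))
    gr <- filterMinSnps(gr, 0)
    ws <- normalizeStats(gr)
    sdPop <- sqrt(2 / 3) * 0.1
    expect_equal(mcols(ws)$ZHp, (c(0.1, 0.2, 0.3) - 0.2) / sdPop)
    expect_equal(mean(mcols(ws)$ZHp), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean(mcols(ws)$ZHp^2)), 1, tolerance = 1e-10)

    grc <- makeWs("chr1", c(1, 10001), c(20000, 30000), Hp = c(0.2, 0.2))
    grc <- filterMinSnps(grc, 0)
    expect_error(normalizeStats(grc, "Hp"), "degenerate")
})

test_that("simulated neutral windows give near-neutral mean Tajima's D", {
    model <- demographicModel(theta = 5, sampleSize = 20, refLength = 20000)
    set.seed(31)
    D <- replicate(2000, {
        s <- simulateWindow(model, 20000)
        if (length(s$counts) == 0) return(NA_real_)
        kbar <- sum(2 * s$counts * (s$n - s$counts) / (s$n * (s$n - 1)))
        tajimasD(length(s$counts), kbar, s$n)
    })
    expect_gt(mean(D, na.rm = TRUE), -0.25)
    expect_lt(mean(D, na.rm = TRUE), 0.10)
})
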