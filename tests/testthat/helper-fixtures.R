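# Shared fixtures: all built in code at test time.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

# write a minimal VCF from a genotype matrix (rows = records)
writeTestVcf <- function(path, chrom, pos, ref, alt, gt) {
    samples <- paste0("s", seq_len(ncol(gt)))
    lines <- c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=1000000>",
               "##contig=<ID=chr2,length=1000000>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"))
    for (i in seq_along(pos))
        lines <- c(lines, paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".",
                                  "PASS", ".", "GT", gt[i, ]), collapse = "\t"))
    writeLines(lines, path)
    path
}

# VariantTable from explicit haplotype matrix (rows = sites, cols = haplotypes)
vtFromHaplotypes <- function(hap, pos, chrom = "chr1", population = "test") {
    n <- ncol(hap)
    stopifnot(n %% 2 == 0)
    alt <- as.integer(rowSums(hap))
    variantTable(population, n / 2,
                 data.frame(chrom = chrom, pos = pos, refCount = n - alt,
                            altCount = alt, missingCount = 0L))
}

# brute-force mean pairwise difference count over all haplotype pairs
bruteKbar <- function(hap) {
    n <- ncol(hap)
    tot <- 0
    for (i in seq_len(n - 1))
        for (j in seq(i + 1, n))
            tot <- tot + sum(hap[, i] != hap[, j])
    tot / (n * (n - 1) / 2)
}

# independent Tajima (1989) implementation used as the D oracle
oracleTajimaD <- function(S, kbar, n) {
    a1 <- sum(1 / seq_len(n - 1))
    a2 <- sum(1 / seq_len(n - 1)^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# demographic model of the default synthetic population (bottleneck then
# expansion, castaneus-like)
defaultTestModel <- function(n = 40L)
    parseMsCommand("-t 1230 -eN 0.368975226 0.406795355 -eN 0.233061222 0.640302075",
                   sampleSize = n)

# windowed statistics GRanges built directly (for caller tests)
makeWs <- function(chrom, start, end, nSNP = 100, Hp = 0.2, pi = 0.002,
                   D = 0, ZHp = 0, retained = TRUE) {
    gr <- GRanges(chrom, IRanges(start, end))
    mcols(gr) <- S4Vectors::DataFrame(nSNP = nSNP, n = 40L, Hp = Hp, S = nSNP,
                                      kbar = pi * 20000, pi = pi, D = D,
                                      retained = retained, ZHp = ZHp,
                                      Zpi = 0, ZD = 0)
    gr
}

thresholdsFor <- function(Hp, pi, D, pop = "test") {
    new("ThresholdSet", population = pop,
        raw = c(Hp = Hp, pi = pi, D = D),
        z = c(Hp = NA_real_, pi = NA_real_, D = NA_real_), nSims = 1L)
}
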