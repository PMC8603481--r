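# Windowed diversity statistics: pool heterozygosity (Hp), nucleotide
# diversity (pi) and Tajima's D in sliding windows, the minimum-SNP filter,
# and per-population Z-normalization.

#' Sliding windows over a genome
#'
#' Windows start at position 1 of each chromosome, advance by \code{step} and
#' are clipped at the chromosome end; every base is covered by at least one
#' window.  Trailing windows shorter than \code{window} are flagged in the
#' \code{clipped} metadata column.
#'
#' @param spec a \linkS4class{GenomeSpec}.
#' @param window window size in bp (default 20000).
#' @param step step size in bp (default 10000); must not exceed \code{window}.
#' @return Sorted GRanges with a \code{clipped} metadata column.
#' @examples
#' gs <- genomeSpec("chr1", 50000)
#' makeWindows(gs, 20000, 10000)
#' @export
makeWindows <- function(spec, window = 20000, step = 10000) {
    stopifnot(is(spec, "GenomeSpec"))
    if (window <= 0) stop("window must be positive")
    if (step <= 0 || step > window) stop("step must be in (0, window]")
    si <- asSeqinfo(spec)
    grl <- lapply(seq_along(spec@chrom), function(i) {
        len <- spec@length[i]
        starts <- seq(0, max(0, len - 1), by = step)
        starts <- starts[starts < len]
        ends <- pmin(starts + window, len)
        GRanges(spec@chrom[i], IRanges(starts + 1, ends),
                clipped = (ends - starts) < window, seqinfo = si)
    })
    do.call(c, grl)
}

#' Pool heterozygosity of a window
#'
#' \deqn{Hp = 2 \Sigma n_{MAJ} \Sigma n_{MIN} / (\Sigma n_{MAJ} + \Sigma n_{MIN})^2}
#' with sums of per-site major and minor allele counts over the SNPs of the
#' window.  Bounded by [0, 0.5], attaining 0.5 iff the summed counts are
#' equal.
#'
#' @param major,minor per-site major and minor allele counts (major >= minor
#'   at every site).
#' @return Hp, or NA for an empty window.
#' @examples
#' poolHeterozygosity(8, 2)            # 0.32
#' poolHeterozygosity(c(9, 7), c(1, 3))  # 0.32
#' @export
poolHeterozygosity <- function(major, minor) {
    if (length(major) != length(minor)) stop("count vectors differ in length")
    if (length(major) == 0L) return(NA_real_)
    if (any(minor > major)) stop("minor count exceeds major count; orient counts first")
    if (any(major < 0) || any(minor < 0)) stop("negative allele count")
    sM <- sum(as.numeric(major))
    sm <- sum(as.numeric(minor))
    if (sM + sm == 0) return(NA_real_)
    2 * sM * sm / (sM + sm)^2
}

#' Per-site nucleotide diversity of a window
#'
#' Unbiased per-site estimator summed over sites and divided by the window
#' length: \deqn{\pi = \sum_i 2 c_i (n_i - c_i) / (n_i (n_i - 1)) / L.}
#' Also returns kbar = pi * L, the mean pairwise difference count, used by
#' Tajima's D.
#'
#' @param minor per-site (minor or derived) allele counts.
#' @param total per-site total allele counts (all >= 2).
#' @param L window length in bp.
#' @return list with elements \code{pi} and \code{kbar}.
#' @export
nucleotideDiversity <- function(minor, total, L) {
    if (L <= 0) stop("window length must be positive")
    if (length(minor) == 0L) return(list(pi = 0, kbar = 0))
    if (any(total < 2)) stop("site with fewer than 2 allele calls")
    if (any(minor < 0) || any(minor > total)) stop("invalid allele count")
    kbar <- sum(2 * minor * (total - minor) / (total * (total - 1)))
    list(pi = kbar / L, kbar = kbar)
}

#' Tajima's D
#'
#' Standard normalized difference between the pairwise and Watterson
#' estimators of theta, using the 1989 constants.  Vectorized over S and
#' kbar; n is the (constant) number of haplotypes.
#'
#' @param S segregating site counts.
#' @param kbar mean pairwise differences per window.
#' @param n haplotypes (>= 4).
#' @return D, NA where S = 0 or the variance term vanishes.
#' @export
tajimasD <- function(S, kbar, n) {
    if (n < 4) stop("sample too small for D")
    i <- seq_len(n - 1)
    a1 <- sum(1 / i)
    a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    varS <- e1 * S + e2 * S * (S - 1)
    D <- ifelse(S > 0 & varS > 0, (kbar - S / a1) / sqrt(varS), NA_real_)
    D
}

#' Windowed diversity statistics from a VariantTable
#'
#' Assigns every SNP record to every window containing it and computes, per
#' window: \code{nSNP} (all admitted records), \code{Hp} from pooled major
#' and minor allele counts over all records (missing genotypes shrink the
#' per-site pool; reference-fixed records contribute major mass only),
#' and \code{S}, \code{kbar}, \code{pi}, \code{D} from complete
#' (zero-missing) sites so that the haplotype count \code{n} is constant.
#'
#' @param vt a \linkS4class{VariantTable}.
#' @param windows windows from \code{\link{makeWindows}}.
#' @return The \code{windows} GRanges with metadata columns \code{nSNP},
#'   \code{n}, \code{Hp}, \code{S}, \code{kbar}, \code{pi}, \code{D}.
#' @export
windowedStats <- function(vt, windows) {
    stopifnot(is(vt, "VariantTable"))
    n <- nHaplotypes(vt)
    s <- siteTable(vt)
    nw <- length(windows)
    nSNP <- integer(nw)
    sumMaj <- numeric(nw)
    sumMin <- numeric(nw)
    S <- integer(nw)
    kbar <- numeric(nw)
    if (nrow(s)) {
        g <- s$refCount + s$altCount           # genotyped alleles per site
        maj <- pmax(s$refCount, s$altCount)
        mnr <- pmin(s$refCount, s$altCount)
        complete <- s$missingCount == 0L
        seg <- complete & s$altCount > 0L & s$altCount < n
        piC <- ifelse(complete & g >= 2, 2 * mnr * (g - mnr) / (g * pmax(g - 1, 1)), 0)
        sgr <- GRanges(s$chrom, IRanges(s$pos, s$pos))
        hits <- findOverlaps(sgr, windows)
        q <- queryHits(hits)
        w <- subjectHits(hits)
        add <- function(vals) {
            out <- numeric(nw)
            tt <- rowsum(vals[q], w)
            out[as.integer(rownames(tt))] <- tt[, 1]
            out
        }
        nSNP <- as.integer(add(rep(1, nrow(s))))
        sumMaj <- add(as.numeric(maj))
        sumMin <- add(as.numeric(mnr))
        S <- as.integer(add(as.numeric(seg)))
        kbar <- add(piC)
    }
    L <- width(windows)
    tot <- sumMaj + sumMin
    Hp <- ifelse(nSNP > 0 & tot > 0, 2 * sumMaj * sumMin / tot^2, NA_real_)
    pi <- kbar / L
    D <- if (n >= 4) tajimasD(S, kbar, n) else rep(NA_real_, nw)
    mcols(windows)$nSNP <- nSNP
    mcols(windows)$n <- n
    mcols(windows)$Hp <- Hp
    mcols(windows)$S <- S
    mcols(windows)$kbar <- kbar
    mcols(windows)$pi <- pi
    mcols(windows)$D <- D
    windows
}

#' Exclude windows with too few SNPs
#'
#' Marks windows with fewer than \code{minSnps} records as not retained (the
#' scan neither normalizes nor flags them, and they break adjacency when
#' candidate windows are merged into regions).
#'
#' @param ws windowed statistics GRanges.
#' @param minSnps minimum SNP records per window (default 50; windows with
#'   strictly fewer are excluded).
#' @return \code{ws} with a logical \code{retained} column; the number of
#'   excluded windows is in \code{attr(, "excluded")}.
#' @export
filterMinSnps <- function(ws, minSnps = 50) {
    retained <- mcols(ws)$nSNP >= minSnps
    mcols(ws)$retained <- retained
    if (!any(retained))
        warning("all windows fall below the SNP-count filter")
    attr(ws, "excluded") <- sum(!retained)
    ws
}

#' Z-normalize windowed statistics within a population
#'
#' Z = (x - mean) / sd over the retained windows with non-missing values,
#' using the population standard deviation (denominator N).  Missing values
#' stay missing; non-retained windows get NA.
#'
#' @param ws windowed statistics GRanges (after \code{\link{filterMinSnps}}).
#' @param stats which statistics to normalize.
#' @return \code{ws} with added \code{ZHp}, \code{Zpi}, \code{ZD} columns and
#'   a \code{zbase} attribute holding the means and sds used.
#' @export
normalizeStats <- function(ws, stats = c("Hp", "pi", "D")) {
    if (is.null(mcols(ws)$retained))
        ws <- filterMinSnps(ws, 0)
    zbase <- list()
    for (st in stats) {
        x <- mcols(ws)[[st]]
        use <- mcols(ws)$retained & !is.na(x)
        if (sum(use) < 2) stop("need >= 2 retained windows to normalize ", st)
        mu <- mean(x[use])
        sdev <- sqrt(mean((x[use] - mu)^2))
        if (sdev == 0) stop("degenerate distribution for ", st)
        z <- rep(NA_real_, length(ws))
        z[use] <- (x[use] - mu) / sdev
        mcols(ws)[[paste0("Z", sub("pi", "pi", st))]] <- z
        zbase[[st]] <- c(mean = mu, sd = sdev)
    }
    attr(ws, "zbase") <- zbase
    ws
}
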