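# Neutral null distributions: parse ms-dialect demographic commands, simulate
# window statistics under the coalescent, and derive one-tailed empirical
# significance thresholds (the extreme value of the simulated distribution in
# the direction a sweep pushes each statistic).

#' Parse an ms-dialect demographic command
#'
#' Accepts \code{-t <theta>} followed by zero or more \code{-eN <t> <x>}
#' events.  Events may be given in any order (ms sorts them internally for
#' simulation); the original order is preserved so that
#' \code{\link{msCommand}} reproduces the input token for token.
#'
#' @param text command string, e.g.
#'   \code{"-t 2449 -eN 0.13237575 0.039843163 -eN 0.08026151 0.152704587"}.
#' @param sampleSize haplotypes to simulate with this model.
#' @param refLength locus length in bp that theta refers to (default 3e5).
#' @return A \linkS4class{DemographicModel}.
#' @export
parseMsCommand <- function(text, sampleSize = 20L, refLength = 3e5) {
    tok <- strsplit(trimws(text), "\\s+")[[1]]
    if (length(tok) < 2L || tok[1] != "-t")
        stop("command must start with -t <theta>")
    theta <- suppressWarnings(as.numeric(tok[2]))
    if (is.na(theta)) stop("invalid theta: ", tok[2])
    times <- numeric(0)
    sizes <- numeric(0)
    i <- 3L
    while (i <= length(tok)) {
        if (tok[i] != "-eN")
            stop("unknown flag: ", tok[i])
        if (i + 2L > length(tok)) stop("-eN needs two arguments")
        tt <- suppressWarnings(as.numeric(tok[i + 1L]))
        xx <- suppressWarnings(as.numeric(tok[i + 2L]))
        if (is.na(tt) || is.na(xx)) stop("invalid -eN arguments")
        times <- c(times, tt)
        sizes <- c(sizes, xx)
        i <- i + 3L
    }
    m <- demographicModel(theta, times, sizes, sampleSize, refLength)
    attr(m, "tokens") <- c(tok[2], vapply(seq_along(times), function(j)
        c(tok[3 * j + 1L], tok[3 * j + 2L]), character(2)))
    m
}

#' Serialize a DemographicModel to its ms command string
#'
#' Reproduces the parsed command token for token (numeric tokens are kept as
#' given when the model came from \code{\link{parseMsCommand}}).
#'
#' @param model a \linkS4class{DemographicModel}.
#' @return The command string.
#' @export
msCommand <- function(model) {
    tok <- attr(model, "tokens")
    if (is.null(tok)) {
        fm <- function(x) format(x, scientific = FALSE, trim = TRUE)
        tok <- c(fm(model@theta), as.vector(rbind(fm(model@eventTimes),
                                                  fm(model@eventSizes))))
    }
    parts <- c("-t", tok[1])
    ne <- length(model@eventTimes)
    if (ne > 0)
        for (j in seq_len(ne))
            parts <- c(parts, "-eN", tok[2 * j], tok[2 * j + 1])
    paste(parts, collapse = " ")
}

#' Simulate one neutral window
#'
#' Hudson coalescent for a single population under the model's
#' piecewise-constant size history (no recombination, matching the ms
#' commands, which carry no -r flag).  Theta is rescaled linearly from the
#' model's reference locus length to the simulated window length.  Uses the
#' R RNG; call \code{set.seed} for reproducibility.
#'
#' @param model a \linkS4class{DemographicModel}.
#' @param windowLength simulated locus length in bp.
#' @param haplotypes if TRUE also return the 0/1 haplotype matrix
#'   (haplotypes x sites).
#' @param n haplotypes to simulate; default \code{model@sampleSize}.
#' @return list with \code{counts} (derived-allele counts, one per
#'   segregating site, each in 1..n-1), \code{n}, and optionally
#'   \code{haplotypes}.
#' @export
simulateWindow <- function(model, windowLength = 20000, haplotypes = FALSE,
                           n = NULL) {
    stopifnot(is(model, "DemographicModel"))
    if (windowLength <= 0) stop("window length must be positive")
    if (is.null(n)) n <- model@sampleSize
    o <- order(model@eventTimes)
    thetaW <- model@theta * windowLength / model@refLength
    res <- .simWindowCpp(as.integer(n), thetaW,
                         model@eventTimes[o], model@eventSizes[o],
                         isTRUE(haplotypes))
    out <- list(counts = res$counts, n = as.integer(n))
    if (haplotypes) out$haplotypes <- res$haplotypes
    out
}

# statistics of one simulated window, matching windowedStats() on observed
# data: Hp from pooled major/minor counts (with fixedSites zero-minor records
# added to reproduce the reference-fixed ascertainment of real VCFs), pi and
# D from the segregating sites.
.simStats <- function(counts, n, L, fixedSites = 0) {
    minor <- pmin(counts, n - counts)
    major <- pmax(counts, n - counts)
    sM <- sum(as.numeric(major)) + as.numeric(fixedSites) * n
    sm <- sum(as.numeric(minor))
    Hp <- if (sM + sm > 0) 2 * sM * sm / (sM + sm)^2 else NA_real_
    kbar <- sum(2 * counts * (n - counts) / (n * (n - 1)))
    S <- length(counts)
    D <- if (n >= 4 && S > 0) tajimasD(S, kbar, n) else NA_real_
    c(Hp = Hp, pi = kbar / L, D = D)
}

#' Build the neutral null distribution for a population
#'
#' Runs independent coalescent window simulations and computes Hp, pi and
#' Tajima's D on each with the same estimators used for observed windows.
#' Per-simulation RNG streams are derived from the master seed by counter, so
#' results do not depend on execution order.
#'
#' @param model a \linkS4class{DemographicModel}.
#' @param windowLength window size in bp (default 20000).
#' @param nSims number of simulations (default 10000).
#' @param seed master seed (integer).
#' @param fixedPerWindow mean number of reference-fixed (zero-minor) SNP
#'   records per window to add to each simulated window, matching the
#'   ascertainment of the observed VCF (see
#'   \code{\link{estimateFixedSiteRate}}); drawn Poisson per simulation.
#' @param population population id to record.
#' @return A \linkS4class{NullDistribution}.
#' @export
buildNull <- function(model, windowLength = 20000, nSims = 10000, seed = 1L,
                      fixedPerWindow = 0, population = "pop") {
    stopifnot(is(model, "DemographicModel"))
    seed <- as.integer(seed)
    out <- matrix(NA_real_, nrow = nSims, ncol = 3,
                  dimnames = list(NULL, c("Hp", "pi", "D")))
    for (i in seq_len(nSims)) {
        set.seed(as.integer((as.numeric(seed) + 1000003 * (i - 1)) %% 2147483629))
        sim <- simulateWindow(model, windowLength)
        fx <- if (fixedPerWindow > 0) rpois(1L, fixedPerWindow) else 0L
        out[i, ] <- .simStats(sim$counts, sim$n, windowLength, fx)
    }
    new("NullDistribution", population = population,
        stats = as.data.frame(out), nSims = as.integer(nSims), seed = seed,
        windowSize = windowLength, fixedPerWindow = as.numeric(fixedPerWindow))
}

#' Estimate the reference-fixed SNP record rate per window
#'
#' Population VCFs called against a diverged reference contain records that
#' are fixed for the alternate allele within the population (zero minor
#' count).  These contribute to the per-window SNP tally and to the
#' major-allele mass of Hp, so the simulated null must carry them at the same
#' density.  Returns the mean count of complete zero-minor records per window
#' length.
#'
#' @param vt a \linkS4class{VariantTable}.
#' @param windowLength window size in bp.
#' @return Mean fixed records per window (numeric).
#' @export
estimateFixedSiteRate <- function(vt, windowLength = 20000) {
    s <- siteTable(vt)
    n <- nHaplotypes(vt)
    fixed <- s$missingCount == 0L & (s$altCount == 0L | s$altCount == n)
    span <- sum(vapply(split(s$pos, s$chrom), function(p) diff(range(p)) + 1,
                       numeric(1)))
    if (span <= 0) return(0)
    sum(fixed) / span * windowLength
}

#' Derive one-tailed significance thresholds from a null distribution
#'
#' The threshold for each statistic is the minimum simulated value (the
#' extreme value in the one-tailed direction of a sweep, which lowers Hp, pi
#' and D).  Observed windows are significant when strictly below the
#' threshold.  The Z-scale image of each threshold under the observed
#' population's mean/sd is attached for plotting.
#'
#' @param null a \linkS4class{NullDistribution}.
#' @param ws observed windowed statistics (normalized via
#'   \code{\link{normalizeStats}}); optional — without it the Z images are NA.
#' @return A \linkS4class{ThresholdSet}.
#' @export
deriveThresholds <- function(null, ws = NULL) {
    st <- null@stats
    if (nrow(st) == 0) stop("empty null distribution")
    if (all(is.na(st$D))) stop("all simulated D values are missing")
    raw <- c(Hp = min(st$Hp, na.rm = TRUE),
             pi = min(st$pi, na.rm = TRUE),
             D = min(st$D, na.rm = TRUE))
    z <- c(Hp = NA_real_, pi = NA_real_, D = NA_real_)
    if (!is.null(ws)) {
        zbase <- attr(ws, "zbase")
        if (is.null(zbase))
            stop("ws must come from normalizeStats()")
        for (stn in names(raw)) {
            b <- zbase[[stn]]
            if (!is.null(b)) z[stn] <- (raw[stn] - b["mean"]) / b["sd"]
        }
    }
    new("ThresholdSet", population = null@population, raw = raw, z = z,
        nSims = null@nSims)
}
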