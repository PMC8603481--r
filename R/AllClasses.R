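#' GenomeSpec: ordered chromosome names and lengths
#'
#' A minimal description of the genome the scan runs on: an ordered set of
#' chromosome names with their lengths in base pairs.  All windows, intervals
#' and regions downstream are validated against it.
#'
#' @slot chrom character vector of unique chromosome names, in genome order.
#' @slot length numeric vector of chromosome lengths (bp), same order.
#' @export
setClass("GenomeSpec",
    representation(chrom = "character", length = "numeric"))

setValidity("GenomeSpec", function(object) {
    msg <- character(0)
    if (length(object@chrom) != length(object@length))
        msg <- c(msg, "chrom and length differ in length")
    if (anyDuplicated(object@chrom))
        msg <- c(msg, "chromosome names must be unique")
    if (any(!is.finite(object@length)) || any(object@length <= 0))
        msg <- c(msg, "chromosome lengths must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a GenomeSpec
#'
#' @param chrom character vector of chromosome names.
#' @param length numeric vector of chromosome lengths in bp.
#' @return A \linkS4class{GenomeSpec}.
#' @examples
#' gs <- genomeSpec(c("chr1", "chr2"), c(2e6, 1e6))
#' genomeLength(gs)
#' @export
genomeSpec <- function(chrom, length) {
    new("GenomeSpec", chrom = as.character(chrom), length = as.numeric(length))
}

#' @describeIn genomeSpec chromosome lengths as a named vector.
#' @param x a GenomeSpec.
#' @export
chromLengths <- function(x) {
    stopifnot(is(x, "GenomeSpec"))
    setNames(x@length, x@chrom)
}

#' @describeIn genomeSpec total genome length in bp.
#' @export
genomeLength <- function(x) sum(chromLengths(x))

#' @describeIn genomeSpec convert to a GenomeInfoDb Seqinfo.
#' @export
asSeqinfo <- function(x) {
    stopifnot(is(x, "GenomeSpec"))
    Seqinfo(seqnames = x@chrom, seqlengths = as.integer(x@length))
}

setMethod("show", "GenomeSpec", function(object) {
    cat("GenomeSpec with", length(object@chrom), "chromosomes,",
        format(sum(object@length), big.mark = ","), "bp total\n")
})

#' VariantTable: per-site allele counts for one population
#'
#' Holds, for one population, the biallelic autosomal SNP records admitted
#' from a VCF: per site the chromosome, 1-based position, and the tallies of
#' reference alleles, alternate alleles and missing haplotype calls over the
#' population's samples.  At every site
#' \code{refCount + altCount + missingCount == 2 * nDiploid}.
#'
#' @slot population population identifier.
#' @slot nDiploid number of diploid samples tallied.
#' @slot sites data.frame with columns \code{chrom}, \code{pos},
#'   \code{refCount}, \code{altCount}, \code{missingCount}, sorted by
#'   (chrom, pos).
#' @export
setClass("VariantTable",
    representation(population = "character", nDiploid = "integer",
                   sites = "data.frame"))

setValidity("VariantTable", function(object) {
    msg <- character(0)
    s <- object@sites
    need <- c("chrom", "pos", "refCount", "altCount", "missingCount")
    if (!all(need %in% names(s)))
        return(paste("sites must have columns", paste(need, collapse = ", ")))
    if (length(object@nDiploid) != 1L || object@nDiploid < 1L)
        msg <- c(msg, "nDiploid must be a single positive integer")
    if (nrow(s)) {
        tot <- s$refCount + s$altCount + s$missingCount
        if (any(tot != 2L * object@nDiploid))
            msg <- c(msg, "ref + alt + missing must equal 2 * nDiploid at every site")
        if (any(s$refCount < 0L) || any(s$altCount < 0L) || any(s$missingCount < 0L))
            msg <- c(msg, "allele counts must be nonnegative")
        o <- order(s$chrom, s$pos)
        if (!identical(o, seq_len(nrow(s))))
            msg <- c(msg, "sites must be sorted by (chrom, pos)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a VariantTable
#'
#' @param population population id.
#' @param nDiploid diploid sample count.
#' @param sites data.frame of per-site counts (see class docs).
#' @return A \linkS4class{VariantTable}.
#' @export
variantTable <- function(population, nDiploid, sites) {
    sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
    rownames(sites) <- NULL
    new("VariantTable", population = as.character(population),
        nDiploid = as.integer(nDiploid), sites = sites)
}

#' @describeIn variantTable the population id.
#' @param x a VariantTable.
#' @export
population <- function(x) x@population

#' @describeIn variantTable number of SNP records.
#' @export
nSites <- function(x) nrow(x@sites)

#' @describeIn variantTable the per-site count table.
#' @export
siteTable <- function(x) x@sites

#' @describeIn variantTable number of haplotypes (2 x diploid samples).
#' @export
nHaplotypes <- function(x) 2L * x@nDiploid

setMethod("show", "VariantTable", function(object) {
    cat("VariantTable for population", sQuote(object@population), "\n ",
        nrow(object@sites), "biallelic SNP records over",
        object@nDiploid, "diploid samples\n")
})

#' DemographicModel: ms-dialect piecewise-constant size history
#'
#' A single-population neutral demographic model in the ms dialect: a
#' population-scaled mutation rate theta (4 N0 mu over the reference locus
#' length it was estimated on) and an ordered set of \code{-eN t x} events
#' setting the population size to \code{x * N0} at time \code{t} (units of
#' 4 N0 generations, looking backward).  Events are stored in the order given
#' on the command line (ms accepts any order) and sorted by time for
#' simulation.
#'
#' @slot theta population-scaled mutation rate for the reference locus.
#' @slot refLength reference locus length in bp that theta refers to.
#' @slot eventTimes event times, command-line order.
#' @slot eventSizes size ratios (x N0), command-line order.
#' @slot sampleSize default number of haplotypes to simulate.
#' @export
setClass("DemographicModel",
    representation(theta = "numeric", refLength = "numeric",
                   eventTimes = "numeric", eventSizes = "numeric",
                   sampleSize = "integer"))

setValidity("DemographicModel", function(object) {
    msg <- character(0)
    if (length(object@theta) != 1L || !is.finite(object@theta) || object@theta < 0)
        msg <- c(msg, "theta must be a single nonnegative number")
    if (object@refLength <= 0) msg <- c(msg, "refLength must be positive")
    if (length(object@eventTimes) != length(object@eventSizes))
        msg <- c(msg, "event times and sizes differ in length")
    if (any(object@eventTimes <= 0)) msg <- c(msg, "event times must be positive")
    if (any(object@eventSizes <= 0)) msg <- c(msg, "event size ratios must be positive")
    if (anyDuplicated(object@eventTimes))
        msg <- c(msg, "duplicate event times")
    if (object@sampleSize < 2L) msg <- c(msg, "sampleSize must be >= 2")
    if (length(msg)) msg else TRUE
})

#' Construct a DemographicModel
#'
#' @param theta population-scaled mutation rate (ms \code{-t}) for the
#'   reference locus length.
#' @param eventTimes,eventSizes \code{-eN} event times (4 N0 generations) and
#'   size ratios, in command-line order.
#' @param sampleSize haplotypes to simulate (2 x diploid sample count).
#' @param refLength reference locus length in bp that \code{theta} was
#'   estimated on (default 3e5).
#' @return A \linkS4class{DemographicModel}.
#' @examples
#' m <- demographicModel(theta = 10, sampleSize = 10)
#' @export
demographicModel <- function(theta, eventTimes = numeric(0),
                             eventSizes = numeric(0), sampleSize = 20L,
                             refLength = 3e5) {
    new("DemographicModel", theta = theta, refLength = refLength,
        eventTimes = as.numeric(eventTimes), eventSizes = as.numeric(eventSizes),
        sampleSize = as.integer(sampleSize))
}

setMethod("show", "DemographicModel", function(object) {
    cat("DemographicModel:", msCommand(object), "\n ",
        "sample size", object@sampleSize, "haplotypes; theta per",
        format(object@refLength, big.mark = ","), "bp\n")
})

#' NullDistribution: simulated neutral window statistics
#'
#' Per-statistic values of Hp, pi (per site) and Tajima's D over independent
#' neutral coalescent window simulations under one demographic model, used to
#' derive empirical significance thresholds.
#'
#' @slot population population id the model belongs to.
#' @slot stats data.frame with one row per simulation and columns
#'   \code{Hp}, \code{pi}, \code{D} (D may be NA when S = 0).
#' @slot nSims number of simulations.
#' @slot seed master seed used.
#' @slot windowSize simulated window length (bp).
#' @slot fixedPerWindow reference-fixed (zero-minor) sites added per window to
#'   match the ascertainment of the observed data.
#' @export
setClass("NullDistribution",
    representation(population = "character", stats = "data.frame",
                   nSims = "integer", seed = "integer",
                   windowSize = "numeric", fixedPerWindow = "numeric"))

setValidity("NullDistribution", function(object) {
    if (nrow(object@stats) != object@nSims)
        return("stats must have one row per simulation")
    if (!all(c("Hp", "pi", "D") %in% names(object@stats)))
        return("stats must have columns Hp, pi, D")
    TRUE
})

setMethod("show", "NullDistribution", function(object) {
    cat("NullDistribution for", sQuote(object@population), "-",
        object@nSims, "simulations of", object@windowSize, "bp windows\n")
})

#' Simulated statistic values of a NullDistribution
#'
#' @param x a NullDistribution.
#' @return data.frame with columns \code{Hp}, \code{pi}, \code{D}.
#' @export
nullStats <- function(x) x@stats

#' ThresholdSet: one-tailed empirical significance thresholds
#'
#' Raw-scale low-tail thresholds for Hp, pi and Tajima's D (the minimum of the
#' simulated neutral values, the one-tailed extreme in the direction a sweep
#' pushes each statistic), plus their images on the Z scale of the observed
#' population for plotting.
#'
#' @slot population population id.
#' @slot raw named numeric: raw-scale thresholds for Hp, pi, D.
#' @slot z named numeric: the same thresholds on the observed Z scale.
#' @slot nSims simulations behind the thresholds.
#' @export
setClass("ThresholdSet",
    representation(population = "character", raw = "numeric", z = "numeric",
                   nSims = "integer"))

setMethod("show", "ThresholdSet", function(object) {
    cat("ThresholdSet for", sQuote(object@population), "(",
        object@nSims, "simulations )\n")
    print(rbind(raw = object@raw, z = object@z))
})

#' Threshold accessors
#'
#' Raw-scale and Z-scale significance thresholds of a
#' \linkS4class{ThresholdSet}.
#'
#' @rdname thresholdAccessors
#' @param x a ThresholdSet.
#' @return \code{rawThresholds}: named numeric of raw-scale thresholds.
#' @export
rawThresholds <- function(x) x@raw

#' @rdname thresholdAccessors
#' @return \code{zThresholds}: named numeric of Z-scale threshold images.
#' @export
zThresholds <- function(x) x@z
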