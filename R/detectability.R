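#' CallerThresholds constructor
#'
#' @param minVaf minimum observed allele fraction (default 0.15, a common
#'   confidence cutoff for ~100x exomes).
#' @param minAltReads minimum alternate-supporting reads.
#' @param minDepth minimum site depth.
#' @return a \linkS4class{CallerThresholds}.
#' @export
CallerThresholds <- function(minVaf = 0.15, minAltReads = 4, minDepth = 10) {
    new("CallerThresholds", minVaf = as.numeric(minVaf),
        minAltReads = as.numeric(minAltReads), minDepth = as.numeric(minDepth))
}

setMethod("show", "CallerThresholds", function(object) {
    cat("CallerThresholds: vaf >= ", object@minVaf, ", alt reads >= ",
        object@minAltReads, ", depth >= ", object@minDepth, "\n", sep = "")
})

#' Expected somatic VAF under tumor purity
#'
#' In a copy-neutral diploid tumor mixed with normal tissue at purity
#' \eqn{\rho}, a heterozygous somatic mutation is carried by one of two
#' chromosomes in the tumor fraction, giving an expected allele fraction of
#' \eqn{\rho/2}; a homozygous mutation gives \eqn{\rho}. For a 30% tumor
#' mixture these are 15% and 30% — which is why such mixtures probe the
#' sensitivity floor of ~100x exome assays. The copy-neutral assumption is
#' part of the model; no copy-number adjustment is made.
#'
#' @param purity tumor purity in (0, 1].
#' @param zygosity "heterozygous" or "homozygous".
#' @return expected variant allele fraction (linear in purity).
#' @export
#' @examples
#' expectedVaf(0.30, "heterozygous")  # 0.15
#' expectedVaf(0.30, "homozygous")    # 0.30
expectedVaf <- function(purity, zygosity = c("heterozygous", "homozygous")) {
    zygosity <- match.arg(zygosity)
    if (any(purity <= 0) || any(purity > 1))
        stop("purity must be in (0, 1]", call. = FALSE)
    if (zygosity == "heterozygous") purity / 2 else purity
}

#' Probability that a mutation is called at given depth and thresholds
#'
#' With \eqn{K \sim \mathrm{Binomial}(d, v)} alternate reads at depth
#' \eqn{d} and true allele fraction \eqn{v}, the mutation is called when the
#' site passes the depth floor, \eqn{K} reaches the alternate-read minimum,
#' and the realized fraction \eqn{K/d} reaches the VAF cutoff (thresholds
#' apply to the observed fraction, as callers do). Both read-count conditions
#' reduce to \eqn{K \ge k_0} with
#' \eqn{k_0 = \max(\mathrm{minAlt}, \lceil \mathrm{minVaf} \cdot d \rceil)},
#' so the probability is an exact binomial tail, computed via
#' \code{pbinom}. It is non-decreasing in \code{vaf}, and with
#' \code{minVaf = 0}, \code{minAltReads = 1} equals
#' \eqn{1 - (1 - v)^d}.
#'
#' @param vaf true allele fraction in [0, 1] (vectorized).
#' @param depth site read depth (vectorized).
#' @param thresholds a \linkS4class{CallerThresholds}.
#' @return detection probability in [0, 1].
#' @export
#' @examples
#' detectionProbability(0.15, 100, CallerThresholds(0.05, 4, 10))
detectionProbability <- function(vaf, depth, thresholds = CallerThresholds()) {
    stopifnot(is(thresholds, "CallerThresholds"))
    if (any(vaf < 0 | vaf > 1)) stop("vaf must be in [0, 1]", call. = FALSE)
    if (any(depth < 0)) stop("depth must be >= 0", call. = FALSE)
    n <- max(length(vaf), length(depth))
    vaf <- rep_len(vaf, n); depth <- rep_len(depth, n)
    ## smallest K satisfying K/d >= minVaf, guarded against 0.05*100 != 5
    k0 <- pmax(thresholds@minAltReads,
               ceiling(thresholds@minVaf * depth - .EPS))
    p <- ifelse(depth < thresholds@minDepth, 0,
         ifelse(k0 <= 0, 1,
                pbinom(k0 - 1, size = depth, prob = vaf,
                       lower.tail = FALSE)))
    as.numeric(p)
}

#' Detection probability marginalized over a depth distribution
#'
#' Site depth in an exome is not fixed; averaging the exact binomial-tail
#' detection probability over a negative-binomial depth distribution gives
#' the per-mutation detection probability the simulator realizes.
#'
#' @param vaf true allele fraction.
#' @param meanDepth,dispersion negative-binomial mean and size.
#' @param thresholds a \linkS4class{CallerThresholds}.
#' @param qmax upper tail quantile at which the depth sum is truncated.
#' @return marginal detection probability.
#' @export
detectionProbabilityMarginal <- function(vaf, meanDepth, dispersion,
                                         thresholds = CallerThresholds(),
                                         qmax = 1 - 1e-10) {
    dmax <- stats::qnbinom(qmax, size = dispersion, mu = meanDepth)
    d <- 0:dmax
    w <- dnbinom(d, size = dispersion, mu = meanDepth)
    sum(w * detectionProbability(rep(vaf, length(d)), d, thresholds))
}

#' Minimum tumor purity at which the expected VAF reaches a cutoff
#'
#' Inverts \code{\link{expectedVaf}}: the smallest purity whose expected
#' allele fraction meets the caller's VAF cutoff. With a 15% cutoff a
#' heterozygous mutation needs 30% tumor content, a homozygous one 15%.
#' For a heterozygous mutation and a cutoff above 0.5 no purity suffices and
#' \code{NA} is returned with a warning.
#'
#' @param minVaf VAF detection cutoff in (0, 1).
#' @param zygosity "heterozygous" or "homozygous".
#' @return minimum purity in (0, 1], or \code{NA}.
#' @export
#' @examples
#' minPurityForDetection(0.15, "heterozygous")  # 0.30
minPurityForDetection <- function(minVaf,
                                  zygosity = c("heterozygous", "homozygous")) {
    zygosity <- match.arg(zygosity)
    if (any(minVaf <= 0) || any(minVaf >= 1))
        stop("minVaf must be in (0, 1)", call. = FALSE)
    p <- if (zygosity == "heterozygous") 2 * minVaf else minVaf
    if (any(p > 1)) {
        warning("no purity reaches a ", minVaf,
                " expected VAF for a heterozygous mutation", call. = FALSE)
        p[p > 1] <- NA_real_
    }
    p
}

#' Detectability table over purity and depth grids
#'
#' Tabulates the detection probability of heterozygous and homozygous somatic
#' mutations over a purity x depth grid at fixed caller thresholds — the
#' planning view of how much tumor content an assay needs.
#'
#' @param purities vector of tumor purities.
#' @param depths vector of sequencing depths.
#' @param thresholds a \linkS4class{CallerThresholds}.
#' @return data.frame with columns purity, depth, zygosity, expectedVaf,
#'   detectionProbability.
#' @export
detectabilityTable <- function(purities = c(0.1, 0.2, 0.3, 0.5, 1),
                               depths = c(50, 100, 200),
                               thresholds = CallerThresholds()) {
    grid <- expand.grid(purity = purities, depth = depths,
                        zygosity = c("heterozygous", "homozygous"),
                        stringsAsFactors = FALSE)
    grid$expectedVaf <- mapply(function(p, z) expectedVaf(p, z),
                               grid$purity, grid$zygosity)
    grid$detectionProbability <- detectionProbability(
        grid$expectedVaf, grid$depth, thresholds)
    grid
}
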