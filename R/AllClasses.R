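#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges granges reduce findOverlaps seqnames
#'   start end width mcols mcols<- sort
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqnames seqlevels
#' @importFrom S4Vectors DataFrame queryHits subjectHits
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' RegionSet: a named set of disjoint genomic intervals
#'
#' Represents a capture-kit target or gene-panel region set. Intervals are
#' stored as a strand-free, sorted, reduced \code{GRanges} (1-based inclusive
#' internally; BED input/output converts to and from 0-based half-open
#' coordinates via \pkg{rtracklayer}). Overlapping or bookended input
#' intervals are merged at construction, so total size is well defined.
#'
#' @slot name single label for the region set.
#' @slot regions sorted, reduced \code{GRanges}.
#' @export
setClass("RegionSet",
    representation(name = "character", regions = "GRanges"))

setValidity("RegionSet", function(object) {
    msg <- NULL
    if (length(object@name) != 1L)
        msg <- c(msg, "'name' must be a single string")
    gr <- object@regions
    if (length(gr)) {
        red <- reduce(sort(GenomicRanges::granges(gr)), ignore.strand = TRUE)
        if (length(red) != length(gr) || !all(start(red) == start(sort(gr))) ||
            !all(end(red) == end(sort(gr))))
            msg <- c(msg, "'regions' must be sorted, disjoint and merged")
    }
    if (is.null(msg)) TRUE else msg
})

#' MutationSet: de-duplicated somatic mutation keys from one report
#'
#' The central container: a set of canonical mutation keys (contig, 1-based
#' position, reference allele, single alternate allele) from one laboratory /
#' sample / replicate, with optional per-key variant allele fraction, read
#' depth and filter status. A unique mutation is identified by coordinate plus
#' base change, nothing else; key equality is exact.
#'
#' The backing \code{GRanges} anchors each key at its (post-normalization)
#' position with width 1, and carries \code{ref}, \code{alt}, \code{vaf},
#' \code{depth} and \code{filter} metadata columns.
#'
#' @slot lab laboratory label.
#' @slot sample sample label.
#' @slot replicate replicate label.
#' @slot calls width-1 \code{GRanges} with allele metadata columns.
#' @export
setClass("MutationSet",
    representation(lab = "character", sample = "character",
                   replicate = "character", calls = "GRanges"))

setValidity("MutationSet", function(object) {
    msg <- NULL
    for (s in c("lab", "sample", "replicate"))
        if (length(slot(object, s)) != 1L)
            msg <- c(msg, sprintf("'%s' must be a single string", s))
    gr <- object@calls
    need <- c("ref", "alt")
    if (!all(need %in% names(mcols(gr))))
        msg <- c(msg, "calls must carry 'ref' and 'alt' metadata columns")
    else if (length(gr)) {
        if (any(width(gr) != 1L))
            msg <- c(msg, "calls must be width-1 anchors")
        if (any(start(gr) < 1L))
            msg <- c(msg, "positions must be >= 1")
        ref <- mcols(gr)$ref; alt <- mcols(gr)$alt
        if (!all(.validAllele(ref)) || !all(.validAllele(alt)))
            msg <- c(msg, "alleles must match [ACGTN]+ (uppercase)")
        if (any(ref == alt))
            msg <- c(msg, "ref and alt must differ for every key")
        if (anyDuplicated(.keyStrings(object)))
            msg <- c(msg, "duplicate mutation keys (set semantics violated)")
    }
    if (is.null(msg)) TRUE else msg
})

#' TruthSet: expected mutations with zygosity
#'
#' A \linkS4class{MutationSet} whose keys additionally carry zygosity
#' (\code{"heterozygous"} or \code{"homozygous"}), serving as ground truth for
#' sensitivity estimation — the role the 178 documented COSMIC mutations play
#' for a 30/70 tumor/normal cell-line mixture.
#'
#' @export
setClass("TruthSet", contains = "MutationSet")

setValidity("TruthSet", function(object) {
    zyg <- mcols(object@calls)$zygosity
    if (is.null(zyg))
        return("truth calls must carry a 'zygosity' metadata column")
    if (!all(zyg %in% c("heterozygous", "homozygous")))
        return("zygosity must be 'heterozygous' or 'homozygous'")
    TRUE
})

#' CallerThresholds: the calling cutoffs a laboratory applies
#'
#' Minimum observed allele fraction, minimum alternate-read count and minimum
#' site depth below which a candidate call is not reported. Thresholds apply
#' to the realized read fraction (alt reads / depth), mirroring how somatic
#' callers filter observed allele fraction.
#'
#' @slot minVaf minimum observed allele fraction in [0, 1].
#' @slot minAltReads minimum alternate-supporting reads.
#' @slot minDepth minimum total depth at the site.
#' @export
setClass("CallerThresholds",
    representation(minVaf = "numeric", minAltReads = "numeric",
                   minDepth = "numeric"))

setValidity("CallerThresholds", function(object) {
    msg <- NULL
    v <- c(object@minVaf, object@minAltReads, object@minDepth)
    if (length(object@minVaf) != 1L || length(object@minAltReads) != 1L ||
        length(object@minDepth) != 1L)
        msg <- c(msg, "all thresholds must be single numbers")
    else {
        if (any(v < 0)) msg <- c(msg, "thresholds must be non-negative")
        if (object@minVaf > 1) msg <- c(msg, "minVaf must be <= 1")
    }
    if (is.null(msg)) TRUE else msg
})

#' LabProfile: simulator parameters for one laboratory
#'
#' Captures the mechanisms through which laboratories disagree: a different
#' capture region, different mean depth (with negative-binomial dispersion),
#' different calling thresholds, a false-positive artifact rate per megabase
#' of capture, and a germline-leakage rate (fraction of a shared germline pool
#' mis-reported as somatic).
#'
#' @slot label laboratory label.
#' @slot capture \linkS4class{RegionSet} targeted by the lab's kit.
#' @slot meanDepth mean on-target coverage.
#' @slot depthDispersion negative-binomial size parameter (smaller = more
#'   overdispersed coverage).
#' @slot thresholds \linkS4class{CallerThresholds}.
#' @slot fpRate expected false calls per megabase of capture.
#' @slot germlineLeakRate per-variant probability that a germline variant in
#'   capture leaks into the somatic report.
#' @slot seedOffset lab-specific offset added to the master seed.
#' @export
setClass("LabProfile",
    representation(label = "character", capture = "RegionSet",
                   meanDepth = "numeric", depthDispersion = "numeric",
                   thresholds = "CallerThresholds", fpRate = "numeric",
                   germlineLeakRate = "numeric", seedOffset = "integer"))

setValidity("LabProfile", function(object) {
    msg <- NULL
    if (length(object@label) != 1L)
        msg <- c(msg, "'label' must be a single string")
    if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be positive")
    if (object@depthDispersion <= 0)
        msg <- c(msg, "depthDispersion must be positive")
    if (object@fpRate < 0 || object@germlineLeakRate < 0 ||
        object@germlineLeakRate > 1)
        msg <- c(msg, "fpRate must be >= 0 and germlineLeakRate in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' CohortConfig: one simulated sample across all laboratories
#'
#' Everything needed to regenerate a multi-laboratory call set for one sample:
#' the toy genome (a \code{Seqinfo}), the common panel, the number of planted
#' somatic mutations and their zygosity mix, tumor purity, per-lab profiles,
#' replicates per lab, the size of the shared germline pool, and a master
#' seed. Identical config + seed gives identical output.
#'
#' @slot sampleLabel sample label (e.g. "S1").
#' @slot genome \code{Seqinfo} with contig names and lengths.
#' @slot panel common gene-panel stand-in (\linkS4class{RegionSet}).
#' @slot nTruthMutations number of planted somatic mutations.
#' @slot hetFraction probability a planted mutation is heterozygous.
#' @slot purity tumor purity in (0, 1].
#' @slot labs list of \linkS4class{LabProfile}.
#' @slot replicates named integer vector: replicates per lab label.
#' @slot nGermline size of the shared germline pool.
#' @slot masterSeed integer master seed.
#' @export
setClass("CohortConfig",
    representation(sampleLabel = "character", genome = "Seqinfo",
                   panel = "RegionSet", nTruthMutations = "integer",
                   hetFraction = "numeric", purity = "numeric",
                   labs = "list", replicates = "integer",
                   nGermline = "integer", masterSeed = "integer"))

setValidity("CohortConfig", function(object) {
    msg <- NULL
    if (!all(vapply(object@labs, is, logical(1), "LabProfile")))
        msg <- c(msg, "'labs' must be a list of LabProfile objects")
    labNames <- vapply(object@labs, function(p) p@label, character(1))
    if (anyDuplicated(labNames))
        msg <- c(msg, "lab labels must be unique")
    if (!all(names(object@replicates) %in% labNames))
        msg <- c(msg, "'replicates' names must match lab labels")
    if (any(object@replicates < 1L))
        msg <- c(msg, "each lab needs at least one replicate")
    if (object@purity <= 0 || object@purity > 1)
        msg <- c(msg, "purity must be in (0, 1]")
    if (object@hetFraction < 0 || object@hetFraction > 1)
        msg <- c(msg, "hetFraction must be in [0, 1]")
    gsize <- sum(as.numeric(seqlengths(object@genome)))
    if (object@nTruthMutations + object@nGermline > gsize)
        msg <- c(msg, "more planted variants than genome positions")
    if (is.null(msg)) TRUE else msg
})

#' StudyConfig: file manifest for one multi-laboratory study
#'
#' Names the laboratories, samples and per-replicate call files of a study,
#' plus the panel BED, per-lab capture BEDs and optional per-sample truth
#' files. Each (lab, sample, replicate) appears exactly once; a (lab, sample)
#' may have a single replicate, which downstream propagates as a not-available
#' concordance rather than zero.
#'
#' @slot labs laboratory labels.
#' @slot samples sample labels.
#' @slot files data.frame with columns lab, sample, replicate, path.
#' @slot panelPath path to the common panel BED (or NA).
#' @slot truthPaths named character vector sample -> truth VCF path.
#' @slot capturePaths named character vector lab -> capture BED path.
#' @slot baseDir directory against which relative paths resolve.
#' @export
setClass("StudyConfig",
    representation(labs = "character", samples = "character",
                   files = "data.frame", panelPath = "character",
                   truthPaths = "character", capturePaths = "character",
                   tabularSchemas = "list", baseDir = "character"))

setValidity("StudyConfig", function(object) {
    msg <- NULL
    need <- c("lab", "sample", "replicate", "path")
    if (!all(need %in% names(object@files)))
        msg <- c(msg, "files must have columns lab, sample, replicate, path")
    else {
        key <- with(object@files, paste(lab, sample, replicate))
        if (anyDuplicated(key))
            msg <- c(msg, "each (lab, sample, replicate) must appear once")
        if (anyDuplicated(object@files$path))
            msg <- c(msg, "each path must be declared exactly once")
    }
    if (is.null(msg)) TRUE else msg
})

#' ConcordanceResult: replicate agreement by the Dice formula
#'
#' Concordance between two replicate call sets is 100 times the number of
#' shared mutations divided by the average of the two reported counts — i.e.
#' the Dice coefficient as a percentage. When only one replicate exists (or
#' both sets are empty) the value is not available (\code{NA}), which is
#' distinct from 0.
#'
#' @slot n1,n2 reported mutation counts of the two replicates.
#' @slot nOverlap number of shared mutation keys.
#' @slot pct concordance percentage, rounded half-up to 2 decimals; \code{NA}
#'   when undefined.
#' @slot status "ok" or "undefined".
#' @export
setClass("ConcordanceResult",
    representation(n1 = "integer", n2 = "integer", nOverlap = "integer",
                   pct = "numeric", status = "character"))

setValidity("ConcordanceResult", function(object) {
    if (!is.na(object@nOverlap) &&
        object@nOverlap > min(object@n1, object@n2, na.rm = TRUE))
        return("overlap cannot exceed either replicate count")
    TRUE
})

#' SensitivityResult: truth-set recovery
#'
#' Sensitivity against an expected-mutation truth set: the number of calls
#' found in the truth set over the truth-set size. The display value is
#' rounded to the nearest integer percent (half-up), as such tables are
#' printed; the exact percentage is retained.
#'
#' @slot nExpected truth-set size.
#' @slot nDetected calls found in the truth set.
#' @slot pct exact percentage.
#' @slot status "ok" or "undefined" (empty truth).
#' @export
setClass("SensitivityResult",
    representation(nExpected = "integer", nDetected = "integer",
                   pct = "numeric", status = "character"))

#' OverlapSummary: shared and private mutations across laboratories
#'
#' Cross-set overlap structure: per-set key counts, the pairwise intersection
#' matrix, the count shared by all sets, and per-set private counts (keys seen
#' by exactly one set).
#'
#' @slot labels set labels.
#' @slot counts per-set key counts.
#' @slot pairwise pairwise intersection count matrix.
#' @slot sharedByAll keys present in every set.
#' @slot private per-set private key counts.
#' @export
setClass("OverlapSummary",
    representation(labels = "character", counts = "integer",
                   pairwise = "matrix", sharedByAll = "integer",
                   private = "integer"))

setValidity("OverlapSummary", function(object) {
    p <- object@pairwise
    if (any(object@sharedByAll > p))
        return("shared-by-all cannot exceed any pairwise intersection")
    if (any(p > pmin(matrix(object@counts, nrow(p), ncol(p)),
                     matrix(object@counts, nrow(p), ncol(p), byrow = TRUE))))
        return("pairwise intersection cannot exceed either set count")
    TRUE
})

#' BurdenEstimate: mutations per megabase
#'
#' Mutational burden as mutation count divided by the interrogated region
#' size in megabases. Undefined (NA) for an empty region.
#'
#' @slot nMutations mutation count.
#' @slot regionMb region size in megabases.
#' @slot burden mutations per Mb (NA when regionMb is 0).
#' @export
setClass("BurdenEstimate",
    representation(nMutations = "integer", regionMb = "numeric",
                   burden = "numeric"))

#' StudyResult: all results of one study run
#'
#' @slot concordance data.frame mirroring the per-lab/per-sample replicate
#'   table (vendor-reported and unified-analysis columns).
#' @slot sensitivity data.frame of per-replicate truth-set sensitivity.
#' @slot overlaps per-sample list with vendor-space and unified
#'   \linkS4class{OverlapSummary} objects.
#' @slot burden data.frame of per-replicate burden estimates.
#' @slot provenance list: config path and md5, input file md5s, parameters.
#' @export
setClass("StudyResult",
    representation(concordance = "data.frame", sensitivity = "data.frame",
                   overlaps = "list", burden = "data.frame",
                   provenance = "list"))
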