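#' Replicate concordance (Dice coefficient as a percentage)
#'
#' Concordance between two replicate call sets is the number of shared
#' mutation keys divided by the average of the two reported counts, times
#' 100 — algebraically the Dice coefficient \eqn{2|A \cap B| / (|A| + |B|)}
#' expressed as a percentage. It is symmetric, 100 exactly when the two
#' non-empty key sets are identical, 0 when one set is empty and the other is
#' not, and undefined (\code{NA}, reported as "N.A.") when both are empty or
#' when \code{b} is \code{NULL} (a single-replicate laboratory).
#'
#' @param a,b \linkS4class{MutationSet} objects, nominally two replicates of
#'   the same laboratory and sample (mismatched labels produce a warning
#'   only). \code{b = NULL} yields the not-available result.
#' @return a \linkS4class{ConcordanceResult}; the percentage is rounded
#'   half-up to 2 decimals.
#' @export
#' @examples
#' a <- MutationSet(contig = "1", position = 1:10, ref = "A", alt = "T")
#' replicateConcordance(a, a)  # 100
replicateConcordance <- function(a, b = NULL) {
    stopifnot(is(a, "MutationSet"))
    if (is.null(b))
        return(new("ConcordanceResult", n1 = length(a), n2 = NA_integer_,
                   nOverlap = NA_integer_, pct = NA_real_,
                   status = "undefined"))
    stopifnot(is(b, "MutationSet"))
    if (labName(a) != labName(b) || sampleName(a) != sampleName(b))
        warning("comparing replicates with different lab/sample labels (",
                labName(a), "/", sampleName(a), " vs ", labName(b), "/",
                sampleName(b), ")", call. = FALSE)
    n1 <- length(a); n2 <- length(b)
    if (n1 + n2 == 0L)
        return(new("ConcordanceResult", n1 = 0L, n2 = 0L,
                   nOverlap = 0L, pct = NA_real_, status = "undefined"))
    ov <- length(keyIntersection(a, b))
    new("ConcordanceResult", n1 = n1, n2 = n2, nOverlap = ov,
        pct = concordanceFromCounts(n1, n2, ov), status = "ok")
}

#' Concordance percentage from printed counts
#'
#' The same formula applied directly to a (replicate 1, replicate 2, overlap)
#' count triple, for reproducing published replicate tables without the
#' underlying key sets.
#'
#' @param n1,n2 replicate mutation counts.
#' @param nOverlap shared-mutation count.
#' @return percentage rounded half-up to 2 decimals.
#' @export
#' @examples
#' concordanceFromCounts(519, 553, 391)   # 72.95
#' concordanceFromCounts(13892, 23410, 573)  # 3.07
concordanceFromCounts <- function(n1, n2, nOverlap) {
    stopifnot(all(nOverlap <= pmin(n1, n2)))
    ifelse(n1 + n2 == 0, NA_real_,
           roundHalfUp(100 * nOverlap / ((n1 + n2) / 2), 2))
}

#' @rdname SomaticConcord-generics
#' @export
setMethod("concordancePct", "ConcordanceResult", function(x) x@pct)

setMethod("show", "ConcordanceResult", function(object) {
    cat("ConcordanceResult: n1=", object@n1, ", n2=", object@n2,
        ", overlap=", object@nOverlap, " -> ", .formatPct(object@pct),
        if (object@status != "ok") " (undefined)" else "", "\n", sep = "")
})

#' Sensitivity against a truth set
#'
#' Counts the calls whose canonical keys are present in the expected-mutation
#' truth set and reports the fraction of the truth set recovered. The exact
#' percentage is retained; published tables print it rounded to the nearest
#' integer, available via \code{sensitivityPct(x, display = TRUE)}.
#' Precision against truth (the fraction of calls that are true), which
#' published comparisons typically omit, is available from
#' \code{\link{callPrecision}} as a labelled extension.
#'
#' @param calls a \linkS4class{MutationSet}.
#' @param truth a \linkS4class{TruthSet}.
#' @return a \linkS4class{SensitivityResult}.
#' @export
truthSensitivity <- function(calls, truth) {
    stopifnot(is(calls, "MutationSet"), is(truth, "TruthSet"))
    nExp <- length(truth)
    if (nExp == 0L)
        return(new("SensitivityResult", nExpected = 0L,
                   nDetected = 0L, pct = NA_real_, status = "undefined"))
    nDet <- length(keyIntersection(calls, truth))
    new("SensitivityResult", nExpected = nExp, nDetected = nDet,
        pct = 100 * nDet / nExp, status = "ok")
}

#' @describeIn SomaticConcord-generics exact sensitivity percentage, or the
#'   nearest-integer display value with \code{display = TRUE}.
#' @param display round half-up to the nearest integer for display.
#' @export
setMethod("sensitivityPct", "SensitivityResult",
    function(x, display = FALSE) {
        if (display) roundHalfUp(x@pct, 0) else x@pct
    })

setMethod("show", "SensitivityResult", function(object) {
    if (object@status != "ok") {
        cat("SensitivityResult: undefined (empty truth set)\n")
    } else {
        cat("SensitivityResult: ", object@nDetected, " of ",
            object@nExpected, " expected mutations detected (",
            roundHalfUp(object@pct, 0), "%)\n", sep = "")
    }
})

#' Precision of calls against a truth set
#'
#' The fraction of reported calls present in the truth set (1 - false
#' discovery rate). This is an extension beyond the usual replicate tables:
#' it is only meaningful when the truth set is exhaustive over the
#' interrogated region, which a curated hotspot list generally is not —
#' interpret with care.
#'
#' @inheritParams truthSensitivity
#' @return list with \code{nCalls}, \code{nTrue}, \code{precisionPct}
#'   (\code{NA} for an empty call set).
#' @export
callPrecision <- function(calls, truth) {
    stopifnot(is(calls, "MutationSet"), is(truth, "TruthSet"))
    n <- length(calls)
    nTrue <- length(keyIntersection(calls, truth))
    list(nCalls = n, nTrue = nTrue,
         precisionPct = if (n) 100 * nTrue / n else NA_real_)
}

#' Shared and private mutations across laboratories
#'
#' Partitions the union of several call sets by membership: per-set totals,
#' all pairwise intersection counts, the count shared by every set, and
#' per-set private counts (keys reported by exactly one set). The partition
#' is checked internally: for every set, private plus shared-with-at-least-
#' one-other equals the set's total.
#'
#' @param sets list of at least two \linkS4class{MutationSet} objects.
#' @param labels optional labels (default: lab names).
#' @return an \linkS4class{OverlapSummary}.
#' @export
overlapSummary <- function(sets, labels = NULL) {
    if (length(sets) < 2L)
        stop("overlap summary needs at least two sets", call. = FALSE)
    stopifnot(all(vapply(sets, is, logical(1), "MutationSet")))
    if (is.null(labels))
        labels <- vapply(sets, labName, character(1))
    if (anyDuplicated(labels))
        labels <- paste0(labels, "/", vapply(sets, replicateName,
                                             character(1)))
    keys <- lapply(sets, mutationKeys)
    for (i in seq_along(keys)[-1])
        .checkNamespace(keys[[1]], keys[[i]])
    k <- length(keys)
    counts <- lengths(keys)
    pw <- matrix(0L, k, k, dimnames = list(labels, labels))
    for (i in seq_len(k))
        for (j in seq_len(k))
            pw[i, j] <- length(intersect(keys[[i]], keys[[j]]))
    shared <- Reduce(intersect, keys)
    priv <- vapply(seq_len(k), function(i)
        length(setdiff(keys[[i]], unlist(keys[-i], use.names = FALSE))),
        integer(1))
    for (i in seq_len(k)) {
        sharedAny <- counts[i] - priv[i]
        stopifnot(priv[i] + sharedAny == counts[i])
    }
    new("OverlapSummary", labels = labels, counts = as.integer(counts),
        pairwise = pw, sharedByAll = length(shared),
        private = as.integer(priv))
}

setMethod("show", "OverlapSummary", function(object) {
    cat("OverlapSummary over ", length(object@labels), " sets\n", sep = "")
    df <- data.frame(set = object@labels, total = object@counts,
                     private = object@private)
    print(df, row.names = FALSE)
    cat("shared by all: ", object@sharedByAll, "\n", sep = "")
})

#' Pairwise cross-set concordance matrix
#'
#' Dice-percentage concordance for every pair of call sets — used to compare
#' cross-laboratory agreement before and after unified analysis.
#'
#' @param sets list of \linkS4class{MutationSet} objects.
#' @param labels optional labels.
#' @return symmetric numeric matrix of concordance percentages (diagonal
#'   100 for non-empty sets).
#' @export
pairwiseConcordance <- function(sets, labels = NULL) {
    if (is.null(labels))
        labels <- vapply(sets, labName, character(1))
    keys <- lapply(sets, mutationKeys)
    k <- length(sets)
    m <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
    for (i in seq_len(k))
        for (j in seq_len(k)) {
            ni <- length(keys[[i]]); nj <- length(keys[[j]])
            if (ni + nj > 0)
                m[i, j] <- 100 * 2 * length(intersect(keys[[i]], keys[[j]])) /
                    (ni + nj)
        }
    m
}

#' Mutational burden per megabase
#'
#' Mutation count normalized by the interrogated region size in megabases.
#' Burden estimates from different laboratories are only comparable over the
#' same regions; if the call set extends beyond the given regions it is
#' restricted first (with a message).
#'
#' @param calls a \linkS4class{MutationSet}.
#' @param regionSet the interrogated \linkS4class{RegionSet}.
#' @return a \linkS4class{BurdenEstimate} (burden \code{NA} for an empty
#'   region set).
#' @export
mutationalBurden <- function(calls, regionSet) {
    stopifnot(is(calls, "MutationSet"), is(regionSet, "RegionSet"))
    inside <- restrictCalls(calls, regionSet)
    if (length(inside) < length(calls)) {
        message(length(calls) - length(inside), " call(s) outside '",
                regionSet@name, "' dropped before burden estimation")
        calls <- inside
    }
    mb <- regionSizeMb(regionSet)
    new("BurdenEstimate", nMutations = length(calls), regionMb = mb,
        burden = if (mb > 0) length(calls) / mb else NA_real_)
}

setMethod("show", "BurdenEstimate", function(object) {
    cat("BurdenEstimate: ", object@nMutations, " mutation(s) over ",
        format(object@regionMb, digits = 4), " Mb = ",
        format(object@burden, digits = 4), " mutations/Mb\n", sep = "")
})

#' Fold range of reported counts
#'
#' Ratio of the largest to the smallest count — the "differed by N-fold"
#' summary of cross-laboratory spread in reported mutation numbers.
#'
#' @param counts positive counts.
#' @return max(counts) / min(counts).
#' @export
#' @examples
#' foldRange(c(336, 23410))  # ~70-fold spread
foldRange <- function(counts) {
    counts <- as.numeric(counts)
    if (!length(counts) || any(is.na(counts)) || any(counts <= 0))
        stop("fold range requires positive counts", call. = FALSE)
    max(counts) / min(counts)
}
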