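#' Construct a RegionSet
#'
#' Builds a named region set from a \code{GRanges} or from parallel
#' contig/start/end vectors given in BED convention (0-based half-open).
#' Intervals are sorted and merged (overlapping or bookended intervals
#' coalesce), so the stored set is always disjoint; merging is idempotent and
#' preserves total covered size for disjoint input.
#'
#' @param name label for the set.
#' @param gr a \code{GRanges} (1-based inclusive), or \code{NULL} to use the
#'   BED-style vectors.
#' @param contig,start,end BED-style interval columns: \code{start} 0-based
#'   inclusive, \code{end} exclusive.
#' @param stripChr,mito contig-namespace options
#'   (see \code{\link{normalizeContigs}}).
#' @return a \linkS4class{RegionSet}.
#' @export
#' @examples
#' RegionSet("panel", contig = c("1", "1"), start = c(0, 50),
#'           end = c(100, 150))  # merges to one 150 bp interval
RegionSet <- function(name = "regions", gr = NULL, contig = character(0),
                      start = integer(0), end = integer(0),
                      stripChr = TRUE, mito = "MT") {
    if (is.null(gr)) {
        start <- as.numeric(start); end <- as.numeric(end)
        if (any(start >= end))
            stop("BED interval with start >= end", call. = FALSE)
        gr <- GRanges(normalizeContigs(contig, stripChr, mito),
                      IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)))
    } else {
        gr <- GRanges(normalizeContigs(as.character(seqnames(gr)),
                                       stripChr, mito),
                      IRanges(start(gr), end(gr)))
    }
    gr <- reduce(sort(gr), ignore.strand = TRUE)
    new("RegionSet", name = as.character(name), regions = gr)
}

#' @rdname SomaticConcord-generics
#' @export
setMethod("regions", "RegionSet", function(x) x@regions)

#' @describeIn SomaticConcord-generics total covered size in base pairs.
#' @export
setMethod("regionSize", "RegionSet",
    function(x) sum(as.numeric(width(x@regions))))

#' @describeIn SomaticConcord-generics total covered size in megabases
#'   (bases / 1e6).
#' @export
setMethod("regionSizeMb", "RegionSet", function(x) regionSize(x) / 1e6)

#' @export
setMethod("length", "RegionSet", function(x) length(x@regions))

setMethod("show", "RegionSet", function(object) {
    cat("RegionSet '", object@name, "': ", length(object@regions),
        " interval(s) on ",
        length(unique(as.character(seqnames(object@regions)))),
        " contig(s), ", regionSize(object), " bp (",
        format(regionSizeMb(object), digits = 4), " Mb)\n", sep = "")
})

#' Intersect two region sets
#'
#' Commutative interval intersection: the result covers exactly the bases
#' covered by both inputs, so its total size never exceeds the smaller input
#' and \code{intersectRegions(a, a)} equals \code{a}. Used to build the
#' common comparison space from per-laboratory capture regions.
#'
#' @param a,b \linkS4class{RegionSet} objects.
#' @param name label for the result.
#' @return a \linkS4class{RegionSet}.
#' @export
intersectRegions <- function(a, b, name = paste0(a@name, "&", b@name)) {
    stopifnot(is(a, "RegionSet"), is(b, "RegionSet"))
    ## disjoint contig sets are a valid (empty) intersection, not a warning
    gr <- withCallingHandlers(
        GenomicRanges::intersect(a@regions, b@regions, ignore.strand = TRUE),
        warning = function(w) {
            if (grepl("sequence levels in common", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    new("RegionSet", name = name, regions = reduce(sort(gr)))
}

#' Restrict a mutation set to a genomic region set
#'
#' Keeps exactly the keys whose (normalized, 1-based) anchor position falls
#' inside the region set — for a 0-based half-open interval [start, end),
#' position p is inside iff p - 1 lies in [start, end), matching bedtools
#' semantics for point variants. Deletions count by their anchor base.
#' Labels and per-key annotation are preserved; the operation is idempotent
#' and composes with region intersection.
#'
#' @param x a \linkS4class{MutationSet} (or \linkS4class{TruthSet}).
#' @param regionSet a \linkS4class{RegionSet}.
#' @return a \linkS4class{MutationSet} of the same class as \code{x}.
#' @export
restrictCalls <- function(x, regionSet) {
    stopifnot(is(x, "MutationSet"), is(regionSet, "RegionSet"))
    out <- x
    if (!length(x@calls) || !length(regionSet@regions)) {
        out@calls <- x@calls[integer(0)]
        return(out)
    }
    hits <- withCallingHandlers(
        findOverlaps(x@calls, regionSet@regions, ignore.strand = TRUE),
        warning = function(w) {
            if (grepl("sequence levels in common", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    out@calls <- x@calls[sort(unique(queryHits(hits)))]
    out
}
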