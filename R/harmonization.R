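## Canonical key strings: contig:position:ref>alt. Key equality is exact —
## two calls agree iff contig, position, ref and alt all match; there is no
## fuzzy position window.
.keyStrings <- function(x) {
    gr <- if (is(x, "MutationSet")) x@calls else x
    if (!length(gr)) return(character(0))
    paste0(as.character(seqnames(gr)), ":", start(gr), ":",
           mcols(gr)$ref, ">", mcols(gr)$alt)
}

#' Trim a ref/alt allele pair to canonical form
#'
#' Removes the shared suffix, then the shared prefix (advancing the position
#' past each trimmed leading base), always leaving at least one base in each
#' allele so that indels keep their anchor base. SNVs pass through unchanged.
#' This removes the dominant representation differences between reports
#' without requiring a reference genome; full left-alignment of indels is not
#' performed (see the package vignette).
#'
#' @param position 1-based position.
#' @param ref,alt uppercase allele strings.
#' @return list with elements \code{position}, \code{ref}, \code{alt}.
#' @keywords internal
.trimAllelePair <- function(position, ref, alt) {
    r <- strsplit(ref, "", fixed = TRUE)[[1]]
    a <- strsplit(alt, "", fixed = TRUE)[[1]]
    while (length(r) > 1L && length(a) > 1L &&
           r[length(r)] == a[length(a)]) {
        r <- r[-length(r)]
        a <- a[-length(a)]
    }
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
        r <- r[-1L]
        a <- a[-1L]
        position <- position + 1L
    }
    list(position = position,
         ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Normalize raw variant records into canonical mutation keys
#'
#' Implements the mutation-identity rule used for cross-laboratory
#' comparison: a unique mutation is a genomic coordinate plus the base
#' change. Each record is split into one key per alternate allele, alleles
#' are uppercased, contigs are funneled through \code{\link{normalizeContigs}},
#' and shared suffix/prefix bases are trimmed with the position advanced past
#' trimmed leading bases. Normalization is idempotent.
#'
#' An optional hook for full reference-based left-alignment may be supplied
#' via \code{leftAlign}; by default no reference genome is required.
#'
#' @param records a \code{DataFrame} of raw variant records as returned by
#'   \code{\link{readVcfCalls}} or \code{\link{readTabularReport}}.
#' @param stripChr,mito contig-namespace options passed to
#'   \code{\link{normalizeContigs}}.
#' @param leftAlign optional function \code{(contig, position, ref, alt) ->
#'   list(position, ref, alt)} applied after trimming, e.g. for
#'   reference-based left alignment.
#' @return a \code{DataFrame} with one row per mutation key: columns
#'   \code{contig}, \code{position}, \code{ref}, \code{alt}, plus carried
#'   \code{vaf}, \code{depth} and \code{filter}.
#' @export
#' @examples
#' rec <- rawVariantRecords(contig = "chr1", position = 100L,
#'                          ref = "CT", alt = list("CA"))
#' normalizeCalls(rec)  # one key at position 101, T>A
normalizeCalls <- function(records, stripChr = TRUE, mito = "MT",
                           leftAlign = NULL) {
    stopifnot(is(records, "DataFrame"))
    if (!nrow(records))
        return(DataFrame(contig = character(0), position = integer(0),
                         ref = character(0), alt = character(0),
                         vaf = numeric(0), depth = integer(0),
                         filter = character(0)))
    nAlt <- lengths(records$alt)
    idx <- rep(seq_len(nrow(records)), nAlt)
    contig <- normalizeContigs(records$contig[idx], stripChr, mito)
    position <- as.integer(records$position[idx])
    ref <- toupper(records$ref[idx])
    alt <- toupper(unlist(records$alt, use.names = FALSE))
    if (!all(.validAllele(ref)) || !all(.validAllele(alt)))
        stop("alleles must match [ACGTN]+", call. = FALSE)
    for (i in seq_along(position)) {
        tr <- .trimAllelePair(position[i], ref[i], alt[i])
        if (tr$ref == tr$alt)
            stop("degenerate variant at ", contig[i], ":", position[i],
                 " (", ref[i], ">", alt[i], "): alt equals ref after trimming",
                 call. = FALSE)
        if (!is.null(leftAlign)) {
            la <- leftAlign(contig[i], tr$position, tr$ref, tr$alt)
            tr[c("position", "ref", "alt")] <- la[c("position", "ref", "alt")]
        }
        position[i] <- tr$position
        ref[i] <- tr$ref
        alt[i] <- tr$alt
    }
    vaf <- if (is.null(records$vaf)) rep(NA_real_, nrow(records)) else records$vaf
    depth <- if (is.null(records$depth)) rep(NA_integer_, nrow(records)) else records$depth
    filt <- if (is.null(records$filter)) rep(NA_character_, nrow(records)) else records$filter
    DataFrame(contig = contig, position = position, ref = ref, alt = alt,
              vaf = as.numeric(vaf[idx]), depth = as.integer(depth[idx]),
              filter = as.character(filt[idx]))
}

#' Construct a MutationSet from key vectors
#'
#' Low-level constructor; most users build sets from files via
#' \code{\link{buildMutationSet}}. Duplicate keys collapse to one entry,
#' keeping the maximum-depth annotation.
#'
#' @param lab,sample,replicate labels for the set.
#' @param contig,position,ref,alt parallel key vectors (alleles uppercase,
#'   positions 1-based).
#' @param vaf,depth,filter optional parallel annotation vectors.
#' @return a \linkS4class{MutationSet}.
#' @export
#' @examples
#' MutationSet("LabA", "S1", "1", contig = "1", position = c(100L, 200L),
#'             ref = c("A", "C"), alt = c("T", "G"))
MutationSet <- function(lab = "unknown", sample = "unknown", replicate = "1",
                        contig = character(0), position = integer(0),
                        ref = character(0), alt = character(0),
                        vaf = NULL, depth = NULL, filter = NULL) {
    n <- length(position)
    gr <- GRanges(rep(as.character(contig), length.out = n),
                  IRanges(as.integer(position), width = 1L))
    mcols(gr)$ref <- toupper(rep(ref, length.out = n))
    mcols(gr)$alt <- toupper(rep(alt, length.out = n))
    mcols(gr)$vaf <- if (is.null(vaf)) rep(NA_real_, n) else as.numeric(vaf)
    mcols(gr)$depth <- if (is.null(depth)) rep(NA_integer_, n) else as.integer(depth)
    mcols(gr)$filter <- if (is.null(filter)) rep(NA_character_, n)
                        else as.character(filter)
    gr <- .dedupeCalls(gr)
    new("MutationSet", lab = as.character(lab), sample = as.character(sample),
        replicate = as.character(replicate), calls = sort(gr))
}

## Collapse duplicate keys, keeping the maximum-depth annotation for each.
.dedupeCalls <- function(gr) {
    if (!length(gr)) return(gr)
    key <- paste0(as.character(seqnames(gr)), ":", start(gr), ":",
                  mcols(gr)$ref, ">", mcols(gr)$alt)
    if (!anyDuplicated(key)) return(gr)
    d <- mcols(gr)$depth
    ord <- order(key, -ifelse(is.na(d), -1, d))
    gr <- gr[ord]
    key <- key[ord]
    gr[!duplicated(key)]
}

#' Construct a TruthSet
#'
#' @inheritParams MutationSet
#' @param zygosity "heterozygous" or "homozygous" per key.
#' @return a \linkS4class{TruthSet}.
#' @export
TruthSet <- function(sample = "truth", contig = character(0),
                     position = integer(0), ref = character(0),
                     alt = character(0), zygosity = character(0),
                     lab = "truth", replicate = "1") {
    ms <- MutationSet(lab = lab, sample = sample, replicate = replicate,
                      contig = contig, position = position,
                      ref = ref, alt = alt)
    mcols(ms@calls)$zygosity <- rep(as.character(zygosity),
                                    length.out = length(ms@calls))
    new("TruthSet", ms)
}

#' Build a de-duplicated MutationSet from raw records
#'
#' Normalizes records into canonical keys (see \code{\link{normalizeCalls}}),
#' optionally drops records that failed the originating pipeline's FILTER,
#' and collapses duplicate keys (a site listed once per transcript, say) to
#' one entry, keeping the maximum-depth annotation. The collapse count is
#' reported via \code{message()}.
#'
#' @param records raw variant records (\code{DataFrame}).
#' @param lab,sample,replicate labels.
#' @param includeFiltered keep records whose filter status is neither
#'   \code{PASS} nor missing. The originating pipelines' filtering rules are
#'   generally unknown, so inclusion is the analyst's choice; the default
#'   (\code{FALSE}) analyses PASS calls only.
#' @param ... passed to \code{\link{normalizeCalls}}.
#' @return a \linkS4class{MutationSet}.
#' @export
buildMutationSet <- function(records, lab = "unknown", sample = "unknown",
                             replicate = "1", includeFiltered = FALSE, ...) {
    keys <- normalizeCalls(records, ...)
    if (!includeFiltered && nrow(keys)) {
        pass <- is.na(keys$filter) | keys$filter %in% c("PASS", ".")
        keys <- keys[pass, , drop = FALSE]
    }
    ms <- MutationSet(lab = lab, sample = sample, replicate = replicate,
                      contig = keys$contig, position = keys$position,
                      ref = keys$ref, alt = keys$alt,
                      vaf = keys$vaf, depth = keys$depth,
                      filter = keys$filter)
    nDup <- nrow(keys) - length(ms@calls)
    if (nDup > 0)
        message(nDup, " duplicate key(s) collapsed for ", lab, "/", sample,
                "/", replicate)
    message("built mutation set ", lab, "/", sample, "/", replicate, ": ",
            length(ms@calls), " unique key(s)")
    ms
}

#' Set operations on mutation keys
#'
#' \code{keyIntersection} returns the keys present in both sets;
#' \code{privateKeys} returns the keys of \code{a} present in none of the
#' \code{others}. Both operate on exact canonical keys and refuse to compare
#' sets whose contig conventions are mixed.
#'
#' @param a,b \linkS4class{MutationSet} objects.
#' @param others list of \linkS4class{MutationSet} objects.
#' @return character vector of canonical key strings
#'   (\code{contig:pos:ref>alt}).
#' @export
keyIntersection <- function(a, b) {
    ka <- mutationKeys(a); kb <- mutationKeys(b)
    .checkNamespace(ka, kb)
    intersect(ka, kb)
}

#' @rdname keyIntersection
#' @export
privateKeys <- function(a, others) {
    if (is(others, "MutationSet")) others <- list(others)
    ka <- mutationKeys(a)
    ko <- unlist(lapply(others, mutationKeys), use.names = FALSE)
    .checkNamespace(ka, ko)
    setdiff(ka, ko)
}

#' Re-apply calling thresholds to a mutation set
#'
#' Filters a set's keys by stored per-key allele fraction and depth against a
#' \linkS4class{CallerThresholds}, the operation a unified analysis performs
#' when re-evaluating heterogeneous reports under one cutoff. Keys lacking
#' vaf/depth annotation are kept (nothing to threshold on).
#'
#' @param x a \linkS4class{MutationSet}.
#' @param thresholds a \linkS4class{CallerThresholds}.
#' @return a filtered \linkS4class{MutationSet} with the same labels.
#' @export
applyThresholds <- function(x, thresholds) {
    stopifnot(is(x, "MutationSet"), is(thresholds, "CallerThresholds"))
    gr <- x@calls
    if (!length(gr)) return(x)
    vaf <- mcols(gr)$vaf
    depth <- mcols(gr)$depth
    alt <- ifelse(is.na(vaf) | is.na(depth), NA_real_,
                  round(vaf * depth))
    keep <- (is.na(depth) | depth >= thresholds@minDepth) &
            (is.na(alt) | alt >= thresholds@minAltReads) &
            (is.na(vaf) | vaf + .EPS >= thresholds@minVaf)
    out <- x
    out@calls <- gr[keep]
    mcols(out@calls)$filter <- rep("PASS", sum(keep))
    out
}

#' Subset a mutation set to calls that passed filtering
#'
#' Keeps keys whose filter status is \code{PASS}, \code{.} or missing — the
#' calls the originating pipeline stood behind.
#'
#' @param x a \linkS4class{MutationSet}.
#' @return a \linkS4class{MutationSet}.
#' @export
passedCalls <- function(x) {
    stopifnot(is(x, "MutationSet"))
    f <- mcols(x@calls)$filter
    out <- x
    out@calls <- x@calls[is.na(f) | f %in% c("PASS", ".")]
    out
}

## ---- accessors & show ----

#' @rdname SomaticConcord-generics
#' @export
setMethod("labName", "MutationSet", function(x) x@lab)

#' @rdname SomaticConcord-generics
#' @export
setMethod("sampleName", "MutationSet", function(x) x@sample)

#' @rdname SomaticConcord-generics
#' @export
setMethod("replicateName", "MutationSet", function(x) x@replicate)

#' @rdname SomaticConcord-generics
#' @export
setMethod("mutationKeys", "MutationSet", function(x, ...) .keyStrings(x))

#' @describeIn SomaticConcord-generics per-key table: contig, position, ref,
#'   alt, vaf, depth, filter (and zygosity for truth sets).
#' @export
setMethod("callData", "MutationSet", function(x, ...) {
    gr <- x@calls
    DataFrame(contig = as.character(seqnames(gr)), position = start(gr),
              mcols(gr))
})

#' @export
setMethod("length", "MutationSet", function(x) length(x@calls))

setMethod("show", "MutationSet", function(object) {
    cat(class(object), "  ", object@lab, "/", object@sample, "/",
        object@replicate, ": ", length(object@calls),
        " unique mutation key(s)\n", sep = "")
    if (length(object@calls)) {
        k <- .keyStrings(object)
        cat("  ", paste(utils::head(k, 4), collapse = ", "),
            if (length(k) > 4) ", ..." else "", "\n", sep = "")
    }
})
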