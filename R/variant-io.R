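#' @importFrom VariantAnnotation readVcf writeVcf VCF VCFHeader header
#'   header<- meta meta<- info info<- fixed alt ref filt geno
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom Biostrings DNAStringSet DNAStringSetList
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom IRanges CharacterList DataFrameList
#' @importFrom rtracklayer import export
NULL

#' Assemble raw variant records
#'
#' Builds the \code{DataFrame} of raw records that the readers return and the
#' harmonization step consumes: one row per report line, multi-allelic lines
#' kept as one row with several alternate alleles.
#'
#' @param contig contig labels (as reported; not yet normalized).
#' @param position 1-based positions.
#' @param ref reference alleles.
#' @param alt list (or \code{CharacterList}) of alternate-allele vectors, or a
#'   character vector for single-alternate records.
#' @param vaf,depth,filter optional per-record annotation.
#' @return a \code{DataFrame} with a \code{CharacterList} column \code{alt}.
#' @export
#' @examples
#' rawVariantRecords("chr1", 100L, "A", list(c("T", "G")))
rawVariantRecords <- function(contig, position, ref, alt,
                              vaf = NULL, depth = NULL, filter = NULL) {
    if (!is.list(alt) && !is(alt, "CharacterList"))
        alt <- as.list(alt)
    n <- length(position)
    position <- as.integer(position)
    if (any(is.na(position)) || any(position < 1L))
        stop("positions must be integers >= 1", call. = FALSE)
    ref <- toupper(as.character(ref))
    alt <- CharacterList(lapply(alt, function(a) toupper(as.character(a))))
    if (!all(.validAllele(ref)) ||
        !all(.validAllele(unlist(alt, use.names = FALSE))))
        stop("alleles must match [ACGTN]+ after uppercasing", call. = FALSE)
    DataFrame(contig = as.character(contig), position = position,
              ref = ref, alt = alt,
              vaf = if (is.null(vaf)) rep(NA_real_, n) else as.numeric(vaf),
              depth = if (is.null(depth)) rep(NA_integer_, n)
                      else as.integer(depth),
              filter = if (is.null(filter)) rep(NA_character_, n)
                       else as.character(filter))
}

#' Read somatic calls from a VCF file
#'
#' Reads a VCF 4.x file (plain or bgzipped) into raw variant records: one
#' record per data line, multi-allelic lines preserved with all alternates.
#' Records that fail FILTER (anything other than \code{PASS} or \code{.}) are
#' returned with their filter status set, not dropped — whether to include
#' them is a downstream choice (\code{\link{buildMutationSet}}).
#'
#' Allele fraction and depth are taken from the INFO fields \code{VAF} (or
#' \code{AF}) and \code{DP} when present; if \code{sampleName} is given, the
#' per-sample FORMAT fields \code{AF} and \code{DP} take precedence.
#'
#' @param path VCF file path.
#' @param sampleName optional genotype column to read AF/DP from.
#' @return raw variant records (see \code{\link{rawVariantRecords}}).
#' @export
readVcfCalls <- function(path, sampleName = NULL) {
    if (!file.exists(path))
        stop("VCF file not found: ", path, call. = FALSE)
    if (!.vcfHasRecords(path)) {
        message("read 0 record(s) from VCF ", path)
        return(rawVariantRecords(character(0), integer(0), character(0),
                                 list()))
    }
    vcf <- tryCatch(
        suppressWarnings(readVcf(path, genome = "unknown")),
        error = function(e)
            stop("malformed VCF '", path, "': ", conditionMessage(e),
                 call. = FALSE))
    rr <- rowRanges(vcf)
    n <- length(rr)
    altL <- CharacterList(lapply(as.list(alt(vcf)), as.character))
    vaf <- rep(NA_real_, n)
    depth <- rep(NA_integer_, n)
    inf <- info(vcf)
    grab1 <- function(x) {
        if (is.list(x) || is(x, "List"))
            vapply(as.list(x), function(v)
                if (length(v)) as.numeric(v[1]) else NA_real_, numeric(1))
        else as.numeric(x)
    }
    if ("VAF" %in% names(inf)) vaf <- grab1(inf$VAF)
    else if ("AF" %in% names(inf)) vaf <- grab1(inf$AF)
    if ("DP" %in% names(inf)) depth <- as.integer(grab1(inf$DP))
    if (!is.null(sampleName)) {
        smp <- colnames(vcf)
        if (!sampleName %in% smp)
            stop("sample '", sampleName, "' not present in ", path,
                 " (samples: ", paste(smp, collapse = ", "), ")",
                 call. = FALSE)
        g <- geno(vcf)
        if ("AF" %in% names(g)) vaf <- grab1(g$AF[, sampleName])
        if ("DP" %in% names(g)) depth <- as.integer(grab1(g$DP[, sampleName]))
    }
    rec <- rawVariantRecords(
        contig = as.character(seqnames(rr)), position = start(rr),
        ref = as.character(ref(vcf)), alt = altL,
        vaf = vaf, depth = depth, filter = filt(vcf))
    message("read ", nrow(rec), " record(s) from VCF ", path)
    rec
}

#' Read somatic calls from a delimited report
#'
#' Vendors deliver mutation reports as delimited text as often as VCF; this
#' reader maps arbitrary column names onto the raw-record fields via a schema.
#' Positions are 1-based unless \code{schema$zeroBased} is \code{TRUE}, in
#' which case they are shifted up by one. Multiple alternate alleles may be
#' comma-separated within the alt column.
#'
#' @param path delimited text file with a header row.
#' @param schema named list mapping fields to column names: required
#'   \code{contig}, \code{position}, \code{ref}, \code{alt}; optional
#'   \code{vaf}, \code{depth}, \code{filter}; optional logical
#'   \code{zeroBased}.
#' @param sep field separator (default tab; use "," for CSV).
#' @return raw variant records.
#' @export
readTabularReport <- function(path, schema, sep = "\t") {
    if (!file.exists(path))
        stop("report file not found: ", path, call. = FALSE)
    need <- c("contig", "position", "ref", "alt")
    missing <- setdiff(need, names(schema))
    if (length(missing))
        stop("schema is missing mapping(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    tab <- read.delim(path, sep = sep, header = TRUE,
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE)
    for (f in need)
        if (!schema[[f]] %in% names(tab))
            stop("mapped column '", schema[[f]], "' (", f,
                 ") not found in ", path, call. = FALSE)
    posRaw <- trimws(tab[[schema$position]])
    pos <- suppressWarnings(as.integer(posRaw))
    bad <- which(is.na(pos) | posRaw != as.character(pos))
    if (length(bad))
        stop("non-integer position '", posRaw[bad[1]], "' in ", path,
             " at data row ", bad[1], call. = FALSE)
    if (isTRUE(schema$zeroBased))
        pos <- pos + 1L
    opt <- function(f, cast) {
        if (is.null(schema[[f]]) || !schema[[f]] %in% names(tab)) NULL
        else cast(tab[[schema[[f]]]])
    }
    rec <- rawVariantRecords(
        contig = tab[[schema$contig]], position = pos,
        ref = tab[[schema$ref]],
        alt = strsplit(toupper(tab[[schema$alt]]), ",", fixed = TRUE),
        vaf = opt("vaf", as.numeric), depth = opt("depth", as.integer),
        filter = opt("filter", as.character))
    message("read ", nrow(rec), " record(s) from report ", path)
    rec
}

## TRUE if the VCF has at least one data line (header-only files make
## readVcf stumble). Stops scanning at the first non-header line.
.vcfHasRecords <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    repeat {
        ln <- readLines(con, n = 1L)
        if (!length(ln)) return(FALSE)
        if (!startsWith(ln, "#") && nzchar(ln)) return(TRUE)
    }
}

#' Read a BED file into a RegionSet
#'
#' Reads a 3+ column BED (0-based half-open), sorts it, and merges
#' overlapping or bookended intervals. Total covered size is preserved for
#' disjoint input.
#'
#' @param path BED file path.
#' @param name label for the region set (default: file base name).
#' @param stripChr,mito contig-namespace options.
#' @return a \linkS4class{RegionSet}.
#' @export
readBed <- function(path, name = sub("\\.bed(\\.gz)?$", "", basename(path)),
                    stripChr = TRUE, mito = "MT") {
    if (!file.exists(path))
        stop("BED file not found: ", path, call. = FALSE)
    gr <- tryCatch(import(path, format = "BED"),
                   error = function(e)
                       stop("malformed BED '", path, "': ",
                            conditionMessage(e), call. = FALSE))
    rs <- RegionSet(name = name, gr = gr, stripChr = stripChr, mito = mito)
    message("read region set '", name, "': ", length(rs), " interval(s), ",
            regionSize(rs), " bp")
    rs
}

#' Write a RegionSet as BED
#'
#' @param x a \linkS4class{RegionSet}.
#' @param path output path.
#' @export
writeBed <- function(x, path) {
    stopifnot(is(x, "RegionSet"))
    export(x@regions, path, format = "BED")
    invisible(path)
}

#' Write a MutationSet as a minimal VCF 4.2 file
#'
#' Writes one coordinate-sorted data line per mutation key, carrying allele
#' fraction and depth as INFO \code{VAF}/\code{DP} (and zygosity as
#' \code{ZYG} for truth sets), and the per-key filter status in FILTER.
#' Reading the file back reproduces the same key set.
#'
#' @param x a \linkS4class{MutationSet} or \linkS4class{TruthSet}.
#' @param path output path (plain text unless it ends in .gz).
#' @return the path, invisibly.
#' @export
writeVcfCalls <- function(x, path) {
    stopifnot(is(x, "MutationSet"))
    gr <- sort(x@calls)
    n <- length(gr)
    filtv <- mcols(gr)$filter
    filtv <- ifelse(is.na(filtv) | filtv == "", ".", filtv)
    fixedDf <- DataFrame(
        REF = DNAStringSet(if (n) mcols(gr)$ref else character(0)),
        ALT = DNAStringSetList(as.list(if (n) mcols(gr)$alt else character(0))),
        QUAL = rep(NA_real_, n), FILTER = as.character(filtv))
    infoDf <- DataFrame(VAF = as.numeric(mcols(gr)$vaf),
                        DP = as.integer(mcols(gr)$depth))
    infoHdr <- DataFrame(
        Number = c("1", "1"), Type = c("Float", "Integer"),
        Description = c("Observed variant allele fraction",
                        "Read depth at site"),
        row.names = c("VAF", "DP"))
    isTruth <- is(x, "TruthSet")
    if (isTruth) {
        infoDf$ZYG <- as.character(mcols(gr)$zygosity)
        infoHdr <- rbind(infoHdr, DataFrame(
            Number = "1", Type = "String",
            Description = "Planted zygosity", row.names = "ZYG"))
    }
    keys <- GRanges(seqnames(gr), IRanges(start(gr), width = 1L))
    vcf <- VCF(rowRanges = keys, fixed = fixedDf, info = infoDf,
               collapsed = TRUE)
    hdr <- VCFHeader(samples = character(0))
    meta(hdr) <- DataFrameList(
        fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
    info(hdr) <- infoHdr
    header(vcf) <- hdr
    writeVcf(vcf, path)
    invisible(path)
}

#' Read a truth VCF (expected mutations with zygosity)
#'
#' Companion to \code{\link{writeVcfCalls}} for truth sets: zygosity is taken
#' from the INFO \code{ZYG} field, defaulting to heterozygous when absent.
#'
#' @param path truth VCF path.
#' @param sample sample label for the resulting set.
#' @return a \linkS4class{TruthSet}.
#' @export
readTruthVcf <- function(path, sample = "truth") {
    vcf <- tryCatch(suppressWarnings(readVcf(path, genome = "unknown")),
                    error = function(e)
                        stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    rr <- rowRanges(vcf)
    altL <- CharacterList(lapply(as.list(alt(vcf)), as.character))
    if (any(lengths(altL) != 1L))
        stop("truth VCF must have one alternate allele per line", call. = FALSE)
    zyg <- if ("ZYG" %in% names(info(vcf))) as.character(info(vcf)$ZYG)
           else rep("heterozygous", length(rr))
    TruthSet(sample = sample,
             contig = normalizeContigs(as.character(seqnames(rr))),
             position = start(rr), ref = as.character(ref(vcf)),
             alt = unlist(altL, use.names = FALSE), zygosity = zyg)
}
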