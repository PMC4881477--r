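#' @import methods
#' @importFrom stats rbinom rnbinom rpois runif setNames dbinom pbinom dnbinom
#' @importFrom utils read.delim write.table combn
NULL

## Numeric guard used wherever an observed allele fraction is compared with a
## threshold: 0.05 * 100 is not exactly 5 in binary floating point.
.EPS <- 1e-9

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; published tables in this field are
#' rounded half-up (e.g. 88.505 prints as 88.51), so percentage display uses
#' this helper throughout.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to \code{digits} places.
#' @export
#' @examples
#' roundHalfUp(88.505, 2)
#' roundHalfUp(79.775, 0)
roundHalfUp <- function(x, digits = 0) {
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5 + .EPS) / m
}

#' Normalize contig labels to one namespace
#'
#' Vendors disagree on chromosome naming ("chr1" vs "1", "M" vs "MT"); every
#' reader funnels contig labels through this function so that downstream key
#' comparison happens in a single namespace.
#'
#' @param x character vector of contig labels.
#' @param stripChr drop a leading "chr" prefix.
#' @param mito label to which both "M" and "MT" are unified.
#' @return character vector of normalized labels.
#' @export
#' @examples
#' normalizeContigs(c("chr1", "2", "chrM", "MT"))
normalizeContigs <- function(x, stripChr = TRUE, mito = "MT") {
    x <- as.character(x)
    if (stripChr)
        x <- sub("^chr", "", x)
    x[x %in% c("M", "MT")] <- mito
    x
}

## Detect mixed contig conventions between two label vectors: comparing sets
## that disagree on "chr" prefixing silently yields empty intersections, so it
## is an error instead.
.checkNamespace <- function(a, b) {
    chrA <- any(grepl("^chr", a))
    chrB <- any(grepl("^chr", b))
    if (length(a) && length(b) && chrA != chrB)
        stop("mutation sets use mixed contig conventions ",
             "('chr' prefix present in one but not the other); ",
             "normalize contigs before comparing", call. = FALSE)
    invisible(TRUE)
}

.isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

.validAllele <- function(x) grepl("^[ACGTN]+$", x)

## Format a percentage the way the published tables print it: two decimals,
## trailing zeros (and a trailing dot) trimmed, so 89.00 -> "89", 85.00 -> "85"
## and 88.52 stays "88.52".
.formatPct <- function(x) {
    ifelse(is.na(x), "N.A.",
           sub("\\.?0+$", "", sprintf("%.2f", roundHalfUp(x, 2))))
}
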