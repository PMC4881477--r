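#' Published multi-laboratory replicate counts
#'
#' Per-laboratory, per-sample replicate mutation counts from a published
#' five-laboratory whole-exome comparison of three tumor/normal pairs:
#' reported counts of the two replicates, their overlap and the printed
#' concordance, both for the laboratories' self-reported calls
#' (\code{vendor_*}) and for the re-analysis of all laboratories' raw data
#' under one pipeline restricted to a common gene panel (\code{unified_*}).
#' Single-replicate entries carry \code{NA}. These printed counts are the
#' reference against which the concordance formula is validated.
#'
#' @return data.frame with one row per laboratory and sample.
#' @export
#' @examples
#' head(interlabCounts())
interlabCounts <- function() {
    read.delim(system.file("extdata", "interlab_replicate_counts.tsv",
                           package = "SomaticConcord"),
               sep = "\t", stringsAsFactors = FALSE)
}

#' Published truth-set sensitivity counts
#'
#' Per-replicate totals and detected-in-truth counts for the cell-line
#' mixture sample of the same five-laboratory comparison: each laboratory's
#' total reported SNVs and how many of the 178 expected hotspot mutations it
#' recovered, with the printed (nearest-integer) sensitivity percentage.
#'
#' @return data.frame with one row per laboratory replicate.
#' @export
cosmicMixSensitivity <- function() {
    read.delim(system.file("extdata", "cosmic_mix_sensitivity.tsv",
                           package = "SomaticConcord"),
               sep = "\t", stringsAsFactors = FALSE)
}
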