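#' @importFrom tools md5sum
#' @importFrom jsonlite write_json
NULL

## Read one replicate's raw records, dispatching on configured format.
.readReplicate <- function(path, lab, schemas) {
    if (lab %in% names(schemas))
        readTabularReport(path, schemas[[lab]],
                          sep = schemas[[lab]]$sep %||% "\t")
    else
        readVcfCalls(path)
}

#' Run the full two-level study analysis
#'
#' The complete pipeline over a study's call files, performing the comparison
#' at two levels: (1) \emph{vendor space} — each laboratory's reported calls
#' as delivered (PASS records only unless \code{includeFiltered}); (2)
#' \emph{unified space} — all candidate records re-thresholded under one
#' harmonized cutoff and restricted to the common panel, so every laboratory
#' is judged on the same regions under the same rules. For each laboratory
#' and sample it computes replicate concordance in both spaces, truth-set
#' sensitivity where a truth file is configured, cross-laboratory overlap
#' partitions, per-megabase burden (capture-based in vendor space where
#' capture BEDs are configured, panel-based in unified space) and the fold
#' range of reported counts.
#'
#' Outputs written to \code{outputDir}: \code{concordance_table.tsv} (lab,
#' sample, then vendor-space and unified replicate counts, overlap and
#' concordance — the layout of a published replicate table),
#' \code{sensitivity_table.tsv}, \code{burden_table.tsv} and a structured
#' \code{results.json} (schema version, all results, provenance with input
#' file md5 checksums). Reruns on identical inputs produce byte-identical
#' structured results.
#'
#' @param config a \linkS4class{StudyConfig} or path to a study YAML.
#' @param outputDir directory for result files (created; \code{NULL} skips
#'   writing).
#' @param includeFiltered include non-PASS records in vendor space.
#' @param harmonizedThresholds \linkS4class{CallerThresholds} applied to all
#'   laboratories in unified space.
#' @param panelPath optional override of the config's panel BED.
#' @param truthPaths optional override of the config's truth files (named by
#'   sample).
#' @return a \linkS4class{StudyResult}.
#' @export
runStudy <- function(config, outputDir = NULL, includeFiltered = FALSE,
                     harmonizedThresholds = CallerThresholds(0.10, 4, 14),
                     panelPath = NULL, truthPaths = NULL) {
    if (is.character(config)) config <- readStudyConfig(config)
    stopifnot(is(config, "StudyConfig"))
    base <- config@baseDir

    pPath <- panelPath %||%
        (if (!is.na(config@panelPath)) .resolvePath(config@panelPath, base)
         else NULL)
    panel <- if (!is.null(pPath)) readBed(pPath, name = "panel") else NULL

    tPaths <- truthPaths %||% .resolvePath(config@truthPaths, base)
    truths <- lapply(setNames(nm = names(tPaths)), function(s)
        readTruthVcf(tPaths[[s]], sample = s))

    captures <- lapply(setNames(nm = names(config@capturePaths)), function(l)
        readBed(.resolvePath(config@capturePaths[[l]], base),
                name = paste0(l, "_capture")))

    missing <- config@files$path[
        !file.exists(.resolvePath(config@files$path, base))]
    if (length(missing))
        stop("missing call file(s):\n  ", paste(missing, collapse = "\n  "),
             call. = FALSE)

    ## read every replicate once; derive the two comparison spaces
    vendor <- list(); unified <- list()
    for (i in seq_len(nrow(config@files))) {
        row <- config@files[i, ]
        rec <- .readReplicate(.resolvePath(row$path, base), row$lab,
                              config@tabularSchemas)
        id <- paste(row$lab, row$sample, row$replicate, sep = "|")
        vendor[[id]] <- buildMutationSet(
            rec, lab = row$lab, sample = row$sample,
            replicate = row$replicate, includeFiltered = includeFiltered)
        u <- buildMutationSet(rec, lab = row$lab, sample = row$sample,
                              replicate = row$replicate,
                              includeFiltered = TRUE)
        u <- applyThresholds(u, harmonizedThresholds)
        if (!is.null(panel)) u <- restrictCalls(u, panel)
        unified[[id]] <- u
        message("replicate ", id, ": vendor ", length(vendor[[id]]),
                " key(s), unified ", length(u), " key(s)")
    }

    sets <- function(space, labWanted, smp) {
        sel <- config@files$lab == labWanted & config@files$sample == smp
        ids <- paste(config@files$lab, config@files$sample,
                     config@files$replicate, sep = "|")[sel]
        space[ids]
    }

    ## concordance table, both spaces
    concRows <- list()
    for (smp in config@samples)
        for (lab in config@labs) {
            v <- sets(vendor, lab, smp)
            if (!length(v)) next
            u <- sets(unified, lab, smp)
            cv <- replicateConcordance(v[[1]], if (length(v) > 1) v[[2]])
            cu <- replicateConcordance(u[[1]], if (length(u) > 1) u[[2]])
            concRows[[length(concRows) + 1L]] <- data.frame(
                lab = lab, sample = smp,
                vendor_rep1 = cv@n1, vendor_rep2 = cv@n2,
                vendor_overlap = cv@nOverlap,
                vendor_concordance = cv@pct,
                unified_rep1 = cu@n1, unified_rep2 = cu@n2,
                unified_overlap = cu@nOverlap,
                unified_concordance = cu@pct, stringsAsFactors = FALSE)
        }
    concordance <- do.call(rbind, concRows)

    ## truth sensitivity (vendor space, per replicate)
    sensRows <- list()
    for (smp in intersect(names(truths), config@samples))
        for (lab in config@labs) {
            v <- sets(vendor, lab, smp)
            for (ms in v) {
                sr <- truthSensitivity(ms, truths[[smp]])
                sensRows[[length(sensRows) + 1L]] <- data.frame(
                    lab = lab, sample = smp, replicate = replicateName(ms),
                    total_calls = length(ms), n_expected = sr@nExpected,
                    n_detected = sr@nDetected,
                    sensitivity_pct = sensitivityPct(sr, display = TRUE),
                    stringsAsFactors = FALSE)
            }
        }
    sensitivity <- if (length(sensRows)) do.call(rbind, sensRows)
        else data.frame()

    ## cross-laboratory overlap partitions (first replicate of each lab)
    overlaps <- list()
    for (smp in config@samples) {
        firsts <- function(space) {
            out <- list()
            for (lab in config@labs) {
                s <- sets(space, lab, smp)
                if (length(s)) out[[lab]] <- s[[1]]
            }
            out
        }
        fv <- firsts(vendor)
        if (length(fv) >= 2)
            overlaps[[smp]] <- list(
                vendor = overlapSummary(fv, labels = names(fv)),
                unified = overlapSummary(firsts(unified),
                                         labels = names(fv)))
    }

    ## burden: capture-based in vendor space, panel-based in unified space
    burdenRows <- list()
    for (i in seq_len(nrow(config@files))) {
        row <- config@files[i, ]
        id <- paste(row$lab, row$sample, row$replicate, sep = "|")
        cap <- captures[[row$lab]]
        bv <- if (!is.null(cap))
            suppressMessages(mutationalBurden(vendor[[id]], cap))
        bu <- if (!is.null(panel))
            suppressMessages(mutationalBurden(unified[[id]], panel))
        burdenRows[[length(burdenRows) + 1L]] <- data.frame(
            lab = row$lab, sample = row$sample, replicate = row$replicate,
            vendor_n = length(vendor[[id]]),
            vendor_mb = if (is.null(bv)) NA_real_ else bv@regionMb,
            vendor_burden = if (is.null(bv)) NA_real_ else bv@burden,
            unified_n = length(unified[[id]]),
            unified_mb = if (is.null(bu)) NA_real_ else bu@regionMb,
            unified_burden = if (is.null(bu)) NA_real_ else bu@burden,
            stringsAsFactors = FALSE)
    }
    burden <- do.call(rbind, burdenRows)

    allPaths <- .resolvePath(
        c(config@files$path, unname(config@truthPaths),
          unname(config@capturePaths),
          if (!is.na(config@panelPath)) config@panelPath), base)
    provenance <- list(
        schema_version = "1.0",
        parameters = list(
            include_filtered = includeFiltered,
            harmonized_min_vaf = harmonizedThresholds@minVaf,
            harmonized_min_alt_reads = harmonizedThresholds@minAltReads,
            harmonized_min_depth = harmonizedThresholds@minDepth),
        input_md5 = as.list(setNames(unname(md5sum(allPaths)),
                                     basename(allPaths))))

    result <- new("StudyResult", concordance = concordance,
                  sensitivity = sensitivity, overlaps = overlaps,
                  burden = burden, provenance = provenance)
    if (!is.null(outputDir)) writeStudyResult(result, outputDir)
    result
}

#' Write study result tables and structured output
#'
#' @param result a \linkS4class{StudyResult}.
#' @param outputDir output directory.
#' @return paths of the written files, invisibly.
#' @export
writeStudyResult <- function(result, outputDir) {
    stopifnot(is(result, "StudyResult"))
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    fmt <- function(df) {
        for (cl in grep("concordance", names(df), value = TRUE))
            df[[cl]] <- .formatPct(df[[cl]])
        df[is.na(df)] <- "N.A."
        df
    }
    paths <- file.path(outputDir, c("concordance_table.tsv",
                                    "sensitivity_table.tsv",
                                    "burden_table.tsv", "results.json"))
    write.table(fmt(result@concordance), paths[1], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(result@sensitivity, paths[2], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(result@burden, paths[3], sep = "\t", quote = FALSE,
                row.names = FALSE)
    ov <- lapply(result@overlaps, function(x) lapply(x, function(o) list(
        labels = o@labels, counts = o@counts,
        pairwise = o@pairwise, shared_by_all = o@sharedByAll,
        private = o@private)))
    write_json(list(schema_version = result@provenance$schema_version,
                    parameters = result@provenance$parameters,
                    concordance = result@concordance,
                    sensitivity = result@sensitivity,
                    burden = result@burden, overlaps = ov,
                    input_md5 = result@provenance$input_md5),
               paths[4], auto_unbox = TRUE, digits = NA, pretty = TRUE,
               na = "null")
    invisible(paths)
}

#' Re-read a written concordance table
#'
#' Parses \code{concordance_table.tsv} back into the numeric form used in a
#' \linkS4class{StudyResult}, so written tables round-trip losslessly.
#'
#' @param path path to a written concordance table.
#' @return data.frame matching the \code{concordance} slot.
#' @export
readConcordanceTable <- function(path) {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     na.strings = "N.A.")
    for (cl in setdiff(names(df), c("lab", "sample")))
        df[[cl]] <- as.numeric(df[[cl]])
    for (cl in grep("rep|overlap", names(df), value = TRUE))
        df[[cl]] <- as.integer(df[[cl]])
    df
}

#' Vendor-space versus unified-analysis cross-laboratory agreement
#'
#' Simulates one replicate per laboratory under a cohort configuration and
#' measures the median pairwise cross-laboratory concordance twice: in
#' \emph{vendor space} (each lab's own thresholds, own capture) and in
#' \emph{unified space} (all candidate calls re-thresholded under one
#' harmonized cutoff and restricted to the common panel). Heterogeneous
#' captures, thresholds and artifact rates depress vendor-space agreement;
#' harmonization removes those factors, which is the qualitative headline a
#' multi-laboratory comparison is expected to show.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param harmonizedThresholds \linkS4class{CallerThresholds} for the
#'   unified space.
#' @return list with elements \code{vendor} and \code{unified}: median
#'   off-diagonal pairwise concordance percentages.
#' @export
vendorUnifiedContrast <- function(config,
                                  harmonizedThresholds =
                                      CallerThresholds(0.10, 4, 14)) {
    stopifnot(is(config, "CohortConfig"))
    truth <- simulateTruth(config)
    germ <- simulateGermlinePool(config)
    vendorSets <- list(); unifiedSets <- list()
    for (p in config@labs) {
        seed <- config@masterSeed + p@seedOffset + 1L
        cand <- simulateLabReplicate(truth, p, config@purity, seed,
                                     germline = germ, keepRejected = TRUE)
        vendorSets[[p@label]] <- passedCalls(cand)
        u <- applyThresholds(cand, harmonizedThresholds)
        unifiedSets[[p@label]] <- restrictCalls(u, config@panel)
    }
    off <- function(m) m[upper.tri(m)]
    list(vendor = stats::median(off(pairwiseConcordance(
             vendorSets, labels = names(vendorSets)))),
         unified = stats::median(off(pairwiseConcordance(
             unifiedSets, labels = names(unifiedSets)))))
}

setMethod("show", "StudyResult", function(object) {
    cat("StudyResult: ", nrow(object@concordance),
        " lab/sample concordance row(s), ", nrow(object@sensitivity),
        " sensitivity row(s), ", length(object@overlaps),
        " overlap summary set(s)\n", sep = "")
})
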