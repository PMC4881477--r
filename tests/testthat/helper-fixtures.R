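## Shared fixture builders. Everything is generated in code; nothing binary.

## A MutationSet of n distinct SNVs at deterministic positions on one contig.
makeKeySet <- function(n, contig = "1", offset = 0L, lab = "LabX",
                       sample = "S", replicate = "1", ...) {
    if (n == 0)
        return(MutationSet(lab, sample, replicate))
    MutationSet(lab, sample, replicate, contig = contig,
                position = offset + seq_len(n) * 10L,
                ref = rep("A", n), alt = rep("T", n), ...)
}

## Two sets of sizes n1 and n2 sharing exactly nOverlap keys.
makeSetPair <- function(n1, n2, nOverlap, lab = "LabX", sample = "S") {
    shared <- seq_len(nOverlap) * 10L
    only1 <- 1000000L + seq_len(n1 - nOverlap) * 10L
    only2 <- 2000000L + seq_len(n2 - nOverlap) * 10L
    a <- MutationSet(lab, sample, "1", contig = "1",
                     position = c(shared, only1),
                     ref = "A", alt = "T")
    b <- MutationSet(lab, sample, "2", contig = "1",
                     position = c(shared, only2),
                     ref = "A", alt = "T")
    list(a = a, b = b)
}

## Minimal handwritten VCF with nPass PASS lines and nFail filtered lines.
writeTinyVcf <- function(path, nPass = 5, nFail = 2) {
    pos <- seq_len(nPass + nFail) * 100L
    filt <- c(rep("PASS", nPass), rep("low_qual", nFail))
    lines <- c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("chr1\t%d\t.\tA\tT\t.\t%s\tDP=%d", pos, filt,
                       50L + pos %% 7L))
    writeLines(lines, path)
    path
}

## Random keys (possibly indels with redundant padding) for normalization
## property tests. Returns a raw-record DataFrame.
randomRawRecords <- function(n, seed) {
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    contig <- sample(c("chr1", "chr2"), n, replace = TRUE)
    position <- sample.int(100000L, n)
    core_ref <- replicate(n, paste(sample(bases, sample(1:3, 1),
                                          replace = TRUE), collapse = ""))
    core_alt <- vapply(core_ref, function(r) {
        repeat {
            a <- paste(sample(bases, sample(1:3, 1), replace = TRUE),
                       collapse = "")
            if (a != r) return(a)
        }
    }, character(1), USE.NAMES = FALSE)
    pad <- replicate(n, paste(sample(bases, sample(0:2, 1), replace = TRUE),
                              collapse = ""))
    rawVariantRecords(contig = contig, position = position,
                      ref = paste0(core_ref, pad),
                      alt = as.list(paste0(core_alt, pad)))
}

## Per-base boolean occupancy oracle for region sets on a small toy contig.
occupancyVector <- function(regionSet, contig, len) {
    occ <- logical(len)
    gr <- regions(regionSet)
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == contig]
    for (i in seq_along(gr)) {
        s <- GenomicRanges::start(gr)[i]
        e <- min(GenomicRanges::end(gr)[i], len)
        if (s <= len) occ[s:e] <- TRUE
    }
    occ
}

## A small two-lab, one-sample cohort for fast end-to-end tests.
miniCohort <- function(masterSeed = 7L, nTruth = 120L) {
    genome <- toyGenome("1", 1e6)
    panel <- RegionSet("panel", contig = "1", start = 0, end = 6e5)
    capA <- RegionSet("capA", contig = "1", start = 0, end = 8e5)
    capB <- RegionSet("capB", contig = "1", start = 0, end = 7e5)
    labs <- list(
        LabProfile("LabA", capA, meanDepth = 120, depthDispersion = 8,
                   thresholds = CallerThresholds(0.08, 4, 12),
                   fpRate = 5, germlineLeakRate = 0.01, seedOffset = 100L),
        LabProfile("LabB", capB, meanDepth = 90, depthDispersion = 6,
                   thresholds = CallerThresholds(0.04, 3, 8),
                   fpRate = 15, germlineLeakRate = 0.03, seedOffset = 200L))
    CohortConfig("S1", genome, panel, nTruthMutations = nTruth,
                 hetFraction = 0.7, purity = 0.4, labs = labs,
                 replicates = c(LabA = 2L, LabB = 1L), nGermline = 100L,
                 masterSeed = masterSeed)
}
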