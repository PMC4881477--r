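test_that("normalization implements coordinate-plus-base-change identity", {
    ## SNV passthrough with chr stripped
    k <- normalizeCalls(rawVariantRecords("chr1", 100L, "A", list("T")))
    expect_equal(as.data.frame(k)[, 1:4],
                 data.frame(contig = "1", position = 100L,
                            ref = "A", alt = "T"))
    ## shared-prefix trim advances the position
    k <- normalizeCalls(rawVariantRecords("1", 100L, "CT", list("CA")))
    expect_equal(k$position, 101L)
    expect_equal(k$ref, "T"); expect_equal(k$alt, "A")
    ## shared-suffix trim comes first
    k <- normalizeCalls(rawVariantRecords("1", 100L, "TAC", list("GC")))
    expect_equal(k$position, 100L)
    expect_equal(k$ref, "TA"); expect_equal(k$alt, "G")
    ## anchored deletion is already canonical; a padded equivalent converges
    k <- normalizeCalls(rawVariantRecords("1", 100L, "ATT", list("A")))
    expect_equal(k$position, 100L)
    expect_equal(k$ref, "ATT"); expect_equal(k$alt, "A")
    k2 <- normalizeCalls(rawVariantRecords("1", 100L, "ATTT", list("AT")))
    expect_equal(as.data.frame(k2)[, 1:4], as.data.frame(k)[, 1:4])
    ## multi-allelic split
    k <- normalizeCalls(rawVariantRecords("1", 100L, "A", list(c("T", "G"))))
    expect_equal(nrow(k), 2L)
    expect_setequal(k$alt, c("T", "G"))
    ## degenerate record
    expect_error(normalizeCalls(rawVariantRecords("1", 100L, "CA",
                                                  list("CA"))),
                 "degenerate")
    ## lower-case input uppercased, case-insensitive identity
    k <- normalizeCalls(rawVariantRecords("1", 100L, "a", list("t")))
    expect_equal(k$ref, "A")
})

test_that("normalization is idempotent over random padded records", {
    rec <- randomRawRecords(200, seed = 5)
    k1 <- normalizeCalls(rec)
    rec2 <- rawVariantRecords(contig = k1$contig, position = k1$position,
                              ref = k1$ref, alt = as.list(k1$alt))
    k2 <- normalizeCalls(rec2)
    expect_equal(as.data.frame(k1[, 1:4]), as.data.frame(k2[, 1:4]))
})

test_that("building a set de-duplicates keys and respects the filter switch", {
    rec <- rawVariantRecords(contig = rep("1", 2), position = c(100L, 100L),
                             ref = "A", alt = list("T", "T"),
                             depth = c(30L, 90L))
    ms <- suppressMessages(buildMutationSet(rec, "LabA", "S1", "1"))
    expect_equal(length(ms), 1L)
    expect_equal(callData(ms)$depth, 90L)  # max-depth annotation kept

    recs <- rawVariantRecords(
        contig = "1", position = seq_len(10) * 10L, ref = "A",
        alt = as.list(rep("T", 10)),
        filter = c(rep("PASS", 8), "low_qual", "artifact"))
    msOn <- suppressMessages(buildMutationSet(recs, includeFiltered = TRUE))
    msOff <- suppressMessages(buildMutationSet(recs, includeFiltered = FALSE))
    expect_equal(length(msOn), 10L)
    expect_equal(length(msOff), 8L)

    ## a 200-SNV report yields a 200-key set
    big <- rawVariantRecords(contig = "1", position = seq_len(200) * 7L,
                             ref = "C", alt = as.list(rep("A", 200)))
    expect_equal(length(suppressMessages(buildMutationSet(big))), 200L)
})

test_that("key equality is exact (no fuzzy position window)", {
    a <- MutationSet("L", "S", "1", contig = "1", position = 100L,
                     ref = "A", alt = "T")
    b <- MutationSet("L", "S", "2", contig = "1", position = 101L,
                     ref = "A", alt = "T")
    d <- MutationSet("L", "S", "2", contig = "1", position = 100L,
                     ref = "A", alt = "G")
    expect_length(keyIntersection(a, b), 0L)
    expect_length(keyIntersection(a, d), 0L)
    expect_length(keyIntersection(a, a), 1L)
})

test_that("set operations match a brute-force membership oracle", {
    set.seed(17)
    core <- seq_len(60) * 100L                      # 60-key planted core
    mk <- function(extraOffset) {
        MutationSet("L", "S", "1", contig = "1",
                    position = c(core, extraOffset + seq_len(40) * 100L),
                    ref = "A", alt = "T")
    }
    sets <- list(mk(100000L), mk(200000L), mk(300000L))
    keys <- lapply(sets, mutationKeys)
    ## brute-force membership matrix over the union
    uni <- unique(unlist(keys))
    memb <- vapply(keys, function(k) uni %in% k, logical(length(uni)))
    expect_equal(length(keyIntersection(sets[[1]], sets[[2]])),
                 sum(memb[, 1] & memb[, 2]))
    expect_equal(length(privateKeys(sets[[1]], sets[-1])),
                 sum(memb[, 1] & !memb[, 2] & !memb[, 3]))
    ## partition identity: private + shared-with->=1 == total
    for (i in 1:3)
        expect_equal(length(privateKeys(sets[[i]], sets[-i])) +
                     sum(memb[, i] & rowSums(memb[, -i, drop = FALSE]) > 0),
                     length(sets[[i]]))
    ## trivial cases
    expect_length(privateKeys(sets[[1]], sets[1]), 0L)
    disjoint <- MutationSet("L", "S", "1", contig = "2",
                            position = seq_len(10) * 5L, ref = "C",
                            alt = "G")
    expect_setequal(privateKeys(disjoint, sets), mutationKeys(disjoint))
})

test_that("mixed contig conventions are refused", {
    a <- MutationSet("L", "S", "1", contig = "1", position = 1L,
                     ref = "A", alt = "T")
    b <- new("MutationSet", lab = "L", sample = "S", replicate = "2",
             calls = {
                 gr <- GenomicRanges::GRanges("chr1",
                                              IRanges::IRanges(1, 1))
                 S4Vectors::mcols(gr)$ref <- "A"
                 S4Vectors::mcols(gr)$alt <- "T"
                 S4Vectors::mcols(gr)$vaf <- NA_real_
                 S4Vectors::mcols(gr)$depth <- NA_integer_
                 S4Vectors::mcols(gr)$filter <- NA_character_
                 gr
             })
    expect_error(keyIntersection(a, b), "mixed contig conventions")
})

test_that("thresholds re-apply to stored vaf/depth annotations", {
    ms <- MutationSet("L", "S", "1", contig = "1",
                      position = c(10L, 20L, 30L, 40L),
                      ref = "A", alt = "T",
                      vaf = c(0.20, 0.05, 0.20, NA),
                      depth = c(100L, 100L, 8L, NA))
    out <- applyThresholds(ms, CallerThresholds(0.10, 4, 10))
    ## keeps: high-vaf deep call; NA-annotated call; drops low vaf and shallow
    expect_setequal(callData(out)$position, c(10L, 40L))
})

test_that("passedCalls subsets by filter status", {
    ms <- MutationSet("L", "S", "1", contig = "1", position = c(10L, 20L),
                      ref = "A", alt = "T",
                      filter = c("PASS", "low_confidence"))
    expect_equal(length(passedCalls(ms)), 1L)
})
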