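test_that("replicate concordance implements the shared/mean formula", {
    pair <- makeSetPair(519, 553, 391)
    r <- suppressWarnings(replicateConcordance(pair$a, pair$b))
    expect_equal(concordancePct(r), 72.95)
    expect_equal(r@n1, 519L); expect_equal(r@n2, 553L)
    expect_equal(r@nOverlap, 391L)
    ## symmetric
    expect_equal(concordancePct(replicateConcordance(pair$b, pair$a)), 72.95)
    ## identity and empty cases
    a <- makeKeySet(20)
    expect_equal(concordancePct(replicateConcordance(a, a)), 100)
    empty <- makeKeySet(0)
    expect_equal(concordancePct(replicateConcordance(a, empty)), 0)
    both <- replicateConcordance(empty, empty)
    expect_true(is.na(concordancePct(both)))
    expect_equal(both@status, "undefined")
    ## single replicate: explicit not-available, never zero
    na <- replicateConcordance(a, NULL)
    expect_true(is.na(concordancePct(na)))
    expect_equal(na@status, "undefined")
    ## label mismatch warns but computes
    b <- makeKeySet(20, lab = "LabY")
    expect_warning(replicateConcordance(a, b), "different lab")
})

test_that("concordance equals the Dice coefficient on random sets", {
    set.seed(51)
    for (i in 1:20) {
        n1 <- sample(5:300, 1); n2 <- sample(5:300, 1)
        ov <- sample.int(min(n1, n2), 1)
        pair <- makeSetPair(n1, n2, ov)
        ## independent Dice implementation on the raw key vectors
        A <- mutationKeys(pair$a); B <- mutationKeys(pair$b)
        dice <- 100 * 2 * length(intersect(A, B)) / (length(A) + length(B))
        expect_equal(concordancePct(replicateConcordance(pair$a, pair$b)),
                     roundHalfUp(dice, 2))
    }
})

test_that("concordance is monotone in shared and private additions", {
    base <- makeSetPair(50, 60, 30)
    c0 <- concordancePct(replicateConcordance(base$a, base$b))
    ## add one shared key to both
    shared <- MutationSet("LabX", "S", "1", contig = "9", position = 5L,
                          ref = "A", alt = "T")
    addKey <- function(ms, other, repl) {
        cd <- callData(ms)
        MutationSet("LabX", "S", repl,
                    contig = c(cd$contig, callData(other)$contig),
                    position = c(cd$position, callData(other)$position),
                    ref = c(cd$ref, callData(other)$ref),
                    alt = c(cd$alt, callData(other)$alt))
    }
    aS <- addKey(base$a, shared, "1"); bS <- addKey(base$b, shared, "2")
    expect_gte(concordancePct(replicateConcordance(aS, bS)), c0)
    ## add one private key to a only
    priv <- MutationSet("LabX", "S", "1", contig = "9", position = 7L,
                        ref = "C", alt = "G")
    aP <- addKey(base$a, priv, "1")
    expect_lte(concordancePct(replicateConcordance(aP, base$b)), c0)
})

test_that("count-based concordance rejects impossible overlaps", {
    expect_error(concordanceFromCounts(10, 10, 11))
    expect_true(is.na(concordanceFromCounts(0, 0, 0)))
})

test_that("truth sensitivity counts detected-in-truth keys with display rounding", {
    truth <- TruthSet(sample = "S1", contig = "1",
                      position = seq_len(178) * 10L, ref = "A", alt = "T",
                      zygosity = rep("heterozygous", 178))
    mkCalls <- function(nDet, nExtra) {
        MutationSet("LabB", "S1", "1", contig = "1",
                    position = c(seq_len(nDet) * 10L,
                                 500000L + seq_len(nExtra) * 10L),
                    ref = "A", alt = "T")
    }
    r <- truthSensitivity(mkCalls(142, 58), truth)
    expect_equal(r@nDetected, 142L)
    expect_equal(sensitivityPct(r, display = TRUE), 80)    # 79.78 -> 80
    expect_equal(sensitivityPct(r), 100 * 142 / 178)
    expect_equal(sensitivityPct(truthSensitivity(mkCalls(161, 0), truth),
                                display = TRUE), 90)
    ## calls == truth gives 100%
    all <- mkCalls(178, 0)
    expect_equal(sensitivityPct(truthSensitivity(all, truth)), 100)
    ## empty truth is undefined
    et <- TruthSet(sample = "S1")
    expect_equal(truthSensitivity(all, et)@status, "undefined")
    ## precision extension
    p <- callPrecision(mkCalls(100, 100), truth)
    expect_equal(p$precisionPct, 50)
})

test_that("overlap summary partitions are internally consistent", {
    a <- makeKeySet(30, lab = "LabA")
    expect_error(overlapSummary(list(a)), "at least two")
    ## identical sets: no private keys, shared == total
    s <- overlapSummary(list(a, makeKeySet(30, lab = "LabB")))
    expect_equal(s@private, c(0L, 0L))
    expect_equal(s@sharedByAll, 30L)
    ## disjoint sets: all private, nothing shared
    d <- overlapSummary(list(makeKeySet(10, lab = "LabA"),
                             makeKeySet(12, offset = 10000L, lab = "LabB"),
                             makeKeySet(14, offset = 20000L, lab = "LabC")))
    expect_equal(d@sharedByAll, 0L)
    expect_equal(d@private, d@counts)
    ## planted 60-key core among three 100-key sets, vs exhaustive oracle
    core <- seq_len(60) * 10L
    mk <- function(off, lab) MutationSet(lab, "S", "1", contig = "1",
        position = c(core, off + seq_len(40) * 10L), ref = "A", alt = "T")
    sets <- list(mk(100000L, "LabA"), mk(200000L, "LabB"),
                 mk(300000L, "LabC"))
    o <- overlapSummary(sets)
    keys <- lapply(sets, mutationKeys)
    uni <- unique(unlist(keys))
    memb <- vapply(keys, function(k) uni %in% k, logical(length(uni)))
    expect_equal(o@sharedByAll, sum(rowSums(memb) == 3))
    for (i in 1:3) {
        expect_equal(o@private[i], sum(memb[, i] & rowSums(memb) == 1))
        for (j in 1:3)
            expect_equal(o@pairwise[i, j], sum(memb[, i] & memb[, j]))
    }
})

test_that("mutational burden normalizes by region megabases", {
    rs <- RegionSet("r", contig = "1", start = 0, end = 1e6)
    calls <- MutationSet("L", "S", "1", contig = "1",
                         position = seq_len(100) * 100L, ref = "A",
                         alt = "T")
    b <- mutationalBurden(calls, rs)
    expect_equal(b@burden, 100)
    expect_equal(mutationalBurden(makeKeySet(0), rs)@burden, 0)
    expect_true(is.na(mutationalBurden(makeKeySet(0),
                                       RegionSet("empty"))@burden))
    ## calls outside the region are dropped (with a message) first
    wide <- MutationSet("L", "S", "1", contig = "1",
                        position = c(100L, 2e6L), ref = "A", alt = "T")
    expect_message(b2 <- mutationalBurden(wide, rs), "outside")
    expect_equal(b2@nMutations, 1L)
    ## a planted density is recovered: 250 mutations over 0.5 Mb
    rs2 <- RegionSet("r2", contig = "1", start = 0, end = 5e5)
    dens <- MutationSet("L", "S", "1", contig = "1",
                        position = seq_len(250) * 1000L, ref = "C",
                        alt = "G")
    expect_equal(mutationalBurden(dens, rs2)@burden, 500)
})

test_that("fold range summarizes count spread", {
    expect_equal(foldRange(c(200, 200)), 1.0)
    expect_equal(foldRange(c(10, 20, 40)), 4.0)
    expect_equal(roundHalfUp(foldRange(c(336, 23410)), 1), 69.7)
    expect_error(foldRange(c(0, 5)), "positive")
    expect_error(foldRange(numeric(0)), "positive")
})

test_that("percentages format the way published tables print them", {
    expect_equal(SomaticConcord:::.formatPct(89.00), "89")
    expect_equal(SomaticConcord:::.formatPct(88.515), "88.52")
    expect_equal(SomaticConcord:::.formatPct(85.002), "85")
    expect_equal(SomaticConcord:::.formatPct(NA_real_), "N.A.")
})
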