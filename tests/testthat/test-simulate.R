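test_that("planted truth sets are uniform, unique and seed-deterministic", {
    cfg <- miniCohort(masterSeed = 9L, nTruth = 178L)
    t1 <- simulateTruth(cfg)
    expect_s4_class(t1, "TruthSet")
    expect_equal(length(t1), 178L)
    expect_equal(anyDuplicated(mutationKeys(t1)), 0L)
    expect_true(all(callData(t1)$zygosity %in%
                    c("heterozygous", "homozygous")))
    ## same seed: identical; different seed: different with high probability
    expect_identical(mutationKeys(simulateTruth(cfg)), mutationKeys(t1))
    cfg2 <- miniCohort(masterSeed = 10L, nTruth = 178L)
    expect_false(setequal(mutationKeys(simulateTruth(cfg2)),
                          mutationKeys(t1)))
    ## empty truth
    expect_equal(length(simulateTruth(miniCohort(nTruth = 0L))), 0L)
    ## capacity error
    tiny <- CohortConfig("S", toyGenome("1", 100), RegionSet("p"),
                         nTruthMutations = 90L, labs = list(),
                         nGermline = 0L, replicates = integer(0))
    expect_error(validObject(CohortConfig("S", toyGenome("1", 100),
                                          RegionSet("p"),
                                          nTruthMutations = 200L,
                                          labs = list(), nGermline = 0L,
                                          replicates = integer(0))),
                 "genome")
    expect_equal(length(simulateTruth(tiny)), 90L)
})

test_that("noiseless high-depth replicate recovers exactly truth-in-capture", {
    cfg <- miniCohort(nTruth = 100L)
    truth <- simulateTruth(cfg)
    cap <- RegionSet("cap", contig = "1", start = 0, end = 5e5)
    prof <- LabProfile("L", cap, meanDepth = 20000, depthDispersion = 1e6,
                       thresholds = CallerThresholds(0, 1, 0),
                       fpRate = 0, germlineLeakRate = 0)
    ms <- simulateLabReplicate(truth, prof, purity = 0.4,
                               replicateSeed = 123L)
    expect_setequal(mutationKeys(ms),
                    mutationKeys(restrictCalls(truth, cap)))
    ## capture disjoint from truth: empty call set
    far <- RegionSet("far", contig = "2", start = 0, end = 100)
    prof2 <- LabProfile("L", far, meanDepth = 100,
                        thresholds = CallerThresholds(0, 1, 0),
                        fpRate = 0, germlineLeakRate = 0)
    expect_equal(length(simulateLabReplicate(truth, prof2, 0.4, 1L)), 0L)
})

test_that("replicate simulation is deterministic under its seed", {
    cfg <- miniCohort()
    truth <- simulateTruth(cfg)
    germ <- simulateGermlinePool(cfg)
    p <- cfg@labs[[1]]
    a <- simulateLabReplicate(truth, p, 0.4, 55L, germline = germ,
                              keepRejected = TRUE)
    b <- simulateLabReplicate(truth, p, 0.4, 55L, germline = germ,
                              keepRejected = TRUE)
    expect_identical(mutationKeys(a), mutationKeys(b))
    expect_identical(callData(a)$vaf, callData(b)$vaf)
    c <- simulateLabReplicate(truth, p, 0.4, 56L, germline = germ)
    expect_false(identical(mutationKeys(a), mutationKeys(c)))
})

test_that("per-mutation detection frequency matches the analytic model", {
    ## 20 heterozygous mutations x 100 draws = 2000 Bernoulli trials
    genome <- toyGenome("1", 1e5)
    cap <- RegionSet("cap", contig = "1", start = 0, end = 1e5)
    th <- CallerThresholds(0.05, 4, 10)
    prof <- LabProfile("L", cap, meanDepth = 100, depthDispersion = 8,
                       thresholds = th, fpRate = 0, germlineLeakRate = 0)
    cfg <- CohortConfig("S", genome, cap, nTruthMutations = 20L,
                        hetFraction = 1, purity = 0.30, labs = list(prof),
                        replicates = c(L = 1L), nGermline = 0L,
                        masterSeed = 77L)
    truth <- simulateTruth(cfg)
    nTrials <- 0L; nDet <- 0L
    for (r in seq_len(100)) {
        ms <- simulateLabReplicate(truth, prof, 0.30, 1000L + r)
        nDet <- nDet + length(ms)
        nTrials <- nTrials + length(truth)
    }
    pHat <- nDet / nTrials
    pAna <- detectionProbabilityMarginal(0.15, 100, 8, th)
    se <- sqrt(pAna * (1 - pAna) / nTrials)
    expect_lt(abs(pHat - pAna), 3 * se + 1e-12)
})

test_that("simulated studies are written completely and reproducibly", {
    cfg <- miniCohort()
    d1 <- tempfile(); d2 <- tempfile()
    sc <- suppressMessages(simulateStudy(cfg, d1))
    expect_s4_class(sc, "StudyConfig")
    manifest <- readLines(file.path(d1, "MANIFEST"))
    ## 2 labs (2 + 1 replicates) + truth + panel + 2 capture beds + yaml
    expect_setequal(manifest,
                    c("LabA_S1_r1.vcf", "LabA_S1_r2.vcf", "LabB_S1_r1.vcf",
                      "truth_S1.vcf", "panel.bed", "capture_LabA.bed",
                      "capture_LabB.bed", "study.yaml"))
    expect_true(all(file.exists(file.path(d1, manifest))))
    suppressMessages(simulateStudy(cfg, d2))
    for (f in setdiff(manifest, "study.yaml"))
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = paste("md5 of", f))
})

test_that("planted burden ordering is recovered end-to-end", {
    ## hypermutated vs low-burden configuration, same lab profiles
    genome <- toyGenome("1", 1e6)
    panel <- RegionSet("panel", contig = "1", start = 0, end = 5e5)
    prof <- LabProfile("LabA", panel, meanDepth = 120, depthDispersion = 8,
                       thresholds = CallerThresholds(0.05, 4, 10),
                       fpRate = 5, germlineLeakRate = 0)
    mk <- function(n, seed) CohortConfig(
        "S", genome, panel, nTruthMutations = n, hetFraction = 0.8,
        purity = 0.6, labs = list(prof), replicates = c(LabA = 1L),
        nGermline = 50L, masterSeed = seed)
    burden <- function(cfg) {
        truth <- simulateTruth(cfg)
        ms <- simulateLabReplicate(truth, prof, cfg@purity,
                                   cfg@masterSeed + 1L)
        mutationalBurden(restrictCalls(ms, panel), panel)@burden
    }
    bHigh <- burden(mk(1500L, 3L))
    bLow <- burden(mk(150L, 4L))
    expect_gt(bHigh, bLow)
})
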