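test_that("VCF reading preserves records, multi-allelic lines and filter status", {
    f <- tempfile(fileext = ".vcf")
    writeLines(c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                 "chr1\t100\t.\tA\tT\t.\tPASS\t.",
                 "chr1\t200\t.\tC\tT,G\t.\tPASS\t.",
                 "chr2\t50\t.\tG\tC\t.\tlow_qual\t."), f)
    rec <- suppressMessages(readVcfCalls(f))
    expect_equal(nrow(rec), 3L)
    expect_equal(rec$position, c(100L, 200L, 50L))
    expect_equal(as.list(rec$alt)[[2]], c("T", "G"))
    expect_equal(rec$filter, c("PASS", "PASS", "low_qual"))
})

test_that("filtered VCF records are returned with status, not dropped", {
    f <- writeTinyVcf(tempfile(fileext = ".vcf"), nPass = 5, nFail = 2)
    rec <- suppressMessages(readVcfCalls(f))
    ## independent line scan of the fixture
    lines <- grep("^[^#]", readLines(f), value = TRUE)
    nonPass <- sum(vapply(strsplit(lines, "\t"),
                          function(x) !x[7] %in% c("PASS", "."), logical(1)))
    expect_equal(nrow(rec), length(lines))
    expect_equal(sum(!rec$filter %in% c("PASS", ".")), nonPass)
    expect_equal(nonPass, 2L)
})

test_that("malformed VCF input raises a format error", {
    f <- tempfile(fileext = ".vcf")
    writeLines(c("not a vcf at all", "chr1 100"), f)
    expect_error(suppressMessages(readVcfCalls(f)), "malformed VCF")
    expect_error(readVcfCalls(tempfile(fileext = ".vcf")), "not found")
})

test_that("tabular reports honor schema mapping and 0-based flag", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("Chrom\tPos\tRef\tAlt",
                 "chr1\t100\tA\tT",
                 "chr2\t250\tG\tC"), f)
    schema <- list(contig = "Chrom", position = "Pos", ref = "Ref",
                   alt = "Alt")
    rec <- suppressMessages(readTabularReport(f, schema))
    expect_equal(nrow(rec), 2L)
    expect_equal(rec$position, c(100L, 250L))

    f0 <- tempfile(fileext = ".tsv")
    writeLines(c("Chrom\tPos\tRef\tAlt", "chr1\t99\tA\tT"), f0)
    rec0 <- suppressMessages(
        readTabularReport(f0, c(schema, zeroBased = TRUE)))
    expect_equal(rec0$position, 100L)

    expect_error(suppressMessages(readTabularReport(f, list(contig = "Chrom"))),
                 "missing mapping")
    expect_error(
        suppressMessages(readTabularReport(
            f, list(contig = "NoSuch", position = "Pos", ref = "Ref",
                    alt = "Alt"))),
        "not found")
})

test_that("a malformed tabular row is reported by row number", {
    f <- tempfile(fileext = ".tsv")
    rows <- sprintf("chr1\t%d\tA\tT", seq_len(10) * 10L)
    rows[7] <- "chr1\tnot_a_number\tA\tT"
    writeLines(c("Chrom\tPos\tRef\tAlt", rows), f)
    expect_error(
        suppressMessages(readTabularReport(
            f, list(contig = "Chrom", position = "Pos", ref = "Ref",
                    alt = "Alt"))),
        "row 7")
})

test_that("BED reading merges overlaps and preserves total size", {
    f <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t0\t100", "chr1\t50\t150"), f)
    rs <- suppressMessages(readBed(f))
    expect_equal(length(rs), 1L)
    expect_equal(regionSize(rs), 150)

    f2 <- tempfile(fileext = ".bed")
    writeLines(c("chr2\t0\t100", "chr1\t0\t100"), f2)  # unsorted input
    rs2 <- suppressMessages(readBed(f2))
    expect_equal(length(rs2), 2L)
    expect_equal(regionSize(rs2), 200)

    expect_error(RegionSet("bad", contig = "1", start = 100, end = 100),
                 "start >= end")
})

test_that("BED merge matches per-base occupancy oracle and is idempotent", {
    set.seed(11)
    n <- 1000
    start <- sample.int(9900L, n, replace = TRUE) - 1L
    end <- start + sample.int(100L, n, replace = TRUE)
    rs <- RegionSet("rand", contig = "1", start = start, end = end)
    occ <- logical(10000)
    for (i in seq_len(n)) occ[(start[i] + 1):min(end[i], 10000)] <- TRUE
    expect_equal(regionSize(rs), sum(occ))
    rs2 <- RegionSet("rand2", gr = regions(rs))  # merge of merged input
    expect_equal(regionSize(rs2), regionSize(rs))
    expect_equal(length(rs2), length(rs))
})

test_that("VCF write/read round trip reproduces the key set", {
    empty <- MutationSet("LabA", "S1", "1")
    f <- tempfile(fileext = ".vcf")
    writeVcfCalls(empty, f)
    expect_equal(nrow(suppressMessages(readVcfCalls(f))), 0L)

    set.seed(3)
    pos <- sample.int(1e6, 500)
    ms <- MutationSet("LabA", "S1", "1", contig = "1", position = pos,
                      ref = sample(c("A", "C"), 500, TRUE),
                      alt = "G",
                      vaf = round(runif(500), 3),
                      depth = sample(50:150, 500, TRUE))
    writeVcfCalls(ms, f)
    back <- buildMutationSet(suppressMessages(readVcfCalls(f)),
                             lab = "LabA", sample = "S1", replicate = "1",
                             includeFiltered = TRUE)
    expect_setequal(mutationKeys(back), mutationKeys(ms))
    ## vaf/depth annotations survive
    expect_equal(sort(callData(back)$depth), sort(callData(ms)$depth))
})

test_that("truth VCF round trip preserves zygosity", {
    ts <- TruthSet(sample = "S1", contig = c("1", "1"),
                   position = c(100L, 200L), ref = c("A", "C"),
                   alt = c("T", "G"),
                   zygosity = c("heterozygous", "homozygous"))
    f <- tempfile(fileext = ".vcf")
    writeVcfCalls(ts, f)
    back <- readTruthVcf(f, sample = "S1")
    expect_s4_class(back, "TruthSet")
    expect_setequal(mutationKeys(back), mutationKeys(ts))
    expect_setequal(callData(back)$zygosity, callData(ts)$zygosity)
})

test_that("study config round trips through YAML and checks files", {
    dir <- tempfile(); dir.create(dir)
    for (f in c("a1.vcf", "a2.vcf", "b1.vcf"))
        writeTinyVcf(file.path(dir, f), 2, 0)
    writeLines(c("chr1\t0\t1000"), file.path(dir, "panel.bed"))
    cfg <- StudyConfig(
        labs = c("LabA", "LabB"), samples = "S1",
        files = data.frame(lab = c("LabA", "LabA", "LabB"),
                           sample = "S1", replicate = c("1", "2", "1"),
                           path = c("a1.vcf", "a2.vcf", "b1.vcf")),
        panelPath = "panel.bed", baseDir = dir)
    yml <- file.path(dir, "study.yaml")
    writeStudyConfig(cfg, yml)
    back <- suppressMessages(readStudyConfig(yml))
    expect_equal(sort(back@files$path), sort(cfg@files$path))
    expect_equal(back@panelPath, "panel.bed")

    cfgBad <- StudyConfig(
        labs = "LabA", samples = "S1",
        files = data.frame(lab = "LabA", sample = "S1", replicate = "1",
                           path = "missing.vcf"), baseDir = dir)
    writeStudyConfig(cfgBad, yml)
    expect_error(suppressMessages(readStudyConfig(yml)), "missing file")
})

test_that("duplicate replicate declarations are rejected", {
    expect_error(StudyConfig(
        labs = "LabA", samples = "S1",
        files = data.frame(lab = "LabA", sample = "S1",
                           replicate = c("1", "1"),
                           path = c("x.vcf", "y.vcf"))),
        "appear once")
})
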