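#' @importFrom GenomeInfoDb Seqinfo
NULL

## Run code under a given seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, code) {
    genv <- globalenv()
    old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
        get(".Random.seed", envir = genv) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(as.integer(seed))
    force(code)
}

#' Build a toy genome
#'
#' A toy genome is just contig names and lengths, carried as a
#' \code{Seqinfo}; the simulator plants variants on it and never needs
#' sequence.
#'
#' @param names contig names.
#' @param lengths contig lengths in bp.
#' @return a \code{Seqinfo}.
#' @export
#' @examples
#' toyGenome(c("1", "2"), c(5e6, 5e6))
toyGenome <- function(names, lengths) {
    stopifnot(length(names) == length(lengths), all(lengths >= 1),
              !anyDuplicated(names))
    Seqinfo(seqnames = as.character(names), seqlengths = as.integer(lengths))
}

#' LabProfile constructor
#'
#' @param label lab label.
#' @param capture \linkS4class{RegionSet} the lab's kit targets.
#' @param meanDepth mean on-target coverage.
#' @param depthDispersion negative-binomial size parameter of per-site depth.
#' @param thresholds \linkS4class{CallerThresholds} the lab's caller applies.
#' @param fpRate expected artifact calls per Mb of capture.
#' @param germlineLeakRate per-variant germline leak probability.
#' @param seedOffset lab-specific seed offset.
#' @return a \linkS4class{LabProfile}.
#' @export
LabProfile <- function(label, capture, meanDepth = 100,
                       depthDispersion = 5,
                       thresholds = CallerThresholds(),
                       fpRate = 5, germlineLeakRate = 0.01,
                       seedOffset = 0L) {
    new("LabProfile", label = as.character(label), capture = capture,
        meanDepth = as.numeric(meanDepth),
        depthDispersion = as.numeric(depthDispersion),
        thresholds = thresholds, fpRate = as.numeric(fpRate),
        germlineLeakRate = as.numeric(germlineLeakRate),
        seedOffset = as.integer(seedOffset))
}

setMethod("show", "LabProfile", function(object) {
    cat("LabProfile '", object@label, "': capture ",
        format(regionSizeMb(object@capture), digits = 3), " Mb, depth ~NB(mu=",
        object@meanDepth, ", size=", object@depthDispersion, "), fp ",
        object@fpRate, "/Mb, germline leak ", object@germlineLeakRate,
        "\n", sep = "")
})

#' CohortConfig constructor
#'
#' @param sampleLabel sample label.
#' @param genome \code{Seqinfo} toy genome.
#' @param panel common-panel \linkS4class{RegionSet}.
#' @param nTruthMutations planted somatic mutations (genome-wide).
#' @param hetFraction probability a planted mutation is heterozygous.
#' @param purity tumor purity in (0, 1].
#' @param labs list of \linkS4class{LabProfile}.
#' @param replicates named integer vector of replicates per lab (unnamed
#'   scalar recycles to every lab).
#' @param nGermline size of the shared germline pool.
#' @param masterSeed master seed; all per-stage seeds derive from it.
#' @return a \linkS4class{CohortConfig}.
#' @export
CohortConfig <- function(sampleLabel, genome, panel, nTruthMutations,
                         hetFraction = 0.8, purity = 0.5, labs = list(),
                         replicates = 2L, nGermline = 500L,
                         masterSeed = 1L) {
    labNames <- vapply(labs, function(p) p@label, character(1))
    if (is.null(names(replicates)))
        replicates <- setNames(rep(as.integer(replicates),
                                   length.out = length(labs)), labNames)
    new("CohortConfig", sampleLabel = as.character(sampleLabel),
        genome = genome, panel = panel,
        nTruthMutations = as.integer(nTruthMutations),
        hetFraction = as.numeric(hetFraction), purity = as.numeric(purity),
        labs = labs, replicates = replicates,
        nGermline = as.integer(nGermline), masterSeed = as.integer(masterSeed))
}

setMethod("show", "CohortConfig", function(object) {
    cat("CohortConfig '", object@sampleLabel, "': ",
        object@nTruthMutations, " planted mutation(s), purity ",
        object@purity, ", ", length(object@labs), " lab(s), seed ",
        object@masterSeed, "\n", sep = "")
})

## Draw n distinct genome positions (uniform, without replacement) plus
## random ref and alt alleles. Assumes the RNG seed is already set.
.randomKeys <- function(genome, n) {
    lens <- as.numeric(seqlengths(genome))
    total <- sum(lens)
    offs <- sort(sample.int(total, n))
    cum <- cumsum(lens)
    ci <- findInterval(offs - 1, c(0, cum), rightmost.closed = FALSE)
    pos <- as.integer(offs - c(0, cum)[ci])
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    list(contig = seqnames(genome)[ci], position = pos,
         ref = ref, alt = unname(alt))
}

#' Plant the somatic truth set for a simulated sample
#'
#' Positions are drawn uniformly without replacement over the toy genome, the
#' alternate allele uniformly from the three non-reference bases, and
#' zygosity is heterozygous with probability \code{hetFraction}. The draw is
#' a deterministic function of the config's master seed.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return a \linkS4class{TruthSet}.
#' @export
simulateTruth <- function(config) {
    stopifnot(is(config, "CohortConfig"))
    n <- config@nTruthMutations
    gsize <- sum(as.numeric(seqlengths(config@genome)))
    if (n > gsize)
        stop("cannot plant ", n, " mutations on a ", gsize, " bp genome",
             call. = FALSE)
    .withSeed(config@masterSeed, {
        k <- .randomKeys(config@genome, n)
        zyg <- ifelse(runif(n) < config@hetFraction,
                      "heterozygous", "homozygous")
        TruthSet(sample = config@sampleLabel, contig = k$contig,
                 position = k$position, ref = k$ref, alt = k$alt,
                 zygosity = zyg)
    })
}

#' Shared germline pool for a simulated sample
#'
#' Every lab sees the same donor, so germline leakage across labs draws from
#' one shared pool; its draw derives from \code{masterSeed + 500000} so it is
#' regenerable independently of the truth set.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return a \linkS4class{TruthSet} (zygosity is the germline genotype).
#' @export
simulateGermlinePool <- function(config) {
    stopifnot(is(config, "CohortConfig"))
    .withSeed(config@masterSeed + 500000L, {
        n <- config@nGermline
        k <- .randomKeys(config@genome, n)
        zyg <- ifelse(runif(n) < 2 / 3, "heterozygous", "homozygous")
        TruthSet(sample = config@sampleLabel, lab = "germline",
                 contig = k$contig, position = k$position,
                 ref = k$ref, alt = k$alt, zygosity = zyg)
    })
}

## Uniform positions within a region set (with replacement; duplicate keys
## collapse downstream). Assumes the seed is already set.
.samplePositionsInRegions <- function(regionSet, n) {
    gr <- regions(regionSet)
    w <- as.numeric(width(gr))
    cum <- cumsum(w)
    offs <- runif(n, 0, sum(w))
    i <- findInterval(offs, c(0, cum), rightmost.closed = TRUE)
    i[i > length(gr)] <- length(gr)
    pos <- as.integer(start(gr)[i] + floor(offs - c(0, cum)[i]))
    pos <- pmin(pos, end(gr)[i])
    list(contig = as.character(seqnames(gr))[i], position = pos)
}

#' Simulate one laboratory replicate call set
#'
#' For each truth mutation inside the lab's capture, per-site depth is drawn
#' from a negative binomial around the lab's mean, the alternate-read count
#' from a binomial at the purity-scaled expected VAF, and the mutation is
#' called when the lab's thresholds pass on the realized values. With
#' \code{keepRejected = TRUE}, candidates with at least one supporting read
#' that fail the thresholds are additionally retained with FILTER
#' \code{low_confidence} so a harmonized re-analysis can re-threshold them;
#' the default returns called keys only. On top of the
#' true calls, \code{Poisson(fpRate x capture Mb)} artifact calls are planted
#' at uniform capture positions, and each shared germline variant in capture
#' leaks into the report independently with the lab's leak rate; both carry
#' FILTER \code{PASS} since the originating pipeline believed them.
#'
#' @param truth somatic \linkS4class{TruthSet}.
#' @param profile a \linkS4class{LabProfile}.
#' @param purity tumor purity.
#' @param replicateSeed seed for this replicate (by convention
#'   \code{masterSeed + seedOffset + replicate index}).
#' @param germline optional shared germline pool (\linkS4class{TruthSet}).
#' @param keepRejected retain sub-threshold candidates with filter status.
#' @param fpTransitionBias probability that an artifact call is forced to a
#'   C>T or G>A change (deamination-style damage); 0 disables.
#' @return a \linkS4class{MutationSet} with per-key \code{vaf}, \code{depth},
#'   \code{filter} and an \code{origin} column
#'   (somatic/artifact/germline).
#' @export
simulateLabReplicate <- function(truth, profile, purity, replicateSeed,
                                 germline = NULL, keepRejected = FALSE,
                                 fpTransitionBias = 0) {
    stopifnot(is(truth, "TruthSet"), is(profile, "LabProfile"))
    th <- profile@thresholds
    .withSeed(replicateSeed, {
        tin <- restrictCalls(truth, profile@capture)
        cd <- callData(tin)
        n <- nrow(cd)
        depth <- rnbinom(n, size = profile@depthDispersion,
                         mu = profile@meanDepth)
        vafTrue <- vapply(cd$zygosity, function(z) expectedVaf(purity, z),
                          numeric(1), USE.NAMES = FALSE)
        altReads <- rbinom(n, size = depth, prob = vafTrue)
        obsVaf <- ifelse(depth > 0, altReads / depth, 0)
        pass <- depth >= th@minDepth & altReads >= th@minAltReads &
            obsVaf + .EPS >= th@minVaf
        keep <- if (keepRejected) altReads >= 1L else pass
        som <- data.frame(
            contig = cd$contig, position = cd$position,
            ref = cd$ref, alt = cd$alt, vaf = obsVaf, depth = depth,
            filter = ifelse(pass, "PASS", "low_confidence"),
            origin = rep("somatic", n),
            stringsAsFactors = FALSE)[keep, , drop = FALSE]

        capMb <- regionSizeMb(profile@capture)
        nFP <- rpois(1, profile@fpRate * capMb)
        fp <- NULL
        if (nFP > 0) {
            loc <- .samplePositionsInRegions(profile@capture, nFP)
            bases <- c("A", "C", "G", "T")
            ref <- sample(bases, nFP, replace = TRUE)
            alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                          character(1), USE.NAMES = FALSE)
            if (fpTransitionBias > 0) {
                damaged <- runif(nFP) < fpTransitionBias
                ref[damaged] <- sample(c("C", "G"), sum(damaged),
                                       replace = TRUE)
                alt[damaged] <- ifelse(ref[damaged] == "C", "T", "A")
            }
            fpDepth <- rnbinom(nFP, size = profile@depthDispersion,
                               mu = profile@meanDepth)
            fpVafTrue <- runif(nFP, 0.02, 0.25)
            fpAlt <- rbinom(nFP, fpDepth, fpVafTrue)
            fpObs <- ifelse(fpDepth > 0, fpAlt / fpDepth, 0)
            ok <- fpAlt >= 1L
            fp <- data.frame(contig = loc$contig, position = loc$position,
                             ref = ref, alt = alt, vaf = fpObs,
                             depth = fpDepth, filter = "PASS",
                             origin = "artifact",
                             stringsAsFactors = FALSE)[ok, , drop = FALSE]
        }

        gl <- NULL
        if (!is.null(germline) && profile@germlineLeakRate > 0) {
            gin <- restrictCalls(germline, profile@capture)
            gd <- callData(gin)
            leak <- runif(nrow(gd)) < profile@germlineLeakRate
            gd <- gd[leak, , drop = FALSE]
            if (nrow(gd)) {
                gDepth <- rnbinom(nrow(gd), size = profile@depthDispersion,
                                  mu = profile@meanDepth)
                gVafTrue <- ifelse(gd$zygosity == "heterozygous", 0.5, 1.0)
                gAlt <- rbinom(nrow(gd), gDepth, gVafTrue)
                gObs <- ifelse(gDepth > 0, gAlt / gDepth, 0)
                ok <- gAlt >= 1L
                gl <- data.frame(contig = gd$contig, position = gd$position,
                                 ref = gd$ref, alt = gd$alt, vaf = gObs,
                                 depth = gDepth, filter = "PASS",
                                 origin = "germline",
                                 stringsAsFactors = FALSE)[ok, , drop = FALSE]
            }
        }

        all <- rbind(som, fp, gl)
        ms <- MutationSet(lab = profile@label, sample = sampleName(truth),
                          replicate = as.character(replicateSeed),
                          contig = all$contig, position = all$position,
                          ref = all$ref, alt = all$alt, vaf = all$vaf,
                          depth = all$depth, filter = all$filter)
        ## re-attach origin after dedupe/sort by key match
        key <- paste0(all$contig, ":", all$position, ":", all$ref, ">",
                      all$alt)
        mcols(ms@calls)$origin <-
            all$origin[match(.keyStrings(ms), key)]
        ms
    })
}

#' Simulate and write a full multi-laboratory study
#'
#' Generates truth, germline pool and per-lab per-replicate call sets for one
#' or more simulated samples, writes everything to disk (call VCFs, truth
#' VCFs, capture and panel BEDs, a YAML study configuration and a manifest),
#' and returns the ready-to-run \linkS4class{StudyConfig}. Fully reproducible
#' under the configs' master seeds: replicate seeds are
#' \code{masterSeed + lab seedOffset + replicate index}, so any single
#' replicate is regenerable in isolation.
#'
#' @param configs a \linkS4class{CohortConfig} or list of them (one per
#'   sample; all sharing the same lab profiles and panel).
#' @param outputDir output directory (created if needed).
#' @param keepRejected write sub-threshold candidates with filter status.
#' @param fpTransitionBias passed to \code{\link{simulateLabReplicate}}.
#' @return the \linkS4class{StudyConfig}, invisibly; its YAML is at
#'   \code{file.path(outputDir, "study.yaml")}.
#' @export
simulateStudy <- function(configs, outputDir, keepRejected = TRUE,
                          fpTransitionBias = 0) {
    if (is(configs, "CohortConfig")) configs <- list(configs)
    stopifnot(all(vapply(configs, is, logical(1), "CohortConfig")))
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    first <- configs[[1]]
    allLabs <- list()
    for (config in configs)
        for (p in config@labs)
            if (!p@label %in% names(allLabs)) allLabs[[p@label]] <- p
    labNames <- names(allLabs)

    panelPath <- "panel.bed"
    writeBed(first@panel, file.path(outputDir, panelPath))
    capturePaths <- setNames(paste0("capture_", labNames, ".bed"), labNames)
    for (p in allLabs)
        writeBed(p@capture, file.path(outputDir, capturePaths[[p@label]]))

    rows <- list()
    truthPaths <- character(0)
    for (config in configs) {
        smp <- config@sampleLabel
        truth <- simulateTruth(config)
        germline <- simulateGermlinePool(config)
        truthPaths[smp] <- paste0("truth_", smp, ".vcf")
        writeVcfCalls(truth, file.path(outputDir, truthPaths[smp]))
        for (p in config@labs) {
            nrep <- config@replicates[[p@label]]
            for (r in seq_len(nrep)) {
                seed <- config@masterSeed + p@seedOffset + r
                ms <- simulateLabReplicate(truth, p, config@purity, seed,
                                           germline = germline,
                                           keepRejected = keepRejected,
                                           fpTransitionBias = fpTransitionBias)
                path <- paste0(p@label, "_", smp, "_r", r, ".vcf")
                writeVcfCalls(ms, file.path(outputDir, path))
                rows[[length(rows) + 1L]] <- data.frame(
                    lab = p@label, sample = smp, replicate = as.character(r),
                    path = path, stringsAsFactors = FALSE)
            }
        }
    }
    files <- do.call(rbind, rows)
    cfg <- StudyConfig(labs = labNames,
                       samples = vapply(configs, function(cc) cc@sampleLabel,
                                        character(1)),
                       files = files, panelPath = panelPath,
                       truthPaths = truthPaths, capturePaths = capturePaths,
                       baseDir = outputDir)
    writeStudyConfig(cfg, file.path(outputDir, "study.yaml"))
    manifest <- sort(c(files$path, panelPath, unname(truthPaths),
                       unname(capturePaths), "study.yaml"))
    writeLines(manifest, file.path(outputDir, "MANIFEST"))
    message("simulated study written to ", outputDir, " (",
            length(manifest), " files)")
    invisible(cfg)
}

## Deterministic tiling helper for preset regions: tiles of `width` bp every
## `stride` bp starting at `offset` (0-based) on every contig.
.tileRegions <- function(genome, name, offset, width, stride = 25000L) {
    starts <- integer(0); ends <- integer(0); contigs <- character(0)
    for (s in seqnames(genome)) {
        len <- seqlengths(genome)[[s]]
        st <- seq(offset, len - width, by = stride)
        contigs <- c(contigs, rep(s, length(st)))
        starts <- c(starts, st)
        ends <- c(ends, st + width)
    }
    RegionSet(name, contig = contigs, start = starts, end = ends)
}

#' Preset cohort configurations for a five-laboratory study
#'
#' A ready-made study emulating the structure of a multi-laboratory exome
#' comparison on a 10 Mb toy genome: five labs with heterogeneous capture
#' regions (a shared 2 Mb panel plus lab-specific extra regions), mean depths
#' from 80x to 180x, calling thresholds from hyper-permissive to strict, and
#' artifact/germline-leak rates spanning more than an order of magnitude; one
#' lab runs a single replicate. Three samples: a purity-0.30 mixture with a
#' 178-mutation truth set (sensitivity benchmarking), a hypermutated sample,
#' and a low-burden sample. The profiles are qualitative gestures at the
#' spread seen across real vendors, not calibrated estimates.
#'
#' @param masterSeed master seed for all three samples.
#' @return list with elements \code{genome}, \code{panel}, \code{labs} and
#'   \code{configs} (named list of \linkS4class{CohortConfig}: S1, S2, S3).
#' @export
cohortPresets <- function(masterSeed = 1L) {
    genome <- toyGenome(c("1", "2"), c(5e6, 5e6))
    panel <- .tileRegions(genome, "toy_panel", offset = 0L, width = 5000L)
    mkCapture <- function(label, extraWidth, jitter) {
        extra <- .tileRegions(genome, paste0(label, "_extra"),
                              offset = 6000L + jitter, width = extraWidth)
        RegionSet(paste0(label, "_capture"),
                  gr = c(regions(panel), regions(extra)))
    }
    labs <- list(
        LabProfile("LabA", mkCapture("LabA", 1250L, 0L), meanDepth = 180,
                   depthDispersion = 10,
                   thresholds = CallerThresholds(0.10, 5, 20),
                   fpRate = 2, germlineLeakRate = 0.002, seedOffset = 1000L),
        LabProfile("LabB", mkCapture("LabB", 3750L, 400L), meanDepth = 135,
                   depthDispersion = 8,
                   thresholds = CallerThresholds(0.05, 4, 14),
                   fpRate = 8, germlineLeakRate = 0.01, seedOffset = 2000L),
        LabProfile("LabC", mkCapture("LabC", 2500L, 800L), meanDepth = 170,
                   depthDispersion = 8,
                   thresholds = CallerThresholds(0.08, 4, 15),
                   fpRate = 4, germlineLeakRate = 0.005, seedOffset = 3000L),
        LabProfile("LabD", mkCapture("LabD", 5000L, 1200L), meanDepth = 100,
                   depthDispersion = 3,
                   thresholds = CallerThresholds(0.02, 2, 6),
                   fpRate = 60, germlineLeakRate = 0.05, seedOffset = 4000L),
        LabProfile("LabE", mkCapture("LabE", 3000L, 1600L), meanDepth = 80,
                   depthDispersion = 4,
                   thresholds = CallerThresholds(0.03, 3, 8),
                   fpRate = 20, germlineLeakRate = 0.02, seedOffset = 5000L))
    replicates <- c(LabA = 2L, LabB = 2L, LabC = 1L, LabD = 2L, LabE = 2L)
    ## the mixture sample is not analyzed by the single-replicate lab,
    ## mirroring the usual study design where one lab runs fewer arms
    s1Labs <- labs[vapply(labs, function(p) p@label != "LabC", logical(1))]
    configs <- list(
        S1 = CohortConfig("S1", genome, panel, nTruthMutations = 178L,
                          hetFraction = 0.7, purity = 0.30, labs = s1Labs,
                          replicates = replicates[names(replicates) != "LabC"],
                          nGermline = 500L,
                          masterSeed = masterSeed),
        S2 = CohortConfig("S2", genome, panel, nTruthMutations = 3000L,
                          hetFraction = 0.85, purity = 0.60, labs = labs,
                          replicates = replicates, nGermline = 500L,
                          masterSeed = masterSeed + 1L),
        S3 = CohortConfig("S3", genome, panel, nTruthMutations = 500L,
                          hetFraction = 0.8, purity = 0.50, labs = labs,
                          replicates = replicates, nGermline = 500L,
                          masterSeed = masterSeed + 2L))
    list(genome = genome, panel = panel, labs = labs, configs = configs)
}
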