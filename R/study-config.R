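#' Construct a StudyConfig
#'
#' @param labs,samples label vectors.
#' @param files data.frame with columns \code{lab}, \code{sample},
#'   \code{replicate}, \code{path} (one row per call file).
#' @param panelPath common panel BED path, or \code{NA}.
#' @param truthPaths named character vector, sample label -> truth VCF path.
#' @param capturePaths named character vector, lab label -> capture BED path.
#' @param tabularSchemas named list, lab label -> schema for
#'   \code{\link{readTabularReport}}, for labs that deliver delimited text
#'   instead of VCF.
#' @param baseDir directory against which relative paths resolve.
#' @return a \linkS4class{StudyConfig}.
#' @export
StudyConfig <- function(labs, samples, files, panelPath = NA_character_,
                        truthPaths = character(0),
                        capturePaths = character(0),
                        tabularSchemas = list(), baseDir = ".") {
    files$lab <- as.character(files$lab)
    files$sample <- as.character(files$sample)
    files$replicate <- as.character(files$replicate)
    files$path <- as.character(files$path)
    if (is.null(truthPaths)) truthPaths <- character(0)
    if (is.null(capturePaths)) capturePaths <- character(0)
    storage.mode(truthPaths) <- "character"
    storage.mode(capturePaths) <- "character"
    new("StudyConfig", labs = as.character(labs),
        samples = as.character(samples), files = files,
        panelPath = as.character(panelPath), truthPaths = truthPaths,
        capturePaths = capturePaths, tabularSchemas = tabularSchemas,
        baseDir = as.character(baseDir))
}

setMethod("show", "StudyConfig", function(object) {
    cat("StudyConfig: ", length(object@labs), " lab(s) x ",
        length(object@samples), " sample(s), ", nrow(object@files),
        " call file(s)\n", sep = "")
    cat("  panel: ", object@panelPath, "; truth for: ",
        paste(names(object@truthPaths), collapse = ", "), "\n", sep = "")
})

.resolvePath <- function(path, baseDir) {
    ifelse(is.na(path) | grepl("^/", path), path, file.path(baseDir, path))
}

#' Read or write a study configuration file
#'
#' The study configuration is a single YAML file naming laboratories,
#' samples, per-replicate call files, the common panel BED, per-lab capture
#' BEDs and optional per-sample truth VCFs. Relative paths resolve against
#' the file's directory. Missing referenced files are enumerated in one error
#' at read time.
#'
#' @param path YAML file path.
#' @param checkFiles error if referenced files are missing.
#' @return a \linkS4class{StudyConfig}.
#' @export
readStudyConfig <- function(path, checkFiles = TRUE) {
    if (!file.exists(path))
        stop("study config not found: ", path, call. = FALSE)
    y <- yaml::read_yaml(path)
    for (f in c("labs", "samples", "replicates"))
        if (is.null(y[[f]]))
            stop("study config lacks required field '", f, "'", call. = FALSE)
    rows <- list()
    for (lab in names(y$replicates))
        for (smp in names(y$replicates[[lab]])) {
            paths <- unlist(y$replicates[[lab]][[smp]])
            rows[[length(rows) + 1L]] <- data.frame(
                lab = lab, sample = smp,
                replicate = as.character(seq_along(paths)),
                path = paths, stringsAsFactors = FALSE)
        }
    files <- do.call(rbind, rows)
    cfg <- StudyConfig(
        labs = unlist(y$labs), samples = unlist(y$samples), files = files,
        panelPath = if (is.null(y$panel)) NA_character_ else y$panel,
        truthPaths = unlist(y$truth %||% list()),
        capturePaths = unlist(y$capture %||% list()),
        tabularSchemas = y$tabular_schemas %||% list(),
        baseDir = dirname(path))
    if (checkFiles) {
        paths <- c(cfg@files$path, cfg@truthPaths, cfg@capturePaths,
                   if (!is.na(cfg@panelPath)) cfg@panelPath)
        paths <- .resolvePath(paths, cfg@baseDir)
        bad <- paths[!file.exists(paths)]
        if (length(bad))
            stop("study config references missing file(s):\n  ",
                 paste(bad, collapse = "\n  "), call. = FALSE)
    }
    message("study config: ", length(cfg@labs), " lab(s), ",
            length(cfg@samples), " sample(s), ", nrow(cfg@files),
            " call file(s)")
    cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readStudyConfig
#' @param config a \linkS4class{StudyConfig} to serialize.
#' @export
writeStudyConfig <- function(config, path) {
    stopifnot(is(config, "StudyConfig"))
    reps <- list()
    for (lab in unique(config@files$lab)) {
        reps[[lab]] <- list()
        sub <- config@files[config@files$lab == lab, , drop = FALSE]
        for (smp in unique(sub$sample))
            reps[[lab]][[smp]] <-
                as.list(sub$path[sub$sample == smp][
                    order(sub$replicate[sub$sample == smp])])
    }
    y <- list(schema = 1L, labs = as.list(config@labs),
              samples = as.list(config@samples), replicates = reps)
    if (!is.na(config@panelPath)) y$panel <- config@panelPath
    if (length(config@truthPaths)) y$truth <- as.list(config@truthPaths)
    if (length(config@capturePaths)) y$capture <- as.list(config@capturePaths)
    if (length(config@tabularSchemas))
        y$tabular_schemas <- config@tabularSchemas
    yaml::write_yaml(y, path)
    invisible(path)
}
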