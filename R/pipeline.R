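#' RunReport: the single end-to-end result object
#'
#' Bundles everything one pipeline run produced: the echoed
#' configuration (so every number is recomputable from named inputs),
#' the per-family [FilterTrace], the candidate-gene table with tiers
#' and locus annotations, the association table, the package version
#' and the seed.
#'
#' @param object A `RunReport`.
#' @aliases RunReport
#' @exportClass RunReport
setClass("RunReport",
         representation(config = "list", trace = "FilterTrace",
                        candidates = "DataFrame", proximity = "ANY",
                        association = "ANY", version = "character",
                        seed = "integer"))

setMethod("show", "RunReport", function(object) {
    cat("RunReport (pedexome", object@version, ", seed",
        object@seed, ")\n")
    cat("families:", ncol(traceCounts(object@trace)), "\n")
    cat("candidate genes:", nrow(object@candidates), "\n")
    if (!is.null(object@association))
        cat("association rows:", nrow(object@association), "\n")
})

#' @rdname RunReport-class
#' @export
setMethod("traceCounts", "RunReport", function(x) traceCounts(x@trace))

.configError <- function(...) stop("configuration error: ", ...,
                                   call. = FALSE)

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full prioritization pipeline from a config
#'
#' Executes the fixed stage order — obtain data (simulate or load),
#' dominant segregation, filter cascade, cross-family candidate
#' discovery, locus proximity, case-control association — and writes
#' the intermediate artifacts plus a JSON+CSV report to `outDir`.
#' Configuration is validated up front: a missing input file aborts
#' before any stage runs. A stage failure aborts with the stage name
#' and cause.
#'
#' The configuration is a named list (or a YAML file with the same
#' structure):
#' \preformatted{
#' seed: 1
#' outDir: runs/demo          # optional; no files written if absent
#' simulate:                  # either this ...
#'   nBackgroundVariants: 2000
#' inputs:                    # ... or this
#'   vcf: {FamA: a.vcf, FamB: b.vcf}
#'   ped: families.ped
#' filter: {afKoreanMax: 0.02}   # FilterConfig overrides
#' minFamilies: 2
#' loci: {path: loci.bed, units: Mb}
#' marginBp: 1000000
#' caseControl:               # optional block
#'   simulate: true           # or countsCsv: counts.csv
#'   models: [allelic, dominant, recessive]
#' }
#'
#' @param config A named list or the path of a YAML file.
#' @return A [RunReport].
#'
#' @examples
#' rep <- runPipeline(list(seed = 9,
#'                         simulate = list(nBackgroundVariants = 200),
#'                         caseControl = list(simulate = TRUE)))
#' rep
#'
#' @export
runPipeline <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config))
            .configError("config file not found: '", config, "'")
        config <- read_yaml(config)
    }
    stopifnot(is.list(config))
    seed <- as.integer(config$seed %||% 1L)
    outDir <- config$outDir
    minFamilies <- as.integer(config$minFamilies %||% 2L)
    marginBp <- as.numeric(config$marginBp %||% 1e6)
    filterCfg <- filterConfigFromList(config$filter %||% list())

    ## ---- validate all referenced inputs before running anything ----
    if (is.null(config$simulate) && is.null(config$inputs))
        .configError("either a 'simulate' or an 'inputs' block is required")
    if (!is.null(config$inputs)) {
        vcfs <- unlist(config$inputs$vcf)
        if (is.null(vcfs) || is.null(config$inputs$ped))
            .configError("'inputs' block needs 'vcf' (named per family) and 'ped'")
        missingFiles <- c(vcfs[!file.exists(vcfs)],
                          config$inputs$ped[!file.exists(config$inputs$ped)])
        if (length(missingFiles))
            .configError("input file(s) not found: ",
                         paste(missingFiles, collapse = ", "))
    }
    if (!is.null(config$loci) && !file.exists(config$loci$path))
        .configError("locus file not found: '", config$loci$path, "'")
    if (!is.null(config$caseControl$countsCsv) &&
        !file.exists(config$caseControl$countsCsv))
        .configError("counts file not found: '",
                     config$caseControl$countsCsv, "'")

    ## ---- data ----
    simCfg <- NULL
    if (!is.null(config$simulate)) {
        simArgs <- config$simulate
        simArgs$seed <- seed
        simCfg <- do.call(simulationConfig, simArgs)
        sim <- .stage("simulate", generateFamilyExome(
            simCfg, outDir = if (!is.null(outDir))
                file.path(outDir, "simulated") else NULL,
            filterCfg = filterCfg))
        famCohorts <- setNames(
            lapply(families(sim$pedigree), function(fam)
                sim$cohort[, familyMembers(sim$pedigree, fam)]),
            families(sim$pedigree))
        ped <- sim$pedigree
    } else {
        ped <- .stage("read-ped", readPedigree(config$inputs$ped))
        famCohorts <- .stage("read-vcf", lapply(config$inputs$vcf,
                                                readAnnotatedVcf))
        badFams <- setdiff(names(famCohorts), families(ped))
        if (length(badFams))
            .configError("vcf family id(s) not in pedigree: ",
                         paste(badFams, collapse = ", "))
    }

    ## ---- segregation + cascade, one family at a time ----
    cascades <- .stage("cascade", lapply(names(famCohorts), function(fam) {
        cohort <- famCohorts[[fam]]
        segs <- applySegregation(cohort, ped, familyIds = fam)
        runCascade(cohort, cfg = filterCfg, familySets = segs)
    }))
    names(cascades) <- names(famCohorts)
    counts <- do.call(cbind, lapply(cascades, function(x)
        traceCounts(x$trace)))
    colnames(counts) <- names(cascades)
    trace <- FilterTrace(counts)
    tiers <- setNames(lapply(names(cascades), function(fam)
        familyGeneTiers(cascades[[fam]], famCohorts[[fam]])[[fam]]),
        names(cascades))

    ## ---- discovery ----
    candidates <- .stage("discover", candidateGenes(tiers, minFamilies))
    proximity <- NULL
    if (!is.null(config$loci)) {
        loci <- .stage("read-loci", readLoci(
            config$loci$path, units = config$loci$units %||% "bp"))
        positions <- .stage("discover", {
            grList <- lapply(names(famCohorts), function(fam) {
                cohort <- famCohorts[[fam]]
                sel <- rowData(cohort)$gene %in% candidates$gene
                gr <- GRanges(seqnames(rowRanges(cohort))[sel],
                              IRanges(start(rowRanges(cohort))[sel],
                                      width = 1L))
                names(gr) <- rowData(cohort)$gene[sel]
                gr
            })
            unique(do.call(c, grList))
        })
        proximity <- .stage("discover",
                            locusProximity(positions, loci, marginBp))
    }

    ## ---- association ----
    association <- NULL
    if (!is.null(config$caseControl)) {
        ccBlock <- config$caseControl
        models <- unlist(ccBlock$models) %||%
            c("allelic", "dominant", "recessive")
        ccCounts <- if (!is.null(ccBlock$countsCsv)) {
            .stage("assoc", readCaseControlCounts(ccBlock$countsCsv))
        } else if (isTRUE(ccBlock$simulate)) {
            ccCfg <- simCfg %||% simulationConfig(seed = seed)
            df <- .stage("assoc", generateCaseControlGenotypes(
                ccCfg, outPath = if (!is.null(outDir))
                    file.path(outDir, "counts.csv") else NULL))
            tmp <- tempfile(fileext = ".csv")
            write.csv(df, tmp, row.names = FALSE)
            on.exit(unlink(tmp), add = TRUE)
            readCaseControlCounts(tmp)
        } else {
            .configError("'caseControl' needs 'countsCsv' or 'simulate: true'")
        }
        association <- .stage("assoc", assocTable(ccCounts, models = models))
    }

    configEcho <- config
    configEcho$filter <- filterConfigToList(filterCfg)
    report <- new("RunReport", config = configEcho, trace = trace,
                  candidates = candidates, proximity = proximity,
                  association = association,
                  version = as.character(packageVersion("pedexome")),
                  seed = seed)
    if (!is.null(outDir))
        .stage("report", writeRunReport(report, outDir))
    report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a RunReport to CSV + JSON
#'
#' Writes `trace.csv` (stage x family survivor counts, long form),
#' `candidates.csv` (gene, families, tier flag, locus annotation when
#' available), `assoc.csv` (when an association table exists) and
#' `report.json` (config echo, version, seed, summary numbers).
#'
#' @param report A [RunReport].
#' @param outDir Output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeRunReport <- function(report, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(report@trace),
              file.path(outDir, "trace.csv"), row.names = FALSE)
    cand <- data.frame(
        gene = report@candidates$gene,
        families = vapply(report@candidates$families, paste,
                          character(1), collapse = ";"),
        nFamilies = report@candidates$nFamilies,
        hasRareVariant = report@candidates$hasRareVariant,
        stringsAsFactors = FALSE)
    if (!is.null(report@proximity)) {
        prox <- as.data.frame(report@proximity)
        cand <- merge(cand, prox, by = "gene", all.x = TRUE, sort = FALSE)
    }
    write.csv(cand, file.path(outDir, "candidates.csv"), row.names = FALSE)
    if (!is.null(report@association))
        write.csv(report@association, file.path(outDir, "assoc.csv"),
                  row.names = FALSE)
    write_json(list(version = report@version, seed = report@seed,
                    config = report@config,
                    nCandidates = nrow(report@candidates),
                    trace = as.data.frame(report@trace)),
               file.path(outDir, "report.json"),
               auto_unbox = TRUE, pretty = TRUE, digits = NA,
               null = "null")
    invisible(outDir)
}
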