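## The seven-stage annotation cascade. Each predicate is vectorized over
## the rows of a VariantCohort (or any data-frame-like object with the
## annotation columns) and returns TRUE for survivors.

.annotationFrame <- function(x) {
    if (is(x, "VariantCohort")) rowData(x) else x
}

#' Stage predicates of the annotation filter cascade
#'
#' Each stage maps one variant to keep (`TRUE`) or drop (`FALSE`):
#'
#' * `effectFilter` (stage 1): effect category is in `cfg@effectKeep`
#'   (coding, protein-altering consequences).
#' * `impactFilter` (stage 2): predicted impact is in `cfg@impactKeep`
#'   (default `HIGH` or `MODERATE`).
#' * `deleteriousnessFilter` (stage 3): a variant is dropped only when
#'   both SIFT and PolyPhen2 HDIV are present and both are benign
#'   (SIFT at or above `siftDamagingMax` and PolyPhen2 below
#'   `polyphenDamagingMin`); one damaging call, or a missing score,
#'   keeps it.
#' * `phylopFilter` (stage 4): PhyloP strictly above `phylopMin`
#'   (positive = conserved), missing passes.
#' * `phastconsFilter` (stage 5): PhastCons at or above
#'   `phastconsMin`, missing passes.
#' * `globalFrequencyFilter` (stage 6): global allele frequency
#'   strictly below `afGlobalMax`, unknown frequency passes.
#' * `koreanFrequencyFilter` (stage 7): population-reference MAF
#'   strictly below `afKoreanMax`, unknown passes.
#'
#' Missing-annotation behaviour of stages 3-7 is governed by
#' `cfg@missingPasses`; with the default `TRUE` a missing score or
#' frequency never removes a variant.
#'
#' @param x A [VariantCohort] or any object with the annotation
#'   columns (`effect`, `impact`, `sift`, `polyphen2Hdiv`, `phylop`,
#'   `phastcons`, `afGlobal`, `afKorean`) accessible by `$`.
#' @param cfg A [FilterConfig].
#' @return Logical vector, one element per variant row.
#'
#' @examples
#' ann <- S4Vectors::DataFrame(sift = c(0.04, 0.77, 0.60),
#'                             polyphen2Hdiv = c(0.272, 0.688, 0.10))
#' deleteriousnessFilter(ann, filterConfig())  # TRUE TRUE FALSE
#'
#' @name cascade-filters
NULL

#' @rdname cascade-filters
#' @export
effectFilter <- function(x, cfg = filterConfig()) {
    ann <- .annotationFrame(x)
    !is.na(ann$effect) & ann$effect %in% cfg@effectKeep
}

#' @rdname cascade-filters
#' @export
impactFilter <- function(x, cfg = filterConfig()) {
    ann <- .annotationFrame(x)
    !is.na(ann$impact) & ann$impact %in% cfg@impactKeep
}

#' @rdname cascade-filters
#' @export
deleteriousnessFilter <- function(x, cfg = filterConfig()) {
    ann <- .annotationFrame(x)
    sift <- ann$sift
    pp <- ann$polyphen2Hdiv
    siftDamaging <- !is.na(sift) & sift < cfg@siftDamagingMax
    ppDamaging <- !is.na(pp) & pp >= cfg@polyphenDamagingMin
    if (cfg@missingPasses[["deleteriousness"]]) {
        ## drop only when both scores are present and both benign
        bothBenignPresent <- !is.na(sift) & !is.na(pp) &
            !siftDamaging & !ppDamaging
        !bothBenignPresent
    } else {
        siftDamaging | ppDamaging
    }
}

.scoreStage <- function(value, pass, missingOk) {
    ifelse(is.na(value), missingOk, pass)
}

#' @rdname cascade-filters
#' @export
phylopFilter <- function(x, cfg = filterConfig()) {
    ann <- .annotationFrame(x)
    .scoreStage(ann$phylop, !is.na(ann$phylop) & ann$phylop > cfg@phylopMin,
                cfg@missingPasses[["phylop"]])
}

#' @rdname cascade-filters
#' @export
phastconsFilter <- function(x, cfg = filterConfig()) {
    ann <- .annotationFrame(x)
    .scoreStage(ann$phastcons,
                !is.na(ann$phastcons) & ann$phastcons >= cfg@phastconsMin,
                cfg@missingPasses[["phastcons"]])
}

#' @rdname cascade-filters
#' @export
globalFrequencyFilter <- function(x, cfg = filterConfig()) {
    ann <- .annotationFrame(x)
    .scoreStage(ann$afGlobal,
                !is.na(ann$afGlobal) & ann$afGlobal < cfg@afGlobalMax,
                cfg@missingPasses[["af_global"]])
}

#' @rdname cascade-filters
#' @export
koreanFrequencyFilter <- function(x, cfg = filterConfig()) {
    ann <- .annotationFrame(x)
    .scoreStage(ann$afKorean,
                !is.na(ann$afKorean) & ann$afKorean < cfg@afKoreanMax,
                cfg@missingPasses[["af_korean"]])
}

#' Run the seven-stage cascade with per-family survivor accounting
#'
#' Applies the annotation filters in their fixed order (effect >
#' impact > deleteriousness > PhyloP > PhastCons > global frequency >
#' population frequency) to the variants that co-segregate with
#' affection status in each family, and records the surviving count
#' after every stage in a [FilterTrace].
#'
#' Segregation is a pre-filter: the `raw` trace row counts the variants
#' entering stage 1, i.e. the per-family dominant-model segregating
#' set. Pass `familySets` to supply those sets directly (e.g. variants
#' already known to segregate); otherwise they are computed from `ped`
#' with [applySegregation()].
#'
#' Survivors of stages 1-5 are split into two tiers: the *rare* tier
#' passes both frequency stages, the *common* tier fails at least one
#' of them. The two tiers are disjoint and jointly equal the stage-5
#' survivor set.
#'
#' @param cohort A [VariantCohort].
#' @param ped A [Pedigree]; ignored when `familySets` is given.
#' @param cfg A [FilterConfig].
#' @param familySets Optional named list, family id -> character vector
#'   of variant keys entering stage 1.
#' @param allowHomAlt Passed to [applySegregation()].
#' @return A list with elements `commonTier` and `rareTier` (named
#'   lists, family id -> character vector of variant keys) and `trace`
#'   (a [FilterTrace]).
#'
#' @examples
#' sim <- generateFamilyExome(simulationConfig(nBackgroundVariants = 200,
#'                                             seed = 7))
#' res <- runCascade(sim$cohort, sim$pedigree)
#' traceCounts(res$trace)
#'
#' @export
runCascade <- function(cohort, ped = NULL, cfg = filterConfig(),
                       familySets = NULL, allowHomAlt = FALSE) {
    if (is.null(familySets)) {
        if (is.null(ped))
            stop("either 'ped' or 'familySets' must be supplied")
        familySets <- applySegregation(cohort, ped, allowHomAlt = allowHomAlt)
    }
    fams <- names(familySets)
    counts <- matrix(0L, nrow = length(cascadeStages()), ncol = length(fams),
                     dimnames = list(cascadeStages(), fams))
    commonTier <- rareTier <- setNames(vector("list", length(fams)), fams)
    ann <- rowData(cohort)
    for (fam in fams) {
        keys <- familySets[[fam]]
        miss <- setdiff(keys, rownames(cohort))
        if (length(miss))
            stop("unknown variant key(s) for family '", fam, "': ",
                 paste(utils::head(miss, 3), collapse = ", "))
        a <- ann[match(keys, rownames(cohort)), , drop = FALSE]
        s1 <- effectFilter(a, cfg)
        s2 <- s1 & impactFilter(a, cfg)
        s3 <- s2 & deleteriousnessFilter(a, cfg)
        s4 <- s3 & phylopFilter(a, cfg)
        s5 <- s4 & phastconsFilter(a, cfg)
        s6 <- s5 & globalFrequencyFilter(a, cfg)
        s7 <- s6 & koreanFrequencyFilter(a, cfg)
        counts[, fam] <- c(length(keys), sum(s1), sum(s2), sum(s3),
                           sum(s4), sum(s5), sum(s6), sum(s7))
        rareTier[[fam]] <- keys[s7]
        commonTier[[fam]] <- keys[s5 & !s7]
    }
    list(commonTier = commonTier, rareTier = rareTier,
         trace = FilterTrace(counts))
}

#' Floor-of-mean survivor count at one cascade stage
#'
#' Averages the per-family survivor counts of a [FilterTrace] at the
#' named stage and truncates to an integer (the convention used when
#' reporting "an average of N variants per family").
#'
#' @param x A [FilterTrace].
#' @param stage One of [cascadeStages()].
#' @return A single integer.
#' @examples
#' m <- matrix(rep(c(50L, 40L, 30L, 20L, 15L, 10L, 5L, 3L), 3), ncol = 3,
#'             dimnames = list(cascadeStages(), c("A", "B", "C")))
#' summarizeTrace(FilterTrace(m), "phastcons")
#' @rdname summarizeTrace
#' @export
setMethod("summarizeTrace", "FilterTrace", function(x, stage) {
    stage <- match.arg(stage, cascadeStages())
    as.integer(floor(mean(x@counts[stage, ])))
})

#' @rdname FilterTrace-class
#' @export
setMethod("as.data.frame", "FilterTrace", function(x, ...) {
    m <- x@counts
    data.frame(family = rep(colnames(m), each = nrow(m)),
               stage = rep(rownames(m), times = ncol(m)),
               survivors = as.vector(m), stringsAsFactors = FALSE)
})
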