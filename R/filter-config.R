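#' FilterConfig: thresholds of the seven-stage cascade
#'
#' Holds every tunable of the annotation cascade. The defaults encode
#' the published thresholds for dominant-model exome prioritization:
#'
#' \describe{
#'   \item{effectKeep}{effect categories retained by stage 1
#'     (default [defaultEffectKeep()]).}
#'   \item{impactKeep}{impact categories retained by stage 2
#'     (default `HIGH`, `MODERATE`).}
#'   \item{siftDamagingMax}{SIFT scores strictly below this are
#'     damaging (default 0.05, exclusive).}
#'   \item{polyphenDamagingMin}{PolyPhen2 HDIV scores at or above this
#'     are at least "possibly damaging" (default 0.453, inclusive).}
#'   \item{phylopMin}{PhyloP must exceed this (default 0, exclusive):
#'     positive scores mark conserved sites.}
#'   \item{phastconsMin}{PhastCons must reach this (default 0.2,
#'     inclusive).}
#'   \item{afGlobalMax}{global (1000-genomes-style) allele frequency
#'     must be strictly below this for the rare tier (default 0.01).}
#'   \item{afKoreanMax}{population-reference (Korean) MAF must be
#'     strictly below this for the rare tier (default 0.02).}
#'   \item{missingPasses}{named logical, one entry per score-based
#'     stage: whether a missing annotation passes that stage
#'     (default all `TRUE`, matching the "or unknown" reading of the
#'     frequency filters and the retention of score-less variants).}
#' }
#'
#' @param effectKeep,impactKeep Character vectors of retained
#'   categories; must be subsets of the declared vocabularies.
#' @param siftDamagingMax,polyphenDamagingMin,phastconsMin,afGlobalMax,afKoreanMax
#'   Thresholds in `[0, 1]`.
#' @param phylopMin Real threshold for PhyloP.
#' @param missingPasses Named logical vector over
#'   `c("deleteriousness", "phylop", "phastcons", "af_global",
#'   "af_korean")`.
#'
#' @return `filterConfig()` returns a validated `FilterConfig`.
#'
#' @examples
#' cfg <- filterConfig()
#' cfg@siftDamagingMax
#' strict <- filterConfig(afKoreanMax = 0.01)
#'
#' @aliases FilterConfig
#' @export filterConfig
#' @exportClass FilterConfig
setClass("FilterConfig",
         representation(effectKeep = "character", impactKeep = "character",
                        siftDamagingMax = "numeric",
                        polyphenDamagingMin = "numeric",
                        phylopMin = "numeric", phastconsMin = "numeric",
                        afGlobalMax = "numeric", afKoreanMax = "numeric",
                        missingPasses = "logical"))

.MISSING_STAGES <- c("deleteriousness", "phylop", "phastcons",
                     "af_global", "af_korean")

setValidity("FilterConfig", function(object) {
    msg <- character()
    badEff <- setdiff(object@effectKeep, effectVocabulary())
    if (length(badEff))
        msg <- c(msg, paste("effectKeep outside vocabulary:",
                            paste(badEff, collapse = ", ")))
    badImp <- setdiff(object@impactKeep, impactVocabulary())
    if (length(badImp))
        msg <- c(msg, paste("impactKeep outside vocabulary:",
                            paste(badImp, collapse = ", ")))
    for (s in c("siftDamagingMax", "polyphenDamagingMin", "phastconsMin",
                "afGlobalMax", "afKoreanMax")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            msg <- c(msg, paste0(s, " must be a single value in [0,1]"))
    }
    if (!setequal(names(object@missingPasses), .MISSING_STAGES))
        msg <- c(msg, paste("missingPasses must be named over:",
                            paste(.MISSING_STAGES, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' @rdname FilterConfig-class
filterConfig <- function(effectKeep = defaultEffectKeep(),
                         impactKeep = c("HIGH", "MODERATE"),
                         siftDamagingMax = 0.05,
                         polyphenDamagingMin = 0.453,
                         phylopMin = 0,
                         phastconsMin = 0.2,
                         afGlobalMax = 0.01,
                         afKoreanMax = 0.02,
                         missingPasses = setNames(rep(TRUE, 5), .MISSING_STAGES)) {
    new("FilterConfig", effectKeep = effectKeep, impactKeep = impactKeep,
        siftDamagingMax = siftDamagingMax,
        polyphenDamagingMin = polyphenDamagingMin,
        phylopMin = phylopMin, phastconsMin = phastconsMin,
        afGlobalMax = afGlobalMax, afKoreanMax = afKoreanMax,
        missingPasses = missingPasses[.MISSING_STAGES])
}

setMethod("show", "FilterConfig", function(object) {
    cat("FilterConfig\n")
    cat("  effectKeep:", paste(object@effectKeep, collapse = ", "), "\n")
    cat("  impactKeep:", paste(object@impactKeep, collapse = ", "), "\n")
    cat(sprintf("  SIFT < %g | PolyPhen2 >= %g ; PhyloP > %g ; PhastCons >= %g\n",
                object@siftDamagingMax, object@polyphenDamagingMin,
                object@phylopMin, object@phastconsMin))
    cat(sprintf("  AF(global) < %g ; AF(Korean) < %g\n",
                object@afGlobalMax, object@afKoreanMax))
    cat("  missing annotation passes:",
        paste(names(object@missingPasses)[object@missingPasses],
              collapse = ", "), "\n")
})

#' Serialize a FilterConfig to and from a plain list
#'
#' The list form is what goes into YAML/JSON config files and into the
#' config echo of every [RunReport].
#'
#' @param cfg A `FilterConfig`.
#' @param x A named list as produced by `filterConfigToList()` (missing
#'   entries fall back to the defaults).
#' @return A plain named list, or a `FilterConfig`.
#' @examples
#' identical(filterConfigFromList(filterConfigToList(filterConfig())),
#'           filterConfig())
#' @export
filterConfigToList <- function(cfg) {
    list(effectKeep = cfg@effectKeep, impactKeep = cfg@impactKeep,
         siftDamagingMax = cfg@siftDamagingMax,
         polyphenDamagingMin = cfg@polyphenDamagingMin,
         phylopMin = cfg@phylopMin, phastconsMin = cfg@phastconsMin,
         afGlobalMax = cfg@afGlobalMax, afKoreanMax = cfg@afKoreanMax,
         missingPasses = as.list(cfg@missingPasses))
}

#' @rdname filterConfigToList
#' @export
filterConfigFromList <- function(x) {
    stopifnot(is.list(x))
    defaults <- filterConfigToList(filterConfig())
    merged <- utils::modifyList(defaults, x)
    mp <- unlist(merged$missingPasses)
    filterConfig(effectKeep = unlist(merged$effectKeep),
                 impactKeep = unlist(merged$impactKeep),
                 siftDamagingMax = merged$siftDamagingMax,
                 polyphenDamagingMin = merged$polyphenDamagingMin,
                 phylopMin = merged$phylopMin,
                 phastconsMin = merged$phastconsMin,
                 afGlobalMax = merged$afGlobalMax,
                 afKoreanMax = merged$afKoreanMax,
                 missingPasses = mp)
}
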