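#' Dominant-model co-segregation of one variant in one family
#'
#' Tests the strict dominant pattern used for family-based discovery:
#' every affected member of the family is heterozygous and every
#' unaffected member is homozygous for the reference allele. Any
#' missing genotype in the family fails the test (prioritization
#' favours specificity). With `allowHomAlt = TRUE` affected members may
#' also be homozygous alternate (a conventional dominant carrier
#' model); the strict heterozygous-only default matches the genotype
#' pattern reported in small dominant pedigrees.
#'
#' @param key Variant key (`chrom:pos_ref/alt` row name).
#' @param cohort A [VariantCohort] containing all family samples.
#' @param ped A [Pedigree].
#' @param family Family id in `ped`.
#' @param allowHomAlt Logical; accept `HOM_ALT` affected members.
#' @param model `"dominant"` (default) or `"recessive"`. Under the
#'   recessive model affected members must be `HOM_ALT` and unaffected
#'   members must carry at most one alternate allele (`HOM_REF` or
#'   `HET`). The recessive mode exists for model exploration and is
#'   not part of the discovery cascade.
#' @return `TRUE` iff the family genotypes follow the model pattern.
#'
#' @examples
#' sim <- generateFamilyExome(simulationConfig(nBackgroundVariants = 50,
#'                                             seed = 1))
#' key <- sim$truth$key[1]
#' dominantSegregation(key, sim$cohort, sim$pedigree,
#'                     families(sim$pedigree)[1])
#'
#' @export
dominantSegregation <- function(key, cohort, ped, family,
                                allowHomAlt = FALSE,
                                model = c("dominant", "recessive")) {
    model <- match.arg(model)
    if (!key %in% rownames(cohort))
        stop("unknown variant key: '", key, "'")
    aff <- affectedIds(ped, family)
    unaff <- unaffectedIds(ped, family)
    missingSamples <- setdiff(c(aff, unaff), colnames(cohort))
    if (length(missingSamples))
        stop("family '", family, "' sample(s) absent from cohort: ",
             paste(missingSamples, collapse = ", "))
    g <- calls(cohort)[key, , drop = TRUE]
    gAff <- g[aff]
    gUnaff <- g[unaff]
    if (any(gAff == "MISSING") || any(gUnaff == "MISSING"))
        return(FALSE)
    if (model == "dominant") {
        affOk <- if (allowHomAlt) gAff %in% c("HET", "HOM_ALT")
                 else gAff == "HET"
        all(affOk) && all(gUnaff == "HOM_REF")
    } else {
        all(gAff == "HOM_ALT") && all(gUnaff %in% c("HOM_REF", "HET"))
    }
}

#' Per-family segregating variant sets
#'
#' Evaluates [dominantSegregation()] for every variant in every family
#' of the pedigree. Families are independent: a variant may segregate
#' in any subset of them.
#'
#' @inheritParams dominantSegregation
#' @param familyIds Families to evaluate (default: all families in
#'   `ped`). Useful when the cohort holds only a subset of the
#'   pedigree's samples.
#' @return Named list, family id -> character vector of variant keys
#'   that co-segregate with affection status in that family.
#'
#' @examples
#' sim <- generateFamilyExome(simulationConfig(nBackgroundVariants = 100,
#'                                             seed = 3))
#' segs <- applySegregation(sim$cohort, sim$pedigree)
#' vapply(segs, length, integer(1))
#'
#' @export
applySegregation <- function(cohort, ped, allowHomAlt = FALSE,
                             model = c("dominant", "recessive"),
                             familyIds = NULL) {
    model <- match.arg(model)
    famIds <- familyIds %||% families(ped)
    g <- calls(cohort)
    out <- list()
    for (fam in famIds) {
        aff <- affectedIds(ped, fam)
        unaff <- unaffectedIds(ped, fam)
        missingSamples <- setdiff(c(aff, unaff), colnames(g))
        if (length(missingSamples))
            stop("family '", fam, "' sample(s) absent from cohort: ",
                 paste(missingSamples, collapse = ", "))
        if (nrow(g) == 0L) {
            out[[fam]] <- character()
            next
        }
        gAff <- g[, aff, drop = FALSE]
        gUnaff <- g[, unaff, drop = FALSE]
        if (model == "dominant") {
            affOk <- if (allowHomAlt)
                rowSums(gAff == "HET" | gAff == "HOM_ALT") == length(aff)
            else rowSums(gAff == "HET") == length(aff)
            unaffOk <- rowSums(gUnaff == "HOM_REF") == length(unaff)
        } else {
            affOk <- rowSums(gAff == "HOM_ALT") == length(aff)
            unaffOk <- rowSums(gUnaff == "HOM_REF" | gUnaff == "HET") ==
                length(unaff)
        }
        out[[fam]] <- rownames(g)[affOk & unaffOk]
    }
    out
}
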