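## Central S4 containers. VariantCohort is a RangedSummarizedExperiment
## whose rowRanges carry one row per ALT allele with the annotation
## columns the cascade consumes, and whose single assay holds categorical
## genotype calls.

ANNOTATION_COLUMNS <- c("ref", "alt", "rsid", "gene", "effect", "impact",
                        "aaChange", "sift", "polyphen2Hdiv", "phylop",
                        "phastcons", "afGlobal", "afEastAsian", "afKorean")

## score columns bounded to [0,1]; phylop is unbounded
UNIT_INTERVAL_COLUMNS <- c("sift", "polyphen2Hdiv", "phastcons",
                           "afGlobal", "afEastAsian", "afKorean")

#' VariantCohort: annotated variants with genotype calls
#'
#' A \linkS4class{RangedSummarizedExperiment} subclass holding one row
#' per called ALT allele and one column per sequenced sample. The
#' `rowData` carries the annotation fields consumed by the filter
#' cascade (gene symbol, snpEff-style effect and impact, SIFT,
#' PolyPhen2 HDIV, PhyloP, PhastCons, and global / East-Asian / Korean
#' allele frequencies); a missing annotation is `NA`, never zero. The
#' single assay `"calls"` stores genotype calls as one of
#' `"HOM_REF"`, `"HET"`, `"HOM_ALT"`, `"MISSING"`.
#'
#' Row names are variant keys of the form `chrom:pos_ref/alt`; gene
#' overlap and tier bookkeeping are keyed on these, never on rsIDs
#' (published rsIDs are treated as opaque, possibly inconsistent
#' labels).
#'
#' @param rowRanges A [GenomicRanges::GRanges] with one range per ALT
#'   allele and mcols covering the annotation columns (`ref`, `alt`,
#'   `rsid`, `gene`, `effect`, `impact`, `aaChange`, `sift`,
#'   `polyphen2Hdiv`, `phylop`, `phastcons`, `afGlobal`, `afEastAsian`,
#'   `afKorean`). Missing optional columns are filled with `NA`.
#' @param calls Character matrix of genotype calls,
#'   `length(rowRanges)` rows by `n` samples, values in [callStates()].
#' @param sampleData Optional `DataFrame` of per-sample covariates
#'   (e.g. family and affection status), one row per column of `calls`.
#' @param x A `VariantCohort`.
#'
#' @return `VariantCohort()` returns a validated `VariantCohort`.
#'   `calls()` returns the genotype call matrix; `variantKeys()` the
#'   vector of `chrom:pos_ref/alt` row keys.
#'
#' @examples
#' gr <- GenomicRanges::GRanges("chr3", IRanges::IRanges(130361856, width = 1))
#' S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
#'     ref = "G", alt = "A", rsid = "rs16830494", gene = "COL6A6",
#'     effect = "NON_SYNONYMOUS_CODING", impact = "MODERATE",
#'     aaChange = "R1739Q", sift = 0.04, polyphen2Hdiv = 0.272,
#'     phylop = 1.703, phastcons = 0.995, afGlobal = 0.12,
#'     afEastAsian = 0.19, afKorean = 0.188)
#' vc <- VariantCohort(gr, matrix("HET", 1, 1, dimnames = list(NULL, "A1")))
#' variantKeys(vc)
#' calls(vc)
#'
#' @aliases VariantCohort calls variantKeys
#' @export VariantCohort
#' @exportClass VariantCohort
setClass("VariantCohort",
         contains = "RangedSummarizedExperiment")

.validVariantCohort <- function(object) {
    msg <- character()
    rd <- rowData(object)
    missing_cols <- setdiff(ANNOTATION_COLUMNS, colnames(rd))
    if (length(missing_cols))
        return(paste("missing rowData column(s):",
                     paste(missing_cols, collapse = ", ")))
    if (!"calls" %in% names(assays(object)))
        return("assay 'calls' is required")
    if (nrow(object)) {
        if (any(start(rowRanges(object)) < 1L))
            msg <- c(msg, "positions must be >= 1")
        same <- !is.na(rd$ref) & !is.na(rd$alt) & rd$ref == rd$alt
        if (any(same))
            msg <- c(msg, "ref and alt alleles must differ")
        bad_eff <- setdiff(unique(rd$effect), effectVocabulary())
        if (length(bad_eff))
            msg <- c(msg, paste("unknown effect token(s):",
                                paste(bad_eff, collapse = ", ")))
        bad_imp <- setdiff(unique(rd$impact), impactVocabulary())
        if (length(bad_imp))
            msg <- c(msg, paste("unknown impact token(s):",
                                paste(bad_imp, collapse = ", ")))
        for (col in UNIT_INTERVAL_COLUMNS) {
            v <- rd[[col]]
            if (any(!is.na(v) & (v < 0 | v > 1)))
                msg <- c(msg, paste0("'", col, "' outside [0,1]"))
        }
        cl <- assay(object, "calls")
        bad_call <- setdiff(unique(as.vector(cl)), callStates())
        if (length(bad_call))
            msg <- c(msg, paste("unknown genotype call(s):",
                                paste(bad_call, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
}
setValidity("VariantCohort", .validVariantCohort)

#' Build the canonical variant key for annotated ranges
#'
#' @param gr A `GRanges` with `ref` and `alt` mcols.
#' @return Character vector `chrom:pos_ref/alt`.
#' @keywords internal
makeVariantKeys <- function(gr) {
    if (!length(gr))
        return(character())
    paste0(as.character(seqnames(gr)), ":", start(gr), "_",
           mcols(gr)$ref, "/", mcols(gr)$alt)
}

VariantCohort <- function(rowRanges, calls, sampleData = NULL) {
    if (is.null(dim(calls)))
        calls <- matrix(calls, nrow = length(rowRanges))
    for (col in setdiff(ANNOTATION_COLUMNS, colnames(mcols(rowRanges)))) {
        mcols(rowRanges)[[col]] <- rep(
            if (col %in% c(UNIT_INTERVAL_COLUMNS, "phylop"))
                NA_real_ else NA_character_,
            length(rowRanges))
    }
    names(rowRanges) <- makeVariantKeys(rowRanges)
    rownames(calls) <- names(rowRanges)
    if (is.null(sampleData))
        sampleData <- DataFrame(row.names = colnames(calls))
    se <- SummarizedExperiment(assays = SimpleList(calls = calls),
                               rowRanges = rowRanges,
                               colData = sampleData)
    new("VariantCohort", se)
}

#' @rdname VariantCohort-class
#' @export
setMethod("calls", "VariantCohort", function(x) assay(x, "calls"))

#' @rdname VariantCohort-class
#' @export
setMethod("variantKeys", "VariantCohort", function(x) rownames(x))

setMethod("show", "VariantCohort", function(object) {
    cat("VariantCohort with", nrow(object), "variant(s) x",
        ncol(object), "sample(s)\n")
    if (nrow(object)) {
        genes <- unique(rowData(object)$gene)
        cat("genes:", length(genes[!is.na(genes)]), "\n")
    }
    callNextMethod()
})

#' Pedigree: family membership and affection status
#'
#' Stores, per sample, the family identifier, a logical affection
#' status and a free-text role label ("father", "child", ...). Every
#' sample id must be unique. A family with no affected or no unaffected
#' member is legal but triggers a validation warning at construction
#' (the dominant segregation test is vacuous in such families).
#'
#' @param family Character vector of family ids.
#' @param sample Character vector of unique sample ids.
#' @param affected Logical vector of affection status.
#' @param role Optional character vector of role labels.
#' @param x,object A `Pedigree`.
#'
#' @return `Pedigree()` returns a validated `Pedigree`. `families()`
#'   lists family ids; `familyMembers()`, `affectedIds()` and
#'   `unaffectedIds()` return sample ids of one family.
#'
#' @examples
#' ped <- Pedigree(family = rep("FamA", 4),
#'                 sample = c("A1", "A2", "A3", "A4"),
#'                 affected = c(TRUE, TRUE, FALSE, FALSE),
#'                 role = c("father", "child", "mother", "child"))
#' affectedIds(ped, "FamA")
#'
#' @aliases Pedigree families familyMembers affectedIds unaffectedIds
#' @export Pedigree
#' @exportClass Pedigree
setClass("Pedigree",
         representation(family = "character", sample = "character",
                        affected = "logical", role = "character"))

setValidity("Pedigree", function(object) {
    msg <- character()
    n <- length(object@sample)
    if (length(object@family) != n || length(object@affected) != n ||
        length(object@role) != n)
        msg <- c(msg, "family, sample, affected and role lengths differ")
    if (anyDuplicated(object@sample))
        msg <- c(msg, paste("duplicate sample id(s):",
                            paste(unique(object@sample[duplicated(object@sample)]),
                                  collapse = ", ")))
    if (any(is.na(object@affected)))
        msg <- c(msg, "affection status must be TRUE or FALSE, not NA")
    if (length(msg)) msg else TRUE
})

Pedigree <- function(family, sample, affected, role = rep("", length(sample))) {
    obj <- new("Pedigree", family = as.character(family),
               sample = as.character(sample),
               affected = as.logical(affected), role = as.character(role))
    for (fam in unique(obj@family)) {
        aff <- obj@affected[obj@family == fam]
        if (!any(aff))
            warning("family '", fam, "' has no affected member", call. = FALSE)
        if (all(aff))
            warning("family '", fam, "' has no unaffected member", call. = FALSE)
    }
    obj
}

#' @rdname Pedigree-class
#' @export
setMethod("families", "Pedigree", function(x) unique(x@family))

#' @rdname Pedigree-class
#' @export
setMethod("familyMembers", "Pedigree", function(x, family) {
    .checkFamily(x, family)
    x@sample[x@family == family]
})

#' @rdname Pedigree-class
#' @export
setMethod("affectedIds", "Pedigree", function(x, family) {
    .checkFamily(x, family)
    x@sample[x@family == family & x@affected]
})

#' @rdname Pedigree-class
#' @export
setMethod("unaffectedIds", "Pedigree", function(x, family) {
    .checkFamily(x, family)
    x@sample[x@family == family & !x@affected]
})

.checkFamily <- function(ped, family) {
    if (!family %in% ped@family)
        stop("unknown family id: '", family, "'", call. = FALSE)
}

#' @rdname Pedigree-class
#' @export
setMethod("length", "Pedigree", function(x) length(x@sample))

setMethod("show", "Pedigree", function(object) {
    cat("Pedigree:", length(object@sample), "sample(s) in",
        length(unique(object@family)), "family(ies)\n")
    for (fam in unique(object@family)) {
        sel <- object@family == fam
        cat("  ", fam, ": ", sum(object@affected[sel]), " affected / ",
            sum(!object@affected[sel]), " unaffected\n", sep = "")
    }
})

#' @rdname Pedigree-class
#' @export
setMethod("as.data.frame", "Pedigree", function(x, ...) {
    data.frame(family = x@family, sample = x@sample,
               affected = x@affected, role = x@role,
               stringsAsFactors = FALSE)
})

#' FilterTrace: per-stage survivor counts of the cascade
#'
#' The bookkeeping object of the filter cascade: an integer matrix of
#' surviving variant counts, one row per cascade stage (in cascade
#' order: `raw`, `effect`, `impact`, `deleteriousness`, `phylop`,
#' `phastcons`, `af_global`, `af_korean`) and one column per family.
#' `raw` is the count entering stage 1, i.e. after segregation
#' pre-filtering. Counts are non-increasing down each column; the
#' validity method enforces this.
#'
#' @param counts Integer matrix, stages x families, with stage row
#'   names in cascade order and family column names.
#' @param x,object A `FilterTrace`.
#'
#' @return `FilterTrace()` returns a validated trace. `traceCounts()`
#'   returns the stage x family matrix; `traceStages()` the stage names
#'   in cascade order.
#'
#' @examples
#' m <- matrix(c(100L, 60L, 50L, 40L, 35L, 30L, 10L, 8L), ncol = 1,
#'             dimnames = list(cascadeStages(), "FamA"))
#' tr <- FilterTrace(m)
#' summarizeTrace(tr, "phastcons")
#'
#' @aliases FilterTrace traceCounts traceStages
#' @export FilterTrace
#' @exportClass FilterTrace
setClass("FilterTrace", representation(counts = "matrix"))

#' @rdname FilterTrace-class
#' @export
cascadeStages <- function() {
    c("raw", "effect", "impact", "deleteriousness", "phylop",
      "phastcons", "af_global", "af_korean")
}

setValidity("FilterTrace", function(object) {
    m <- object@counts
    if (!identical(rownames(m), cascadeStages()))
        return(paste("trace rows must be the cascade stages:",
                     paste(cascadeStages(), collapse = " > ")))
    if (!is.numeric(m) || any(is.na(m)) || any(m < 0))
        return("trace counts must be non-negative and non-missing")
    if (ncol(m) && any(apply(m, 2, function(x) any(diff(x) > 0))))
        return("survivor counts must be non-increasing along the cascade")
    TRUE
})

FilterTrace <- function(counts) {
    storage.mode(counts) <- "integer"
    new("FilterTrace", counts = counts)
}

#' @rdname FilterTrace-class
#' @export
setMethod("traceCounts", "FilterTrace", function(x) x@counts)

#' @rdname FilterTrace-class
#' @export
setMethod("traceStages", "FilterTrace", function(x) rownames(x@counts))

setMethod("show", "FilterTrace", function(object) {
    cat("FilterTrace over", ncol(object@counts), "family(ies)\n")
    print(object@counts)
})

#' CaseControlCounts: genotype counts at one SNP
#'
#' Genotype counts for cases and controls at a single biallelic SNP,
#' the input to the association module. Counts are named
#' `HOM_REF`, `HET`, `HOM_ALT` and refer to the alt allele.
#'
#' @param snp SNP identifier.
#' @param case,control Named integer vectors of genotype counts with
#'   names `HOM_REF`, `HET`, `HOM_ALT`.
#' @param refAllele,altAllele Allele labels used in reports.
#' @param x,object A `CaseControlCounts`.
#'
#' @return `CaseControlCounts()` returns a validated object;
#'   `caseCounts()`/`controlCounts()` return the named count vectors.
#'
#' @examples
#' cc <- CaseControlCounts("rs59021909",
#'     case = c(HOM_REF = 89L, HET = 21L, HOM_ALT = 2L),
#'     control = c(HOM_REF = 47L, HET = 14L, HOM_ALT = 0L),
#'     refAllele = "C", altAllele = "T")
#' genotypeToAlleleCounts(caseCounts(cc))
#'
#' @aliases CaseControlCounts caseCounts controlCounts
#' @export CaseControlCounts
#' @exportClass CaseControlCounts
setClass("CaseControlCounts",
         representation(snp = "character", case = "integer",
                        control = "integer", refAllele = "character",
                        altAllele = "character"))

.GENO_NAMES <- c("HOM_REF", "HET", "HOM_ALT")

setValidity("CaseControlCounts", function(object) {
    msg <- character()
    for (grp in c("case", "control")) {
        v <- slot(object, grp)
        if (!identical(names(v), .GENO_NAMES))
            msg <- c(msg, paste(grp, "counts must be named HOM_REF, HET, HOM_ALT"))
        else if (any(is.na(v)) || any(v < 0))
            msg <- c(msg, paste(grp, "counts must be non-negative integers"))
    }
    if (length(msg)) msg else TRUE
})

CaseControlCounts <- function(snp, case, control,
                              refAllele = "REF", altAllele = "ALT") {
    new("CaseControlCounts", snp = as.character(snp),
        case = setNames(as.integer(case[.GENO_NAMES]), .GENO_NAMES),
        control = setNames(as.integer(control[.GENO_NAMES]), .GENO_NAMES),
        refAllele = refAllele, altAllele = altAllele)
}

#' @rdname CaseControlCounts-class
#' @export
setMethod("caseCounts", "CaseControlCounts", function(x) x@case)

#' @rdname CaseControlCounts-class
#' @export
setMethod("controlCounts", "CaseControlCounts", function(x) x@control)

setMethod("show", "CaseControlCounts", function(object) {
    cat("CaseControlCounts for", object@snp,
        sprintf("(%s>%s)\n", object@refAllele, object@altAllele))
    print(rbind(case = object@case, control = object@control))
})

#' AssociationResult: a 2x2 odds-ratio estimate
#'
#' One odds-ratio estimate under one genetic model, with its Woolf
#' 95 percent confidence interval and a flag recording whether the
#' Haldane-Anscombe zero-cell correction was applied. The 2x2 table is
#' oriented rows = (case, control), columns = (exposed, unexposed).
#'
#' @param object An `AssociationResult`.
#' @return Accessed via `as.data.frame()`, yielding columns `snp`,
#'   `model`, the four cell counts, `oddsRatio`, `ciLow`, `ciHigh`,
#'   `correctionApplied`.
#' @aliases AssociationResult
#' @exportClass AssociationResult
setClass("AssociationResult",
         representation(snp = "character", model = "character",
                        table = "matrix", oddsRatio = "numeric",
                        ciLow = "numeric", ciHigh = "numeric",
                        correctionApplied = "logical"))

setValidity("AssociationResult", function(object) {
    msg <- character()
    if (!identical(dim(object@table), c(2L, 2L)))
        msg <- c(msg, "table must be 2x2")
    if (!is.na(object@oddsRatio) && object@oddsRatio <= 0)
        msg <- c(msg, "odds ratio must be positive")
    if (!any(is.na(c(object@ciLow, object@ciHigh, object@oddsRatio))) &&
        (object@ciLow > object@oddsRatio || object@ciHigh < object@oddsRatio))
        msg <- c(msg, "confidence interval must bracket the odds ratio")
    if (length(msg)) msg else TRUE
})

setMethod("show", "AssociationResult", function(object) {
    cat(sprintf("AssociationResult %s [%s model]: OR = %.3f (95%% CI %.3f-%.3f)%s\n",
                object@snp, object@model, object@oddsRatio,
                object@ciLow, object@ciHigh,
                if (object@correctionApplied) " [Haldane-Anscombe corrected]" else ""))
})

#' @rdname AssociationResult-class
#' @export
setMethod("as.data.frame", "AssociationResult", function(x, ...) {
    data.frame(snp = x@snp, model = x@model,
               caseExposed = x@table[1, 1], caseUnexposed = x@table[1, 2],
               controlExposed = x@table[2, 1], controlUnexposed = x@table[2, 2],
               oddsRatio = x@oddsRatio, ciLow = x@ciLow, ciHigh = x@ciHigh,
               correctionApplied = x@correctionApplied,
               stringsAsFactors = FALSE)
})
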