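#' Default INFO-key mapping for annotated VCFs
#'
#' Maps the internal annotation field names onto the INFO keys of an
#' annotated VCF. Override individual entries when reading files
#' annotated with different key names (e.g. `dbNSFP_SIFT_score`).
#'
#' @return Named character vector: internal field -> INFO key.
#' @examples
#' keys <- defaultAnnotationKeys()
#' keys[["sift"]]
#' @export
defaultAnnotationKeys <- function() {
    c(gene = "GENE", effect = "EFFECT", impact = "IMPACT",
      aaChange = "AAC", sift = "SIFT", polyphen2Hdiv = "PP2HDIV",
      phylop = "PHYLOP", phastcons = "PHASTCONS",
      afGlobal = "AF_GLOBAL", afEastAsian = "AF_EAS",
      afKorean = "AF_KOR")
}

.CHAR_FIELDS <- c("gene", "effect", "impact", "aaChange")
.NUM_FIELDS <- c("sift", "polyphen2Hdiv", "phylop", "phastcons",
                 "afGlobal", "afEastAsian", "afKorean")

## pull one INFO column, replicated to the per-ALT expansion
.expandInfoField <- function(v, recIdx, altIdx) {
    if (is.list(v) || is(v, "List")) {
        vapply(seq_along(recIdx), function(i) {
            el <- v[[recIdx[i]]]
            if (length(el) >= altIdx[i]) el[altIdx[i]]
            else if (length(el)) el[1L]
            else NA
        }, FUN.VALUE = if (is(v, "NumericList")) numeric(1) else character(1))
    } else {
        v[recIdx]
    }
}

## map one diploid genotype string onto the k-th ALT allele
.mapGenotypes <- function(gt, recIdx, altIdx) {
    out <- matrix("MISSING", nrow = length(altIdx), ncol = ncol(gt),
                  dimnames = list(NULL, colnames(gt)))
    for (j in seq_len(ncol(gt))) {
        parts <- strsplit(gt[, j], "[/|]")
        out[, j] <- vapply(seq_along(altIdx), function(i) {
            al <- parts[[recIdx[i]]]
            if (any(al == ".") || !length(al)) return("MISSING")
            nAlt <- sum(al == as.character(altIdx[i]))
            if (nAlt >= 2L) "HOM_ALT" else if (nAlt == 1L) "HET" else "HOM_REF"
        }, character(1))
    }
    out
}

#' Read an annotated VCF into a VariantCohort
#'
#' Parses a VCF 4.x file whose INFO field carries per-variant
#' annotations (gene, snpEff-style effect and impact, SIFT, PolyPhen2
#' HDIV, PhyloP, PhastCons and population allele frequencies) together
#' with per-sample genotypes. Multi-allelic records are split into one
#' row per ALT allele before anything else; genotype strings are mapped
#' onto the four call states relative to that ALT allele (any `.`
#' allele gives `MISSING`). Missing annotations are stored as `NA`,
#' never as zero. Unknown effect or impact tokens are a hard error, as
#' is an annotation key absent from the VCF header.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param annotationKeys Named character vector mapping internal field
#'   names to INFO keys; see [defaultAnnotationKeys()]. Entries mapped
#'   to `NA` are skipped and left missing.
#' @return A [VariantCohort].
#'
#' @examples
#' sim <- generateFamilyExome(simulationConfig(nBackgroundVariants = 20,
#'                                             seed = 2),
#'                            outDir = tempfile())
#' vc <- readAnnotatedVcf(sim$vcfPaths[[1]])
#' vc
#'
#' @seealso [writeAnnotatedVcf()]
#' @export
readAnnotatedVcf <- function(path, annotationKeys = defaultAnnotationKeys()) {
    if (!file.exists(path))
        stop("VCF file not found: '", path, "'")
    vcf <- tryCatch(
        suppressWarnings(readVcf(path, genome = "unknown")),
        error = function(e)
            stop("malformed VCF '", path, "': ", conditionMessage(e),
                 call. = FALSE))
    annotationKeys <- annotationKeys[!is.na(annotationKeys)]
    headerKeys <- rownames(info(header(vcf)))
    absent <- setdiff(unname(annotationKeys), headerKeys)
    if (length(absent))
        stop("annotation key(s) not declared in VCF header: ",
             paste(absent, collapse = ", "))
    sampleIds <- colnames(vcf)
    nAlt <- elementNROWS(alt(vcf))
    if (length(vcf) == 0L || sum(nAlt) == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(ref = character(), alt = character(),
                               rsid = character())
        emptyCalls <- matrix(character(), nrow = 0, ncol = length(sampleIds),
                             dimnames = list(NULL, sampleIds))
        return(VariantCohort(gr, emptyCalls))
    }
    recIdx <- rep(seq_along(vcf), nAlt)
    altIdx <- unlist(lapply(nAlt, seq_len), use.names = FALSE)
    refChar <- as.character(ref(vcf))
    altChar <- vapply(seq_along(recIdx), function(i)
        as.character(alt(vcf)[[recIdx[i]]][altIdx[i]]), character(1))

    gr <- GRanges(seqnames(rowRanges(vcf))[recIdx],
                  IRanges(start(rowRanges(vcf))[recIdx],
                          end(rowRanges(vcf))[recIdx]))
    ## an absent ID round-trips as the key VariantAnnotation constructs
    ids <- rownames(vcf)
    constructed <- paste0(as.character(seqnames(rowRanges(vcf))), ":",
                          start(rowRanges(vcf)), "_", refChar, "/",
                          vapply(as.list(alt(vcf)), function(a)
                              paste(as.character(a), collapse = "/"),
                              character(1)))
    rsid <- ifelse(ids == "." | ids == constructed, NA_character_, ids)

    ann <- DataFrame(ref = refChar[recIdx], alt = altChar,
                     rsid = rsid[recIdx])
    infoData <- info(vcf)
    for (field in names(annotationKeys)) {
        v <- .expandInfoField(infoData[[annotationKeys[[field]]]],
                              recIdx, altIdx)
        if (field %in% .NUM_FIELDS) {
            v <- suppressWarnings(as.numeric(v))
        } else {
            v <- as.character(v)
            v[v == "."] <- NA_character_
        }
        ann[[field]] <- v
    }
    badEffect <- setdiff(unique(ann$effect[!is.na(ann$effect)]),
                         effectVocabulary())
    if (length(badEffect))
        stop("unknown effect token(s) in '", path, "': ",
             paste(badEffect, collapse = ", "))
    badImpact <- setdiff(unique(ann$impact[!is.na(ann$impact)]),
                         impactVocabulary())
    if (length(badImpact))
        stop("unknown impact token(s) in '", path, "': ",
             paste(badImpact, collapse = ", "))
    mcols(gr) <- ann
    gt <- geno(vcf)$GT
    if (is.null(gt))
        stop("VCF '", path, "' has no GT genotype field")
    VariantCohort(gr, .mapGenotypes(gt, recIdx, altIdx))
}

#' Write a VariantCohort to an annotated VCF
#'
#' Serializes a cohort back to VCF 4.2 with one (biallelic) record per
#' row, annotations in the INFO field under the configured keys, and
#' genotypes as a GT FORMAT column. Missing annotations are omitted
#' from INFO (and therefore read back as `NA`); `MISSING` calls become
#' `./.`. Reading the file with [readAnnotatedVcf()] reproduces the
#' cohort content field by field.
#'
#' @param cohort A [VariantCohort].
#' @param path Output path; a `.vcf` text file.
#' @param annotationKeys As in [readAnnotatedVcf()].
#' @return `path`, invisibly.
#' @seealso [readAnnotatedVcf()]
#' @export
writeAnnotatedVcf <- function(cohort, path,
                              annotationKeys = defaultAnnotationKeys()) {
    ann <- rowData(cohort)
    n <- nrow(cohort)
    rr <- GRanges(seqnames(rowRanges(cohort)),
                  IRanges(start(rowRanges(cohort)), width = 1L))
    names(rr) <- ifelse(is.na(ann$rsid), ".", ann$rsid)
    fx <- DataFrame(REF = DNAStringSet(if (n) ann$ref else character()),
                    ALT = CharacterList(as.list(if (n) ann$alt else character())),
                    QUAL = rep(NA_real_, n), FILTER = rep(".", n))
    infoDf <- DataFrame(row.names = seq_len(n))
    typeRow <- character()
    for (field in names(annotationKeys)) {
        infoDf[[annotationKeys[[field]]]] <- ann[[field]]
        typeRow <- c(typeRow,
                     if (field %in% .NUM_FIELDS) "Float" else "String")
    }
    hdr <- VCFHeader(samples = colnames(cohort))
    geno(hdr) <- DataFrame(Number = "1", Type = "String",
                           Description = "Genotype", row.names = "GT")
    info(hdr) <- DataFrame(Number = rep("1", length(annotationKeys)),
                           Type = typeRow,
                           Description = paste("Annotation:",
                                               names(annotationKeys)),
                           row.names = unname(annotationKeys))
    meta(hdr) <- DataFrameList(
        fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
    gtCode <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1",
                MISSING = "./.")
    gt <- matrix(gtCode[calls(cohort)], nrow = n,
                 dimnames = list(NULL, colnames(cohort)))
    vcf <- VCF(rowRanges = rr,
               colData = DataFrame(Samples = seq_len(ncol(cohort)),
                                   row.names = colnames(cohort)),
               exptData = list(header = hdr), fixed = fx,
               info = infoDf, geno = SimpleList(GT = gt),
               collapsed = TRUE)
    writeVcf(vcf, path)
    invisible(path)
}
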