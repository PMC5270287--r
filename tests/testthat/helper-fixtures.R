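## Shared builders for small in-code fixtures.

fixturePath <- function(f) {
    p <- system.file("extdata", f, package = "pedexome")
    if (!nzchar(p)) stop("fixture not found: ", f)
    p
}

## annotation DataFrame with NA defaults, overridable per column
annFrame <- function(n = 1L, ...) {
    df <- S4Vectors::DataFrame(
        ref = rep("G", n), alt = rep("A", n), rsid = rep(NA_character_, n),
        gene = rep(NA_character_, n),
        effect = rep("NON_SYNONYMOUS_CODING", n),
        impact = rep("MODERATE", n), aaChange = rep(NA_character_, n),
        sift = rep(NA_real_, n), polyphen2Hdiv = rep(NA_real_, n),
        phylop = rep(NA_real_, n), phastcons = rep(NA_real_, n),
        afGlobal = rep(NA_real_, n), afEastAsian = rep(NA_real_, n),
        afKorean = rep(NA_real_, n))
    over <- list(...)
    for (nm in names(over)) df[[nm]] <- over[[nm]]
    df
}

## cohort with explicit genotype calls (rows auto-placed on chr1)
makeCohort <- function(calls, ann = NULL, sampleData = NULL) {
    n <- nrow(calls)
    if (is.null(colnames(calls)))
        colnames(calls) <- paste0("A", seq_len(ncol(calls)))
    if (is.null(ann)) ann <- annFrame(n)
    gr <- GenomicRanges::GRanges(rep("chr1", n),
                                 IRanges::IRanges(seq_len(n) * 1000L,
                                                  width = 1L))
    S4Vectors::mcols(gr) <- ann
    VariantCohort(gr, calls, sampleData = sampleData)
}

## standard 2 affected + 2 unaffected test family
quadPedigree <- function(fam = "FamA", prefix = "A") {
    Pedigree(family = rep(fam, 4),
             sample = paste0(prefix, 1:4),
             affected = c(TRUE, TRUE, FALSE, FALSE),
             role = c("father", "child", "mother", "child"))
}

## cohort from the published candidate-variant table, with the strict
## dominant genotype pattern planted for one family's samples
cohortFromTable <- function(tab, samples = paste0("A", 1:4),
                            affected = c(TRUE, TRUE, FALSE, FALSE)) {
    gr <- GenomicRanges::GRanges(tab$chrom,
                                 IRanges::IRanges(tab$pos, width = 1L))
    S4Vectors::mcols(gr) <- annFrame(
        nrow(tab), gene = tab$gene, effect = tab$effect,
        impact = tab$impact, sift = tab$sift,
        polyphen2Hdiv = tab$polyphen2Hdiv, phylop = tab$phylop,
        phastcons = tab$phastcons, afGlobal = tab$afGlobal,
        afEastAsian = tab$afEastAsian, afKorean = tab$afKorean,
        rsid = tab$rsid, aaChange = tab$aaChange)
    callRow <- ifelse(affected, "HET", "HOM_REF")
    calls <- matrix(rep(callRow, each = nrow(tab)), nrow = nrow(tab),
                    dimnames = list(NULL, samples))
    VariantCohort(gr, calls)
}

## one-pass scalar reference filter, deliberately independent of the
## vectorized cascade implementation
bruteForceCascade <- function(ann, cfg = filterConfig()) {
    stages <- matrix(FALSE, nrow = nrow(ann), ncol = 7L)
    for (i in seq_len(nrow(ann))) {
        a <- as.list(ann[i, , drop = FALSE])
        ok1 <- !is.na(a$effect) && a$effect %in% cfg@effectKeep
        ok2 <- ok1 && !is.na(a$impact) && a$impact %in% cfg@impactKeep
        del <- TRUE
        if (!is.na(a$sift) && !is.na(a$polyphen2Hdiv) &&
            a$sift >= cfg@siftDamagingMax &&
            a$polyphen2Hdiv < cfg@polyphenDamagingMin)
            del <- FALSE
        ok3 <- ok2 && del
        ok4 <- ok3 && (is.na(a$phylop) || a$phylop > cfg@phylopMin)
        ok5 <- ok4 && (is.na(a$phastcons) || a$phastcons >= cfg@phastconsMin)
        ok6 <- ok5 && (is.na(a$afGlobal) || a$afGlobal < cfg@afGlobalMax)
        ok7 <- ok6 && (is.na(a$afKorean) || a$afKorean < cfg@afKoreanMax)
        stages[i, ] <- c(ok1, ok2, ok3, ok4, ok5, ok6, ok7)
    }
    colnames(stages) <- cascadeStages()[-1]
    stages
}

## minimal hand-written annotated VCF text
writeTestVcf <- function(records, path,
                         samples = c("S1", "S2", "S3", "S4")) {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
             "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"e\">",
             "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"i\">",
             "##INFO=<ID=AAC,Number=1,Type=String,Description=\"a\">",
             "##INFO=<ID=SIFT,Number=1,Type=Float,Description=\"s\">",
             "##INFO=<ID=PP2HDIV,Number=1,Type=Float,Description=\"p\">",
             "##INFO=<ID=PHYLOP,Number=1,Type=Float,Description=\"c\">",
             "##INFO=<ID=PHASTCONS,Number=1,Type=Float,Description=\"c\">",
             "##INFO=<ID=AF_GLOBAL,Number=1,Type=Float,Description=\"f\">",
             "##INFO=<ID=AF_EAS,Number=1,Type=Float,Description=\"f\">",
             "##INFO=<ID=AF_KOR,Number=1,Type=Float,Description=\"f\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", samples),
                   collapse = "\t"))
    writeLines(c(hdr, records), path)
    path
}
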