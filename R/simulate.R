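#' SimulationConfig: parameters of the synthetic cohort generator
#'
#' Describes a synthetic study: a small number of nuclear families
#' with a fixed affected/unaffected split, a background of exome-like
#' annotated variants whose genotypes are drawn independently of
#' affection status, one planted causal variant per family that
#' segregates perfectly and passes every cascade stage by
#' construction, and an optional case-control block drawn under
#' Hardy-Weinberg proportions.
#'
#' Key defaults emulate the study design the package targets: 3
#' families of 2 affected + 2 unaffected members; 20,000 background
#' coding-region variants per cohort drawn from a shared pool of 5,000
#' gene symbols; a planted gene on chr3 with one variant position per
#' family; a validation cohort of 112 cases and 61 controls typed at
#' three SNPs whose case/control alt-allele frequencies match the
#' published frequency table.
#'
#' Annotation scores are two-component mixtures (a benign bulk plus a
#' damaging/conserved tail) so that every cascade stage removes a
#' nontrivial fraction of background variants; `missingnessRate`
#' controls the fraction of scores stored as `NA`. Background allele
#' frequencies follow a Beta(`afShape1`, `afShape2`) distribution,
#' skewed toward rare variants.
#'
#' @param nFamilies Number of families.
#' @param affectedPerFamily,unaffectedPerFamily Family composition.
#' @param nBackgroundVariants Background variants in the cohort.
#' @param genePoolSize Number of distinct background gene symbols
#'   (shared across families, so gene-level overlap can arise by
#'   chance).
#' @param effectProbs Named probability vector over
#'   [effectVocabulary()] categories for background variants.
#' @param impactFidelity Probability that a background variant's
#'   impact is the canonical snpEff impact of its effect (the
#'   remainder is spread over the other impact classes).
#' @param missingnessRate Per-score missingness probability.
#' @param damagingFracSift,damagingFracPolyphen Mixture weight of the
#'   damaging score component.
#' @param conservedFracPhylop,conservedFracPhastcons Mixture weight of
#'   the conserved score component.
#' @param afShape1,afShape2 Beta parameters of the background
#'   population allele-frequency distribution.
#' @param plantedGene,plantedChrom,plantedPositions Planted causal
#'   gene symbol, its chromosome, and one variant position per family.
#' @param plantedAnnotation Named list of annotation values for the
#'   planted variants; must satisfy every threshold of the
#'   [FilterConfig] in force (validated at generation time).
#' @param ccSnps,ccCaseFreq,ccControlFreq,ccRefAlleles,ccAltAlleles
#'   Case-control block: SNP ids, per-group alt-allele frequencies and
#'   allele labels.
#' @param nCases,nControls Case-control group sizes.
#' @param seed Single global seed; every stochastic draw of the
#'   generators flows from it.
#'
#' @return `simulationConfig()` returns a validated
#'   `SimulationConfig`.
#'
#' @examples
#' cfg <- simulationConfig(nBackgroundVariants = 500, seed = 42)
#' cfg@plantedGene
#'
#' @aliases SimulationConfig
#' @export simulationConfig
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nFamilies = "integer", affectedPerFamily = "integer",
                        unaffectedPerFamily = "integer",
                        nBackgroundVariants = "integer",
                        genePoolSize = "integer", effectProbs = "numeric",
                        impactFidelity = "numeric",
                        missingnessRate = "numeric",
                        damagingFracSift = "numeric",
                        damagingFracPolyphen = "numeric",
                        conservedFracPhylop = "numeric",
                        conservedFracPhastcons = "numeric",
                        afShape1 = "numeric", afShape2 = "numeric",
                        plantedGene = "character", plantedChrom = "character",
                        plantedPositions = "numeric",
                        plantedAnnotation = "list",
                        ccSnps = "character", ccCaseFreq = "numeric",
                        ccControlFreq = "numeric",
                        ccRefAlleles = "character",
                        ccAltAlleles = "character",
                        nCases = "integer", nControls = "integer",
                        seed = "integer"))

.defaultEffectProbs <- function() {
    c(NON_SYNONYMOUS_CODING = 0.30, SYNONYMOUS_CODING = 0.28,
      INTRON = 0.15, UTR_3_PRIME = 0.06, UTR_5_PRIME = 0.04,
      UPSTREAM = 0.04, DOWNSTREAM = 0.04, INTERGENIC = 0.03,
      STOP_GAINED = 0.01, FRAME_SHIFT = 0.01,
      SPLICE_SITE_ACCEPTOR = 0.005, SPLICE_SITE_DONOR = 0.005,
      CODON_CHANGE = 0.01, CODON_INSERTION = 0.005,
      CODON_DELETION = 0.005, STOP_LOST = 0.002, START_LOST = 0.002,
      START_GAINED = 0.006)
}

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nFamilies < 1L)
        msg <- c(msg, "nFamilies must be >= 1")
    if (object@affectedPerFamily < 1L || object@unaffectedPerFamily < 1L)
        msg <- c(msg, "each family needs >= 1 affected and >= 1 unaffected")
    bad <- setdiff(names(object@effectProbs), effectVocabulary())
    if (length(bad))
        msg <- c(msg, paste("effectProbs outside vocabulary:",
                            paste(bad, collapse = ", ")))
    if (abs(sum(object@effectProbs) - 1) > 1e-6)
        msg <- c(msg, "effectProbs must sum to 1")
    for (s in c("impactFidelity", "missingnessRate", "damagingFracSift",
                "damagingFracPolyphen", "conservedFracPhylop",
                "conservedFracPhastcons"))
        if (slot(object, s) < 0 || slot(object, s) > 1)
            msg <- c(msg, paste(s, "must lie in [0,1]"))
    if (length(object@plantedPositions) != object@nFamilies)
        msg <- c(msg, "plantedPositions needs one position per family")
    nSnp <- length(object@ccSnps)
    if (length(object@ccCaseFreq) != nSnp ||
        length(object@ccControlFreq) != nSnp)
        msg <- c(msg, "case-control frequencies must match ccSnps length")
    if (any(c(object@ccCaseFreq, object@ccControlFreq) < 0) ||
        any(c(object@ccCaseFreq, object@ccControlFreq) > 1))
        msg <- c(msg, "allele frequencies must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
simulationConfig <- function(nFamilies = 3L,
                             affectedPerFamily = 2L,
                             unaffectedPerFamily = 2L,
                             nBackgroundVariants = 20000L,
                             genePoolSize = 5000L,
                             effectProbs = .defaultEffectProbs(),
                             impactFidelity = 0.7,
                             missingnessRate = 0.1,
                             damagingFracSift = 0.25,
                             damagingFracPolyphen = 0.3,
                             conservedFracPhylop = 0.55,
                             conservedFracPhastcons = 0.6,
                             afShape1 = 0.4, afShape2 = 2.5,
                             plantedGene = "COL6A6",
                             plantedChrom = "chr3",
                             plantedPositions = NULL,
                             plantedAnnotation = list(
                                 effect = "NON_SYNONYMOUS_CODING",
                                 impact = "MODERATE", sift = 0.01,
                                 polyphen2Hdiv = 0.99, phylop = 4.6,
                                 phastcons = 1.0, afGlobal = 0.001,
                                 afEastAsian = 0.005, afKorean = 0.01),
                             ccSnps = c("rs16830494", "rs59021909",
                                        "rs200963433"),
                             ccCaseFreq = c(0.156, 0.112, 0.018),
                             ccControlFreq = c(0.189, 0.115, 0.008),
                             ccRefAlleles = c("G", "C", "C"),
                             ccAltAlleles = c("A", "T", "T"),
                             nCases = 112L, nControls = 61L,
                             seed = 1L) {
    if (is.null(plantedPositions)) {
        plantedPositions <- if (nFamilies == 3L)
            c(130361856, 130285929, 130289976)
        else 130285929 + seq_len(nFamilies) * 1000
    }
    new("SimulationConfig", nFamilies = as.integer(nFamilies),
        affectedPerFamily = as.integer(affectedPerFamily),
        unaffectedPerFamily = as.integer(unaffectedPerFamily),
        nBackgroundVariants = as.integer(nBackgroundVariants),
        genePoolSize = as.integer(genePoolSize),
        effectProbs = effectProbs, impactFidelity = impactFidelity,
        missingnessRate = missingnessRate,
        damagingFracSift = damagingFracSift,
        damagingFracPolyphen = damagingFracPolyphen,
        conservedFracPhylop = conservedFracPhylop,
        conservedFracPhastcons = conservedFracPhastcons,
        afShape1 = afShape1, afShape2 = afShape2,
        plantedGene = plantedGene, plantedChrom = plantedChrom,
        plantedPositions = plantedPositions,
        plantedAnnotation = plantedAnnotation,
        ccSnps = ccSnps, ccCaseFreq = ccCaseFreq,
        ccControlFreq = ccControlFreq, ccRefAlleles = ccRefAlleles,
        ccAltAlleles = ccAltAlleles, nCases = as.integer(nCases),
        nControls = as.integer(nControls), seed = as.integer(seed))
}

.canonicalImpact <- function(effect) {
    high <- c("STOP_GAINED", "STOP_LOST", "START_LOST", "FRAME_SHIFT",
              "SPLICE_SITE_ACCEPTOR", "SPLICE_SITE_DONOR")
    moderate <- c("NON_SYNONYMOUS_CODING", "CODON_CHANGE",
                  "CODON_INSERTION", "CODON_DELETION",
                  "CODON_CHANGE_PLUS_CODON_INSERTION",
                  "CODON_CHANGE_PLUS_CODON_DELETION")
    low <- c("SYNONYMOUS_CODING", "SYNONYMOUS_STOP", "START_GAINED")
    ifelse(effect %in% high, "HIGH",
           ifelse(effect %in% moderate, "MODERATE",
                  ifelse(effect %in% low, "LOW", "MODIFIER")))
}

## check a planted annotation against every cascade threshold; stop
## naming the violated one
.validatePlanted <- function(annotation, filterCfg) {
    a <- annotation
    fail <- function(what)
        stop("planted causal annotation violates the ", what,
             " threshold", call. = FALSE)
    if (!a$effect %in% filterCfg@effectKeep) fail("effect keep-set")
    if (!a$impact %in% filterCfg@impactKeep) fail("impact keep-set")
    siftDam <- !is.null(a$sift) && !is.na(a$sift) &&
        a$sift < filterCfg@siftDamagingMax
    ppDam <- !is.null(a$polyphen2Hdiv) && !is.na(a$polyphen2Hdiv) &&
        a$polyphen2Hdiv >= filterCfg@polyphenDamagingMin
    if (!siftDam && !ppDam) fail("SIFT/PolyPhen2 deleteriousness")
    if (!is.null(a$phylop) && !is.na(a$phylop) &&
        a$phylop <= filterCfg@phylopMin) fail("PhyloP")
    if (!is.null(a$phastcons) && !is.na(a$phastcons) &&
        a$phastcons < filterCfg@phastconsMin) fail("PhastCons")
    if (!is.null(a$afGlobal) && !is.na(a$afGlobal) &&
        a$afGlobal >= filterCfg@afGlobalMax) fail("global allele frequency")
    if (!is.null(a$afKorean) && !is.na(a$afKorean) &&
        a$afKorean >= filterCfg@afKoreanMax) fail("Korean allele frequency")
    invisible(TRUE)
}

.mixBeta <- function(n, frac, shapeTail1, shapeTail2, shapeBulk1, shapeBulk2) {
    tail <- runif(n) < frac
    out <- numeric(n)
    out[tail] <- rbeta(sum(tail), shapeTail1, shapeTail2)
    out[!tail] <- rbeta(sum(!tail), shapeBulk1, shapeBulk2)
    out
}

.withMissing <- function(x, rate) {
    x[runif(length(x)) < rate] <- NA
    x
}

#' Generate a synthetic multi-family annotated exome cohort
#'
#' Draws a joint cohort: background variants with exome-like annotation
#' mixtures whose genotypes are Hardy-Weinberg draws independent of
#' affection status (so they pass the segregation test only by
#' chance), plus one planted causal variant per family that is
#' heterozygous in every affected and homozygous-reference in every
#' unaffected member of that family (and homozygous-reference in all
#' other families). The planted annotation is validated against
#' `filterCfg` before any data is drawn; a planted value violating a
#' threshold is a generation-time error naming that threshold.
#'
#' The generator seeds R's RNG from `cfg@seed`, so a given config is
#' fully reproducible, including the emitted files.
#'
#' @param cfg A [SimulationConfig].
#' @param outDir Optional directory; when given, one annotated VCF per
#'   family (restricted to that family's samples), a joint PED file and
#'   a truth CSV are written there.
#' @param filterCfg The [FilterConfig] the planted annotation must
#'   satisfy.
#' @return A list:
#' \describe{
#'   \item{cohort}{the joint [VariantCohort] (all families' samples);
#'     `rowData` carries a `simPopFreq` column with the generating
#'     allele frequency of each background variant and `NA` for
#'     planted rows.}
#'   \item{pedigree}{the [Pedigree].}
#'   \item{truth}{`data.frame` of planted variants (gene, family, key,
#'     chrom, pos).}
#'   \item{vcfPaths, pedPath, truthPath}{file paths (when `outDir`
#'     given, else `NULL`).}
#' }
#'
#' @examples
#' sim <- generateFamilyExome(simulationConfig(nBackgroundVariants = 100,
#'                                             seed = 11))
#' sim$truth$gene
#'
#' @export
generateFamilyExome <- function(cfg, outDir = NULL,
                                filterCfg = filterConfig()) {
    stopifnot(is(cfg, "SimulationConfig"))
    .validatePlanted(cfg@plantedAnnotation, filterCfg)
    set.seed(cfg@seed)

    famIds <- paste0("Fam", LETTERS[seq_len(cfg@nFamilies)])
    perFam <- cfg@affectedPerFamily + cfg@unaffectedPerFamily
    sampleIds <- unlist(lapply(seq_len(cfg@nFamilies), function(i)
        paste0(LETTERS[i], seq_len(perFam))))
    ped <- Pedigree(
        family = rep(famIds, each = perFam),
        sample = sampleIds,
        affected = rep(c(rep(TRUE, cfg@affectedPerFamily),
                         rep(FALSE, cfg@unaffectedPerFamily)),
                       cfg@nFamilies),
        role = rep(c("father", rep("child", cfg@affectedPerFamily - 1L),
                     "mother", rep("child", cfg@unaffectedPerFamily - 1L)),
                   cfg@nFamilies))

    nBg <- cfg@nBackgroundVariants
    bases <- c("A", "C", "G", "T")
    chrom <- paste0("chr", sample(1:22, nBg, replace = TRUE),
                    recycle0 = TRUE)
    pos <- sample.int(2.4e8, nBg, replace = FALSE)
    ref <- sample(bases, nBg, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                  character(1), USE.NAMES = FALSE)
    gene <- paste0("GENE", formatC(sample.int(cfg@genePoolSize, nBg,
                                              replace = TRUE),
                                   width = 5, flag = "0"),
                   recycle0 = TRUE)
    effect <- sample(names(cfg@effectProbs), nBg, replace = TRUE,
                     prob = cfg@effectProbs)
    canonical <- .canonicalImpact(effect)
    jitterImpact <- runif(nBg) >= cfg@impactFidelity
    impact <- canonical
    impact[jitterImpact] <- vapply(canonical[jitterImpact], function(ci)
        sample(setdiff(impactVocabulary(), ci), 1L), character(1))

    mr <- cfg@missingnessRate
    sift <- .withMissing(.mixBeta(nBg, cfg@damagingFracSift,
                                  0.6, 8, 5, 1.5), mr)
    pp <- .withMissing(.mixBeta(nBg, cfg@damagingFracPolyphen,
                                6, 1, 1, 6), mr)
    conserved <- runif(nBg) < cfg@conservedFracPhylop
    phylop <- .withMissing(ifelse(conserved, rnorm(nBg, 2.5, 1.2),
                                  rnorm(nBg, -0.5, 0.8)), mr)
    phastcons <- .withMissing(.mixBeta(nBg, cfg@conservedFracPhastcons,
                                       8, 1, 1, 8), mr)
    popFreq <- rbeta(nBg, cfg@afShape1, cfg@afShape2)
    jitterAf <- function(p)
        .withMissing(pmin(1, pmax(0, p * runif(nBg, 0.8, 1.2))), mr)
    afGlobal <- jitterAf(popFreq)
    afEastAsian <- jitterAf(popFreq)
    afKorean <- jitterAf(popFreq)

    ## background genotypes: HW draws, independent of affection status
    nS <- length(sampleIds)
    dosage <- matrix(rbinom(nBg * nS, 2L, rep(popFreq, nS)), nrow = nBg,
                     ncol = nS)
    callsBg <- matrix(c("HOM_REF", "HET", "HOM_ALT")[dosage + 1L],
                      nrow = nBg, ncol = nS,
                      dimnames = list(NULL, sampleIds))

    ## planted causal variants: one per family, perfect dominant pattern
    pa <- cfg@plantedAnnotation
    nP <- cfg@nFamilies
    plantedCalls <- matrix("HOM_REF", nrow = nP, ncol = nS,
                           dimnames = list(NULL, sampleIds))
    for (i in seq_len(nP))
        plantedCalls[i, affectedIds(ped, famIds[i])] <- "HET"

    gr <- GRanges(c(chrom, rep(cfg@plantedChrom, nP)),
                  IRanges(c(pos, cfg@plantedPositions), width = 1L))
    getOr <- function(x, default) if (is.null(x)) default else x
    mcols(gr) <- DataFrame(
        ref = c(ref, rep("G", nP)),
        alt = c(alt, rep("A", nP)),
        rsid = NA_character_,
        gene = c(gene, rep(cfg@plantedGene, nP)),
        effect = c(effect, rep(pa$effect, nP)),
        impact = c(impact, rep(pa$impact, nP)),
        aaChange = NA_character_,
        sift = c(sift, rep(getOr(pa$sift, NA_real_), nP)),
        polyphen2Hdiv = c(pp, rep(getOr(pa$polyphen2Hdiv, NA_real_), nP)),
        phylop = c(phylop, rep(getOr(pa$phylop, NA_real_), nP)),
        phastcons = c(phastcons, rep(getOr(pa$phastcons, NA_real_), nP)),
        afGlobal = c(afGlobal, rep(getOr(pa$afGlobal, NA_real_), nP)),
        afEastAsian = c(afEastAsian, rep(getOr(pa$afEastAsian, NA_real_), nP)),
        afKorean = c(afKorean, rep(getOr(pa$afKorean, NA_real_), nP)),
        simPopFreq = c(popFreq, rep(NA_real_, nP)))
    cohort <- VariantCohort(gr, rbind(callsBg, plantedCalls),
                            sampleData = DataFrame(
                                family = rep(famIds, each = perFam),
                                affected = ped@affected,
                                row.names = sampleIds))

    truth <- data.frame(
        gene = cfg@plantedGene, family = famIds,
        key = rownames(cohort)[nBg + seq_len(nP)],
        chrom = cfg@plantedChrom, pos = cfg@plantedPositions,
        stringsAsFactors = FALSE)

    vcfPaths <- pedPath <- truthPath <- NULL
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        vcfPaths <- setNames(file.path(outDir, paste0(famIds, ".vcf")),
                             famIds)
        for (fam in famIds)
            writeAnnotatedVcf(cohort[, familyMembers(ped, fam)],
                              vcfPaths[[fam]])
        pedPath <- file.path(outDir, "families.ped")
        writePedigree(ped, pedPath)
        truthPath <- file.path(outDir, "truth.csv")
        write.csv(truth, truthPath, row.names = FALSE)
    }
    list(cohort = cohort, pedigree = ped, truth = truth,
         vcfPaths = vcfPaths, pedPath = pedPath, truthPath = truthPath)
}

#' Generate a synthetic case-control genotype cohort
#'
#' For each configured SNP, draws case and control genotypes under
#' Hardy-Weinberg proportions at the group's alt-allele frequency and
#' tabulates them into the counts schema consumed by
#' [readCaseControlCounts()] / [assocTable()].
#'
#' @param cfg A [SimulationConfig] (the `cc*`, `nCases`, `nControls`
#'   and `seed` fields are used).
#' @param outPath Optional CSV path to write the counts to.
#' @return A `data.frame` with columns `snp`, `group`, `hom_ref`,
#'   `het`, `hom_alt`, `ref_allele`, `alt_allele`.
#'
#' @examples
#' counts <- generateCaseControlGenotypes(simulationConfig(seed = 5))
#' head(counts)
#'
#' @export
generateCaseControlGenotypes <- function(cfg, outPath = NULL) {
    stopifnot(is(cfg, "SimulationConfig"))
    set.seed(cfg@seed + 1L)
    rows <- list()
    for (i in seq_along(cfg@ccSnps)) {
        drawCounts <- function(n, p) {
            dos <- rbinom(n, 2L, p)
            c(sum(dos == 0L), sum(dos == 1L), sum(dos == 2L))
        }
        for (grp in c("case", "control")) {
            n <- if (grp == "case") cfg@nCases else cfg@nControls
            p <- if (grp == "case") cfg@ccCaseFreq[i] else cfg@ccControlFreq[i]
            g <- drawCounts(n, p)
            rows[[length(rows) + 1L]] <- data.frame(
                snp = cfg@ccSnps[i], group = grp,
                hom_ref = g[1], het = g[2], hom_alt = g[3],
                ref_allele = cfg@ccRefAlleles[i],
                alt_allele = cfg@ccAltAlleles[i],
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    if (!is.null(outPath)) {
        dir.create(dirname(outPath), recursive = TRUE, showWarnings = FALSE)
        write.csv(out, outPath, row.names = FALSE)
    }
    out
}
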