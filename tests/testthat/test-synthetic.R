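test_that("the generator is deterministic given a seed, including emitted files", {
    cfg <- simulationConfig(nBackgroundVariants = 120L, seed = 77)
    d1 <- tempfile(); d2 <- tempfile()
    s1 <- generateFamilyExome(cfg, outDir = d1)
    s2 <- generateFamilyExome(cfg, outDir = d2)
    expect_identical(SummarizedExperiment::rowData(s1$cohort),
                     SummarizedExperiment::rowData(s2$cohort))
    expect_identical(calls(s1$cohort), calls(s2$cohort))
    for (fam in names(s1$vcfPaths))
        expect_identical(readLines(s1$vcfPaths[[fam]]),
                         readLines(s2$vcfPaths[[fam]]))
    expect_identical(readLines(s1$pedPath), readLines(s2$pedPath))
    ccA <- generateCaseControlGenotypes(cfg)
    ccB <- generateCaseControlGenotypes(cfg)
    expect_identical(ccA, ccB)
    ## a different seed gives different draws
    s3 <- generateFamilyExome(simulationConfig(nBackgroundVariants = 120L,
                                               seed = 78))
    expect_false(identical(calls(s1$cohort), calls(s3$cohort)))
})

test_that("a planted annotation violating a cascade threshold fails generation by name", {
    bad <- simulationConfig(
        nBackgroundVariants = 10L,
        plantedAnnotation = list(effect = "NON_SYNONYMOUS_CODING",
                                 impact = "MODERATE", sift = 0.5,
                                 polyphen2Hdiv = 0.1, phylop = 4,
                                 phastcons = 1, afGlobal = 0.001,
                                 afKorean = 0.01))
    expect_error(generateFamilyExome(bad), "deleteriousness")
    badAf <- simulationConfig(
        nBackgroundVariants = 10L,
        plantedAnnotation = list(effect = "NON_SYNONYMOUS_CODING",
                                 impact = "MODERATE", sift = 0.01,
                                 polyphen2Hdiv = 0.99, phylop = 4,
                                 phastcons = 1, afGlobal = 0.5,
                                 afKorean = 0.01))
    expect_error(generateFamilyExome(badAf), "global allele frequency")
    badEffect <- simulationConfig(
        nBackgroundVariants = 10L,
        plantedAnnotation = list(effect = "SYNONYMOUS_CODING",
                                 impact = "MODERATE", sift = 0.01,
                                 polyphen2Hdiv = 0.99, phylop = 4,
                                 phastcons = 1, afGlobal = 0.001,
                                 afKorean = 0.01))
    expect_error(generateFamilyExome(badEffect), "effect keep-set")
})

test_that("with no background noise the pipeline output is exactly the planted gene", {
    sim <- generateFamilyExome(simulationConfig(nBackgroundVariants = 0L,
                                                seed = 4))
    res <- runCascade(sim$cohort, sim$pedigree)
    tiers <- familyGeneTiers(res, sim$cohort)
    cand <- candidateGenes(tiers, minFamilies = 3)
    expect_equal(cand$gene, "COL6A6")
    expect_true(all(traceCounts(res$trace) == 1L))
})

test_that("background segregation rate matches the Hardy-Weinberg closed form", {
    cfg <- simulationConfig(nBackgroundVariants = 4000L, seed = 202)
    sim <- generateFamilyExome(cfg)
    p <- SummarizedExperiment::rowData(sim$cohort)$simPopFreq
    p <- p[!is.na(p)]
    ## P(2 affected HET, 2 unaffected HOM_REF) per family, per variant
    q <- (2 * p * (1 - p))^2 * ((1 - p)^2)^2
    segs <- applySegregation(sim$cohort, sim$pedigree)
    bg <- setdiff(rownames(sim$cohort), sim$truth$key)
    observed <- sum(vapply(segs, function(s)
        length(intersect(s, bg)), integer(1)))
    expected <- 3 * sum(q)
    sdTot <- sqrt(3 * sum(q * (1 - q)))
    expect_lt(abs(observed - expected), 4.5 * sdTot + 1)
})

test_that("case-control genotypes are Hardy-Weinberg draws at the configured frequencies", {
    nSnp <- 300L
    cfg <- simulationConfig(ccSnps = paste0("snp", seq_len(nSnp)),
                            ccCaseFreq = rep(0.3, nSnp),
                            ccControlFreq = rep(0.3, nSnp),
                            ccRefAlleles = rep("C", nSnp),
                            ccAltAlleles = rep("T", nSnp),
                            nCases = 200L, nControls = 50L, seed = 55)
    counts <- generateCaseControlGenotypes(cfg)
    caseRows <- counts[counts$group == "case", ]
    pvals <- apply(caseRows, 1, function(r)
        hweExactCheck(c(HOM_REF = as.integer(r[["hom_ref"]]),
                        HET = as.integer(r[["het"]]),
                        HOM_ALT = as.integer(r[["hom_alt"]]))))
    rejectRate <- mean(pvals < 0.05)
    ## the exact test is valid (size <= alpha) but conservative
    expect_lte(rejectRate, 0.07)
    expect_gte(rejectRate, 0.001)
    ## observed alt frequency concentrates around the generating one
    altFreq <- with(caseRows, (het + 2 * hom_alt) / (2 * 200))
    expect_equal(mean(altFreq), 0.3, tolerance = 0.02)
})

test_that("null case-control cohorts give allelic odds ratios near one", {
    logOR <- vapply(1:20, function(i) {
        cfg <- simulationConfig(ccSnps = "s", ccCaseFreq = 0.1,
                                ccControlFreq = 0.1, ccRefAlleles = "C",
                                ccAltAlleles = "T", nCases = 1000L,
                                nControls = 1000L, seed = 700L + i)
        counts <- generateCaseControlGenotypes(cfg)
        toCounts <- function(grp) {
            r <- counts[counts$group == grp, ]
            c(HOM_REF = r$hom_ref, HET = r$het, HOM_ALT = r$hom_alt)
        }
        cc <- CaseControlCounts("s", toCounts("case"), toCounts("control"))
        log(as.data.frame(oddsRatioCI(collapseModel(cc, "allelic")))$oddsRatio)
    }, numeric(1))
    ## mean log-OR ~ N(0, sigma/sqrt(20)), sigma ~ 0.105
    expect_lt(abs(mean(logOR)), 0.07)
})

test_that("a real allele-frequency difference recovers the generating odds ratio", {
    cfg <- simulationConfig(ccSnps = "s", ccCaseFreq = 0.2,
                            ccControlFreq = 0.1, ccRefAlleles = "C",
                            ccAltAlleles = "T", nCases = 10000L,
                            nControls = 10000L, seed = 99)
    counts <- generateCaseControlGenotypes(cfg)
    toCounts <- function(grp) {
        r <- counts[counts$group == grp, ]
        c(HOM_REF = r$hom_ref, HET = r$het, HOM_ALT = r$hom_alt)
    }
    cc <- CaseControlCounts("s", toCounts("case"), toCounts("control"))
    or <- as.data.frame(oddsRatioCI(collapseModel(cc, "allelic")))$oddsRatio
    trueOR <- (0.2 / 0.8) / (0.1 / 0.9)  # 2.25
    expect_lt(abs(or - trueOR) / trueOR, 0.10)
})
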