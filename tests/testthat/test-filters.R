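cfg <- filterConfig()

test_that("deleteriousness filter keeps any damaging or missing score, drops dual-benign", {
    ann <- annFrame(6,
        sift = c(0.04, 0.77, 0.11, 0.60, NA, 0.60),
        polyphen2Hdiv = c(0.272, 0.688, NA, 0.10, NA, 0.453))
    expect_equal(deleteriousnessFilter(ann, cfg),
                 c(TRUE,   # SIFT damaging (COL6A6-like)
                   TRUE,   # PolyPhen possibly damaging (TUFT1-like)
                   TRUE,   # PolyPhen absent, retained (DNAH17-like)
                   FALSE,  # both present, both benign
                   TRUE,   # both missing
                   TRUE))  # PolyPhen exactly at the inclusive threshold
})

test_that("threshold boundaries follow the declared open/closed semantics", {
    ## SIFT 0.05 is not damaging (exclusive); pair it with a benign PolyPhen
    expect_false(deleteriousnessFilter(
        annFrame(1, sift = 0.05, polyphen2Hdiv = 0.1), cfg))
    expect_true(deleteriousnessFilter(
        annFrame(1, sift = 0.0499, polyphen2Hdiv = 0.1), cfg))
    ## PolyPhen 0.453 inclusive
    expect_true(deleteriousnessFilter(
        annFrame(1, sift = 0.9, polyphen2Hdiv = 0.453), cfg))
    expect_false(deleteriousnessFilter(
        annFrame(1, sift = 0.9, polyphen2Hdiv = 0.4529), cfg))
    ## PhyloP strictly positive
    expect_true(phylopFilter(annFrame(1, phylop = 0.049), cfg))
    expect_false(phylopFilter(annFrame(1, phylop = 0), cfg))
    expect_false(phylopFilter(annFrame(1, phylop = -1), cfg))
    expect_true(phylopFilter(annFrame(1, phylop = NA_real_), cfg))
    ## PhastCons 0.2 inclusive
    expect_true(phastconsFilter(annFrame(1, phastcons = 0.2), cfg))
    expect_false(phastconsFilter(annFrame(1, phastcons = 0.19), cfg))
    expect_true(phastconsFilter(annFrame(1, phastcons = NA_real_), cfg))
    ## frequency maxima exclusive; unknown passes
    expect_false(globalFrequencyFilter(annFrame(1, afGlobal = 0.01), cfg))
    expect_true(globalFrequencyFilter(annFrame(1, afGlobal = 0.0099), cfg))
    expect_true(globalFrequencyFilter(annFrame(1, afGlobal = NA_real_), cfg))
    expect_false(koreanFrequencyFilter(annFrame(1, afKorean = 0.02), cfg))
    expect_true(koreanFrequencyFilter(annFrame(1, afKorean = 0.017), cfg))
})

test_that("effect and impact filters apply their keep-sets", {
    expect_true(effectFilter(annFrame(1, effect = "NON_SYNONYMOUS_CODING"), cfg))
    expect_true(effectFilter(annFrame(1, effect = "STOP_GAINED"), cfg))
    expect_false(effectFilter(annFrame(1, effect = "SYNONYMOUS_CODING"), cfg))
    expect_true(impactFilter(annFrame(1, impact = "HIGH"), cfg))
    expect_true(impactFilter(annFrame(1, impact = "MODERATE"), cfg))
    expect_false(impactFilter(annFrame(1, impact = "MODIFIER"), cfg))
})

test_that("cascade matches an independent one-pass reference filter on synthetic variants", {
    sim <- generateFamilyExome(simulationConfig(nBackgroundVariants = 10000L,
                                                seed = 101))
    ann <- SummarizedExperiment::rowData(sim$cohort)
    keys <- rownames(sim$cohort)
    res <- runCascade(sim$cohort, cfg = cfg,
                      familySets = list(all = keys))
    oracle <- bruteForceCascade(ann, cfg)
    expect_equal(unname(traceCounts(res$trace)[, "all"]),
                 c(length(keys), unname(colSums(oracle))))
    expect_setequal(res$rareTier$all, keys[oracle[, "af_korean"]])
    expect_setequal(res$commonTier$all,
                    keys[oracle[, "phastcons"] & !oracle[, "af_korean"]])
})

test_that("tiers partition the stage-5 survivors and the trace is monotone", {
    for (seed in c(5, 6)) {
        sim <- generateFamilyExome(simulationConfig(nBackgroundVariants = 800L,
                                                    seed = seed))
        res <- runCascade(sim$cohort, sim$pedigree, cfg)
        tc <- traceCounts(res$trace)
        expect_true(all(apply(tc, 2, function(x) all(diff(x) <= 0))))
        for (fam in colnames(tc)) {
            expect_length(intersect(res$commonTier[[fam]],
                                    res$rareTier[[fam]]), 0)
            expect_equal(length(res$commonTier[[fam]]) +
                         length(res$rareTier[[fam]]),
                         unname(tc["phastcons", fam]))
            expect_equal(length(res$rareTier[[fam]]),
                         unname(tc["af_korean", fam]))
        }
    }
})

test_that("published Family-A rows split into common and rare tiers as printed, bar the inconsistent conservation cell", {
    tab <- readFamilyVariantTable(fixturePath("family_candidate_variants.csv"))
    famA <- tab[tab$family == "FamA", ]
    vc <- cohortFromTable(famA)
    res <- runCascade(vc, cfg = cfg,
                      familySets = list(FamA = variantKeys(vc)))
    rareGenes <- famA$gene[match(res$rareTier$FamA, variantKeys(vc))]
    expect_setequal(rareGenes, c("DNAH17", "COL6A6"))
    commonGenes <- famA$gene[match(res$commonTier$FamA, variantKeys(vc))]
    ## the published EDN1 row prints a PhastCons value below the
    ## threshold it supposedly survived; the cascade drops it and the
    ## remaining 10 common-tier genes match the published list
    expect_setequal(commonGenes,
                    setdiff(famA$gene[famA$tier == "common"], "EDN1"))
    expect_equal(traceCounts(res$trace)["raw", "FamA"], 13L,
                 ignore_attr = TRUE)
    ## everything the cascade kept at stage 5 is exactly common + rare
    expect_equal(unname(traceCounts(res$trace)["phastcons", "FamA"]),
                 length(res$commonTier$FamA) + length(res$rareTier$FamA))
})

test_that("empty input produces a zero trace and empty tiers", {
    sim <- generateFamilyExome(simulationConfig(nBackgroundVariants = 10L,
                                                seed = 2))
    res <- runCascade(sim$cohort, cfg = cfg,
                      familySets = list(FamA = character()))
    expect_true(all(traceCounts(res$trace) == 0L))
    expect_length(res$commonTier$FamA, 0)
    expect_length(res$rareTier$FamA, 0)
})

test_that("trace averages use floor of the per-family mean", {
    m <- matrix(c(7523L, 2799L, 502L, 278L, 234L, 200L, 33L, 31L,
                  3564L, 2489L, 516L, 258L, 225L, 173L, 60L, 54L,
                  3227L, 2198L, 443L, 231L, 206L, 156L, 53L, 49L),
                ncol = 3, dimnames = list(cascadeStages(),
                                          c("FamA", "FamB", "FamC")))
    tr <- FilterTrace(m)
    expect_equal(summarizeTrace(tr, "phastcons"), 176L)
    expect_equal(summarizeTrace(tr, "af_global"), 48L)
    expect_equal(summarizeTrace(tr, "af_korean"), 44L)
    constant <- FilterTrace(matrix(10L, nrow = 8, ncol = 3,
                                   dimnames = list(cascadeStages(),
                                                   c("a", "b", "c"))))
    expect_equal(summarizeTrace(constant, "effect"), 10L)
})

test_that("a FilterTrace with increasing counts is rejected", {
    m <- matrix(c(10L, 20L, 5L, 5L, 5L, 5L, 5L, 5L), ncol = 1,
                dimnames = list(cascadeStages(), "FamA"))
    expect_error(FilterTrace(m), "non-increasing")
})

test_that("filter configs round-trip through their list serialization", {
    cfg2 <- filterConfig(afKoreanMax = 0.01, phastconsMin = 0.3,
                         missingPasses = setNames(
                             c(TRUE, FALSE, TRUE, TRUE, FALSE),
                             c("deleteriousness", "phylop", "phastcons",
                               "af_global", "af_korean")))
    expect_equal(filterConfigFromList(filterConfigToList(cfg2)), cfg2)
    expect_error(filterConfig(siftDamagingMax = 1.5), "\\[0,1\\]")
})
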