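ccFixture <- function() readCaseControlCounts(
    fixturePath("case_control_counts.csv"))

test_that("allele counts are the standard 2*hom + het collapse", {
    expect_equal(genotypeToAlleleCounts(c(HOM_REF = 47, HET = 14, HOM_ALT = 0)),
                 c(ref = 108, alt = 14))
    expect_equal(genotypeToAlleleCounts(c(HOM_REF = 89, HET = 21, HOM_ALT = 2)),
                 c(ref = 199, alt = 25))
    expect_equal(genotypeToAlleleCounts(c(HOM_REF = 30, HET = 0, HOM_ALT = 0)),
                 c(ref = 60, alt = 0))
})

test_that("frequency tables reproduce the published case-control percentages", {
    cc <- ccFixture()
    ftAll <- lapply(cc, frequencyTable)
    f16 <- ftAll$rs16830494
    expect_equal(f16$controlPct[f16$level == "allele" & f16$label == "A"], 18.9)
    f59 <- ftAll$rs59021909
    expect_equal(f59$controlPct[f59$label == "CT"], 23.0)
    expect_equal(f59$casePct[f59$label == "TT"], 1.8)
    expect_equal(f59$casePct[f59$level == "allele" & f59$label == "T"], 11.2)
    f20 <- ftAll$rs200963433
    expect_equal(f20$casePct[f20$label == "CT"], 3.6)
    expect_equal(f20$controlPct[f20$label == "CT"], 1.6)
    ## per-group percentages close to 100 up to rounding slack
    for (ft in ftAll) {
        for (col in c("casePct", "controlPct")) {
            expect_lt(abs(sum(ft[[col]][ft$level == "allele"]) - 100), 0.11)
            expect_lt(abs(sum(ft[[col]][ft$level == "genotype"]) - 100), 0.16)
        }
    }
})

test_that("percentages round half-up as in the published table", {
    ## 14/61 = 22.95..% must print 23.0, not 22.9
    cc <- CaseControlCounts("x", case = c(HOM_REF = 1, HET = 0, HOM_ALT = 0),
                            control = c(HOM_REF = 47, HET = 14, HOM_ALT = 0))
    ft <- frequencyTable(cc)
    expect_equal(ft$controlPct[ft$label == "REFALT"], 23.0)
})

test_that("model collapsing produces the expected 2x2 tables", {
    cc <- ccFixture()
    rec59 <- collapseModel(cc$rs59021909, "recessive")
    expect_equal(unname(rec59["case", ]), c(2L, 110L))
    expect_equal(unname(rec59["control", ]), c(0L, 61L))
    dom16 <- collapseModel(cc$rs16830494, "dominant")
    expect_equal(unname(dom16["case", ]), c(32L, 79L))
    expect_equal(unname(dom16["control", ]), c(22L, 39L))
    all20 <- collapseModel(cc$rs200963433, "allelic")
    expect_equal(unname(all20["case", ]), c(4L, 220L))
    expect_equal(unname(all20["control", ]), c(1L, 121L))
    mono <- CaseControlCounts("m", case = c(HOM_REF = 5, HET = 0, HOM_ALT = 0),
                              control = c(HOM_REF = 7, HET = 0, HOM_ALT = 0))
    expect_equal(unname(collapseModel(mono, "dominant")[, "exposed"]),
                 c(0L, 0L))
})

test_that("odds ratios follow the cross-product with Woolf intervals", {
    r <- as.data.frame(oddsRatioCI(rbind(c(4, 220), c(1, 121))))
    expect_equal(signif(r$oddsRatio, 2), 2.2)
    expect_false(r$correctionApplied)
    flat <- as.data.frame(oddsRatioCI(rbind(c(10, 10), c(10, 10))))
    expect_equal(flat$oddsRatio, 1.0)
    expect_lt(flat$ciLow, 1)
    expect_gt(flat$ciHigh, 1)
})

test_that("zero cells trigger the Haldane-Anscombe correction, or an error when disabled", {
    r <- as.data.frame(oddsRatioCI(rbind(c(2, 110), c(0, 61))))
    expect_true(r$correctionApplied)
    expect_equal(r$oddsRatio, (2.5 * 61.5) / (110.5 * 0.5), tolerance = 1e-12)
    expect_equal(round(r$oddsRatio, 2), 2.78)
    expect_true(is.finite(r$ciLow) && is.finite(r$ciHigh))
    expect_error(oddsRatioCI(rbind(c(2, 110), c(0, 61)), correct = FALSE),
                 "undefined")
})

test_that("transposing case and control inverts the odds ratio and its interval", {
    set.seed(42)
    for (i in 1:25) {
        tab <- matrix(rpois(4, 30) + 1, 2, 2)
        a <- as.data.frame(oddsRatioCI(tab))
        b <- as.data.frame(oddsRatioCI(tab[2:1, ]))
        expect_equal(b$oddsRatio, 1 / a$oddsRatio, tolerance = 1e-12)
        expect_equal(b$ciLow, 1 / a$ciHigh, tolerance = 1e-12)
        expect_equal(b$ciHigh, 1 / a$ciLow, tolerance = 1e-12)
    }
})

test_that("every finite table gives a finite corrected odds ratio and interval", {
    set.seed(99)
    for (i in 1:50) {
        tab <- matrix(rbinom(4, 40, 0.15), 2, 2)
        r <- as.data.frame(oddsRatioCI(tab))
        expect_true(is.finite(r$oddsRatio) && r$oddsRatio > 0)
        expect_true(is.finite(r$ciLow) && is.finite(r$ciHigh))
        expect_lte(r$ciLow, r$oddsRatio)
        expect_gte(r$ciHigh, r$oddsRatio)
    }
})

test_that("assocTable runs all models over all SNPs without adjustment", {
    tab <- assocTable(ccFixture())
    expect_equal(nrow(tab), 9L)
    expect_setequal(unique(tab$model), c("allelic", "dominant", "recessive"))
    expect_equal(attr(tab, "nTests"), 9L)
    expect_true(all(tab$oddsRatio > 0))
})

## independent log-factorial enumeration of the Levene-Haldane
## distribution, used only as an oracle for the recurrence version
hweOracle <- function(g) {
    nAB <- g[["HET"]]; nAA <- g[["HOM_REF"]]; nBB <- g[["HOM_ALT"]]
    n <- nAA + nAB + nBB
    nA <- 2 * nAA + nAB
    hets <- seq((nA %% 2), min(nA, 2 * n - nA), by = 2)
    logP <- vapply(hets, function(h) {
        aa <- (nA - h) / 2
        bb <- n - aa - h
        lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
            h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) -
            lgamma(2 * n + 1)
    }, numeric(1))
    p <- exp(logP - max(logP)); p <- p / sum(p)
    obs <- p[match(nAB, hets)]
    min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

test_that("the exact Hardy-Weinberg test matches an independent enumeration", {
    set.seed(7)
    for (i in 1:30) {
        n <- sample(5:120, 1)
        p <- runif(1, 0.05, 0.95)
        dos <- rbinom(n, 2, p)
        g <- c(HOM_REF = sum(dos == 0), HET = sum(dos == 1),
               HOM_ALT = sum(dos == 2))
        expect_equal(hweExactCheck(g), hweOracle(g), tolerance = 1e-9,
                     info = paste(g, collapse = "/"))
    }
})

test_that("exact HWE edge cases behave as expected", {
    expect_equal(hweExactCheck(c(HOM_REF = 25, HET = 50, HOM_ALT = 25)), 1)
    expect_lt(hweExactCheck(c(HOM_REF = 0, HET = 20, HOM_ALT = 0)), 0.01)
    expect_equal(hweExactCheck(c(HOM_REF = 0, HET = 1, HOM_ALT = 0)), 1)
    expect_equal(hweExactCheck(c(HOM_REF = 50, HET = 0, HOM_ALT = 0)), 1)
})
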