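tiersFromFixture <- function() {
    variantTableTiers(readFamilyVariantTable(
        fixturePath("family_candidate_variants.csv")))
}

test_that("the three published family lists intersect to 14 genes, COL6A6 in all three", {
    cand <- candidateGenes(tiersFromFixture(), minFamilies = 2)
    expect_equal(nrow(cand), 14L)
    expect_setequal(cand$gene,
                    c("COL6A6", "ANKRD35", "TUFT1", "TMEM175", "EDN1",
                      "NRAP", "HGFAC", "UNC93A", "ABCA13", "SSPO",
                      "TTC40", "DNAH17", "UVSSA", "CDX1"))
    strict <- candidateGenes(tiersFromFixture(), minFamilies = 3)
    expect_equal(strict$gene, "COL6A6")
    expect_equal(unname(strict$nFamilies), 3L)
})

test_that("four of the overlapping genes carry a rare-tier variant", {
    cand <- candidateGenes(tiersFromFixture(), minFamilies = 2)
    rare <- rareOverlapGenes(cand)
    expect_setequal(rare$gene, c("COL6A6", "CDX1", "DNAH17", "ANKRD35"))
})

test_that("overlap is monotone decreasing in minFamilies and empty beyond the family count", {
    tiers <- tiersFromFixture()
    sizes <- vapply(1:4, function(k)
        nrow(candidateGenes(tiers, minFamilies = k)), integer(1))
    expect_true(all(diff(sizes) <= 0))
    expect_equal(sizes[4], 0L)
    expect_equal(nrow(overlappingGenes(list(FamA = c("G1", "G2")),
                                       minFamilies = 2)), 0L)
})

test_that("gene-level overlap counts distinct variants of one gene in different families", {
    tiers <- list(FamA = list(common = "TTC40", rare = character()),
                  FamC = list(common = "TTC40", rare = character()))
    cand <- candidateGenes(tiers, minFamilies = 2)
    expect_equal(cand$gene, "TTC40")
})

test_that("rare-overlap handles the degenerate all-rare and no-rare cases", {
    allRare <- list(FamA = list(common = character(), rare = c("G1", "G2")),
                    FamB = list(common = character(), rare = c("G1", "G2")))
    cand <- candidateGenes(allRare)
    expect_equal(nrow(rareOverlapGenes(cand)), nrow(cand))
    noRare <- list(FamA = list(common = c("G1", "G2"), rare = character()),
                   FamB = list(common = c("G1", "G2"), rare = character()))
    expect_equal(nrow(rareOverlapGenes(candidateGenes(noRare))), 0L)
})

lociFixture <- function() readLoci(fixturePath("ad_linkage_loci.tsv"),
                                   units = "Mb")

test_that("locus proximity classifies within, proximal and unlinked genes", {
    loci <- lociFixture()
    pos <- GenomicRanges::GRanges(
        c("chr1", "chr3", "chr7"),
        IRanges::IRanges(c(145500000, 130200000, 48313881), width = 1))
    names(pos) <- c("ANKRD35", "COL6A6", "ABCA13")
    prox <- locusProximity(pos, loci, marginBp = 1e6)
    expect_equal(prox$status[prox$gene == "ANKRD35"], "WITHIN")
    expect_equal(prox$locus[prox$gene == "ANKRD35"], "1q21")
    expect_equal(prox$status[prox$gene == "COL6A6"], "PROXIMAL")
    expect_equal(prox$locus[prox$gene == "COL6A6"], "3q21")
    expect_equal(prox$distanceBp[prox$gene == "COL6A6"], 700000)
    expect_equal(prox$status[prox$gene == "ABCA13"], "NONE")
})

test_that("margin zero never yields PROXIMAL and growing margins never demote WITHIN", {
    loci <- lociFixture()
    pos <- GenomicRanges::GRanges(
        c("chr3", "chr1"), IRanges::IRanges(c(130200000, 145500000), width = 1))
    names(pos) <- c("COL6A6", "ANKRD35")
    zero <- locusProximity(pos, loci, marginBp = 0)
    expect_false(any(zero$status == "PROXIMAL"))
    expect_equal(zero$status[zero$gene == "COL6A6"], "NONE")
    for (margin in c(0, 7e5, 5e6)) {
        p <- locusProximity(pos, loci, marginBp = margin)
        expect_equal(p$status[p$gene == "ANKRD35"], "WITHIN")
    }
})

test_that("ties between loci resolve to the nearest interval", {
    loci <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(1000, 9000), c(2000, 9500)),
        locus = c("near", "far"))
    names(loci) <- loci$locus
    pos <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2500, width = 1))
    names(pos) <- "GENE1"
    p <- locusProximity(pos, loci, marginBp = 1e4)
    expect_equal(p$locus, "near")
})
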