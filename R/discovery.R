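#' Gene-level overlap across families
#'
#' Intersects per-family gene sets at the gene level: a gene overlaps
#' when it appears in at least `minFamilies` families, regardless of
#' whether the underlying variants are identical (different variants of
#' one gene in different families count).
#'
#' @param geneSets Named list, family id -> character vector of gene
#'   symbols (duplicates and `NA` are dropped).
#' @param minFamilies Minimum number of families a gene must appear in
#'   (>= 2 for a meaningful overlap). A value larger than the number of
#'   families yields an empty result, not an error.
#' @return A [S4Vectors::DataFrame] with one row per overlapping gene:
#'   `gene`, `families` (a `CharacterList`), `nFamilies`; ordered by
#'   decreasing `nFamilies`, then gene symbol.
#'
#' @examples
#' sets <- list(FamA = c("COL6A6", "TUFT1", "SSPO"),
#'              FamB = c("COL6A6", "TUFT1"),
#'              FamC = c("COL6A6", "UVSSA"))
#' overlappingGenes(sets, minFamilies = 2)
#' overlappingGenes(sets, minFamilies = 3)$gene
#'
#' @export
overlappingGenes <- function(geneSets, minFamilies = 2L) {
    stopifnot(is.list(geneSets), minFamilies >= 1L)
    perFam <- lapply(geneSets, function(g) unique(g[!is.na(g)]))
    long <- data.frame(
        family = rep(names(perFam), lengths(perFam)),
        gene = unlist(perFam, use.names = FALSE),
        stringsAsFactors = FALSE)
    if (!nrow(long))
        return(DataFrame(gene = character(),
                         families = CharacterList(),
                         nFamilies = integer()))
    famByGene <- split(long$family, long$gene)
    famByGene <- famByGene[lengths(famByGene) >= minFamilies]
    out <- DataFrame(gene = names(famByGene),
                     families = CharacterList(unname(famByGene)),
                     nFamilies = lengths(famByGene))
    out[order(-out$nFamilies, out$gene), , drop = FALSE]
}

#' Candidate genes from per-family tier results
#'
#' Builds the candidate-gene table from per-family common/rare tier
#' gene lists: the gene-level overlap of the union of both tiers,
#' flagged with whether the gene carries a rare-tier variant in at
#' least one family.
#'
#' @param familyTiers Named list, family id -> list with character
#'   elements `common` and `rare` (gene symbols per tier). The output
#'   of [familyGeneTiers()] has this shape.
#' @param minFamilies As in [overlappingGenes()].
#' @return A `DataFrame` with columns `gene`, `families`, `nFamilies`,
#'   `hasRareVariant`.
#'
#' @examples
#' tiers <- list(
#'   FamA = list(common = c("TUFT1", "SSPO"), rare = "COL6A6"),
#'   FamB = list(common = "TUFT1", rare = "COL6A6"),
#'   FamC = list(common = c("SSPO", "COL6A6"), rare = character()))
#' candidateGenes(tiers)
#'
#' @export
candidateGenes <- function(familyTiers, minFamilies = 2L) {
    unionSets <- lapply(familyTiers, function(t)
        unique(c(t$common, t$rare)))
    ov <- overlappingGenes(unionSets, minFamilies)
    rareGenes <- unique(unlist(lapply(familyTiers, `[[`, "rare"),
                               use.names = FALSE))
    ov$hasRareVariant <- ov$gene %in% rareGenes
    ov
}

#' @rdname candidateGenes
#' @param candidates A `DataFrame` as returned by [candidateGenes()].
#' @return `rareOverlapGenes()` returns the subset of `candidates` with
#'   a rare-tier variant in at least one family.
#' @export
rareOverlapGenes <- function(candidates) {
    stopifnot("hasRareVariant" %in% colnames(candidates))
    candidates[candidates$hasRareVariant, , drop = FALSE]
}

#' Per-family tier gene lists from a cascade result
#'
#' @param cascade The list returned by [runCascade()].
#' @param cohort The [VariantCohort] the cascade ran on.
#' @return Named list, family id -> `list(common = genes, rare =
#'   genes)`, suitable for [candidateGenes()].
#' @export
familyGeneTiers <- function(cascade, cohort) {
    geneOf <- function(keys)
        unique(rowData(cohort)[match(keys, rownames(cohort)), "gene"])
    fams <- names(cascade$commonTier)
    setNames(lapply(fams, function(fam)
        list(common = geneOf(cascade$commonTier[[fam]]),
             rare = geneOf(cascade$rareTier[[fam]]))), fams)
}

#' Annotate candidate genes against linkage loci
#'
#' Classifies each gene's representative position(s) against a set of
#' linkage-locus intervals: `WITHIN` if a position falls inside a
#' same-chromosome locus, `PROXIMAL` if it lies within `marginBp`
#' bases of a locus end, `NONE` otherwise. When a gene has several
#' positions or several candidate loci, `WITHIN` beats `PROXIMAL` and
#' ties are broken by the smallest distance.
#'
#' @param positions A [GenomicRanges::GRanges] of representative
#'   positions with gene symbols as names (several rows per gene are
#'   allowed).
#' @param loci A `GRanges` of loci as returned by [readLoci()] (1-based
#'   inclusive intervals, locus names as names).
#' @param marginBp Non-negative proximity margin in base pairs
#'   (default 1 Mb). With `marginBp = 0` nothing is `PROXIMAL`.
#' @return A `DataFrame` with one row per gene: `gene`, `status`
#'   (`WITHIN`/`PROXIMAL`/`NONE`), `locus` (matched locus name or
#'   `NA`), `distanceBp` (0 for `WITHIN`, gap in bases otherwise,
#'   `NA` for `NONE`).
#'
#' @examples
#' loci <- GenomicRanges::GRanges(c("chr3", "chr1"),
#'     IRanges::IRanges(c(122200000, 143200000), c(129500000, 155100000)),
#'     locus = c("3q21", "1q21"))
#' names(loci) <- loci$locus
#' pos <- GenomicRanges::GRanges(c("chr3", "chr1"),
#'     IRanges::IRanges(c(130285929, 145562293), width = 1))
#' names(pos) <- c("COL6A6", "ANKRD35")
#' locusProximity(pos, loci)
#'
#' @export
locusProximity <- function(positions, loci, marginBp = 1e6) {
    stopifnot(marginBp >= 0)
    genes <- unique(names(positions))
    if (is.null(genes))
        stop("'positions' must carry gene symbols as names")
    status <- character(length(genes))
    locus <- rep(NA_character_, length(genes))
    distBp <- rep(NA_real_, length(genes))
    for (i in seq_along(genes)) {
        pos <- positions[names(positions) == genes[i]]
        ## positions and loci legitimately live on different chromosome
        ## sets; the seqlevel-merge warning is expected noise here
        hits <- suppressWarnings(
            findOverlaps(pos, loci, ignore.strand = TRUE))
        if (length(hits)) {
            status[i] <- "WITHIN"
            locus[i] <- names(loci)[S4Vectors::subjectHits(hits)[1]]
            distBp[i] <- 0
            next
        }
        ## gap + 1 = bases separating the position from the interval end
        d <- outer(seq_along(pos), seq_along(loci), Vectorize(function(p, l)
            suppressWarnings(distance(pos[p], loci[l],
                                      ignore.strand = TRUE)))) + 1
        if (all(is.na(d)) || min(d, na.rm = TRUE) > marginBp) {
            status[i] <- "NONE"
            next
        }
        best <- which(d == min(d, na.rm = TRUE), arr.ind = TRUE)[1, ]
        status[i] <- "PROXIMAL"
        locus[i] <- names(loci)[best[2]]
        distBp[i] <- min(d, na.rm = TRUE)
    }
    DataFrame(gene = genes, status = status, locus = locus,
              distanceBp = distBp)
}
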