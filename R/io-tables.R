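#' Read a per-family candidate-variant table
#'
#' Reads a CSV of per-family prioritized variants — the tabular form in
#' which family-specific candidate lists are published — into the
#' internal annotation column names. Expected columns: `family`,
#' `tier` (`common`/`rare`), `gene`, `rsid`, `chrom`, `pos`,
#' `aa_change`, `effect`, `impact`, `sift`, `polyphen2_hdiv`,
#' `phylop`, `phastcons`, `af_global`, `af_east_asian`, `af_korean`.
#' Empty cells become `NA` (a missing score, never zero). A copy of
#' the published three-family candidate table ships with the package:
#' `system.file("extdata", "family_candidate_variants.csv",
#' package = "pedexome")`.
#'
#' @param path CSV path.
#' @return A `data.frame` with columns `family`, `tier`, `gene`,
#'   `rsid`, `chrom`, `pos`, `aaChange`, `effect`, `impact`, `sift`,
#'   `polyphen2Hdiv`, `phylop`, `phastcons`, `afGlobal`,
#'   `afEastAsian`, `afKorean`.
#'
#' @examples
#' tab <- readFamilyVariantTable(system.file("extdata",
#'     "family_candidate_variants.csv", package = "pedexome"))
#' table(tab$family, tab$tier)
#'
#' @export
readFamilyVariantTable <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
    rename <- c(aa_change = "aaChange", polyphen2_hdiv = "polyphen2Hdiv",
                af_global = "afGlobal", af_east_asian = "afEastAsian",
                af_korean = "afKorean")
    for (old in names(rename))
        names(tab)[names(tab) == old] <- rename[[old]]
    need <- c("family", "tier", "gene", "chrom", "pos", "effect",
              "impact", "sift", "polyphen2Hdiv", "phylop", "phastcons",
              "afGlobal", "afKorean")
    missingCols <- setdiff(need, names(tab))
    if (length(missingCols))
        stop("candidate table '", path, "' lacks column(s): ",
             paste(missingCols, collapse = ", "))
    badTier <- setdiff(unique(tab$tier), c("common", "rare"))
    if (length(badTier))
        stop("unknown tier label(s): ", paste(badTier, collapse = ", "))
    tab
}

#' Per-family tier gene lists from a candidate-variant table
#'
#' Convenience bridge from [readFamilyVariantTable()] output to the
#' `familyTiers` shape [candidateGenes()] consumes.
#'
#' @param tab A `data.frame` from [readFamilyVariantTable()].
#' @return Named list, family -> `list(common = genes, rare = genes)`.
#' @export
variantTableTiers <- function(tab) {
    fams <- unique(tab$family)
    setNames(lapply(fams, function(fam) {
        sub <- tab[tab$family == fam, ]
        list(common = unique(sub$gene[sub$tier == "common"]),
             rare = unique(sub$gene[sub$tier == "rare"]))
    }), fams)
}
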