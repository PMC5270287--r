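#' Collapse genotype counts to allele counts
#'
#' @param g Named integer vector of genotype counts (`HOM_REF`, `HET`,
#'   `HOM_ALT`).
#' @return Named numeric vector `c(ref, alt)`; `ref + alt` is exactly
#'   twice the genotype total.
#' @examples
#' genotypeToAlleleCounts(c(HOM_REF = 47, HET = 14, HOM_ALT = 0))
#' @export
genotypeToAlleleCounts <- function(g) {
    g <- g[.GENO_NAMES]
    stopifnot(!any(is.na(g)), all(g >= 0))
    c(ref = unname(2 * g[["HOM_REF"]] + g[["HET"]]),
      alt = unname(2 * g[["HOM_ALT"]] + g[["HET"]]))
}

## half-up rounding to `digits` decimals (printed frequency convention;
## base round() is round-half-even)
roundHalfUp <- function(x, digits = 1L) {
    p <- 10^digits
    floor(x * p + 0.5) / p
}

#' Allele and genotype frequency table for one SNP
#'
#' Computes the publication-style percentage table for a case-control
#' SNP: per-group genotype percentages (count / group size) and allele
#' percentages (allele count / 2 x group size), rounded half-up to one
#' decimal.
#'
#' @param cc A [CaseControlCounts].
#' @return A `data.frame` with columns `snp`, `level` (`allele` or
#'   `genotype`), `label` (allele or genotype symbol), `caseCount`,
#'   `casePct`, `controlCount`, `controlPct`.
#'
#' @examples
#' cc <- CaseControlCounts("rs59021909",
#'     case = c(HOM_REF = 89L, HET = 21L, HOM_ALT = 2L),
#'     control = c(HOM_REF = 47L, HET = 14L, HOM_ALT = 0L),
#'     refAllele = "C", altAllele = "T")
#' frequencyTable(cc)
#'
#' @export
frequencyTable <- function(cc) {
    caseN <- sum(cc@case)
    ctrlN <- sum(cc@control)
    caseAll <- genotypeToAlleleCounts(cc@case)
    ctrlAll <- genotypeToAlleleCounts(cc@control)
    genoLabel <- c(paste0(cc@refAllele, cc@refAllele),
                   paste0(cc@refAllele, cc@altAllele),
                   paste0(cc@altAllele, cc@altAllele))
    pct <- function(count, denom)
        if (denom > 0) roundHalfUp(count / denom * 100, 1L) else NA_real_
    data.frame(
        snp = cc@snp,
        level = c("allele", "allele", rep("genotype", 3L)),
        label = c(cc@refAllele, cc@altAllele, genoLabel),
        caseCount = c(unname(caseAll), unname(cc@case)),
        casePct = c(pct(caseAll[["ref"]], 2 * caseN),
                    pct(caseAll[["alt"]], 2 * caseN),
                    pct(cc@case[["HOM_REF"]], caseN),
                    pct(cc@case[["HET"]], caseN),
                    pct(cc@case[["HOM_ALT"]], caseN)),
        controlCount = c(unname(ctrlAll), unname(cc@control)),
        controlPct = c(pct(ctrlAll[["ref"]], 2 * ctrlN),
                       pct(ctrlAll[["alt"]], 2 * ctrlN),
                       pct(cc@control[["HOM_REF"]], ctrlN),
                       pct(cc@control[["HET"]], ctrlN),
                       pct(cc@control[["HOM_ALT"]], ctrlN)),
        stringsAsFactors = FALSE)
}

#' Collapse genotype counts to a 2x2 table under a genetic model
#'
#' * `allelic`: alt vs ref allele counts (2n alleles per group);
#' * `dominant`: alt-carrying samples (`HET` + `HOM_ALT`) vs `HOM_REF`;
#' * `recessive`: `HOM_ALT` vs (`HET` + `HOM_REF`) samples.
#'
#' Rows are (case, control), columns (exposed, unexposed), the
#' orientation [oddsRatioCI()] expects.
#'
#' @param cc A [CaseControlCounts].
#' @param model One of `"allelic"`, `"dominant"`, `"recessive"`.
#' @return An integer 2x2 matrix.
#'
#' @examples
#' cc <- CaseControlCounts("rs59021909",
#'     case = c(HOM_REF = 89L, HET = 21L, HOM_ALT = 2L),
#'     control = c(HOM_REF = 47L, HET = 14L, HOM_ALT = 0L))
#' collapseModel(cc, "recessive")
#'
#' @export
collapseModel <- function(cc, model = c("allelic", "dominant", "recessive")) {
    model <- match.arg(model)
    row1 <- switch(model,
        allelic = rev(genotypeToAlleleCounts(cc@case)),
        dominant = c(cc@case[["HET"]] + cc@case[["HOM_ALT"]],
                     cc@case[["HOM_REF"]]),
        recessive = c(cc@case[["HOM_ALT"]],
                      cc@case[["HET"]] + cc@case[["HOM_REF"]]))
    row2 <- switch(model,
        allelic = rev(genotypeToAlleleCounts(cc@control)),
        dominant = c(cc@control[["HET"]] + cc@control[["HOM_ALT"]],
                     cc@control[["HOM_REF"]]),
        recessive = c(cc@control[["HOM_ALT"]],
                      cc@control[["HET"]] + cc@control[["HOM_REF"]]))
    m <- rbind(case = row1, control = row2)
    colnames(m) <- c("exposed", "unexposed")
    storage.mode(m) <- "integer"
    m
}

#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio `(a d)/(b c)` of a 2x2 table oriented
#' rows = (case, control), columns = (exposed, unexposed), with the
#' Woolf log-scale interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell
#' is zero and `correct = TRUE`, 0.5 is added to all four cells
#' (Haldane-Anscombe) before both the estimate and the interval, and
#' the result is flagged. With `correct = FALSE` a zero row or column
#' is an error rather than a silent `NaN`.
#'
#' @param tab Numeric 2x2 table with non-negative cells.
#' @param alpha Two-sided type-I level for the interval (default 0.05
#'   for a 95 percent CI).
#' @param correct Apply the Haldane-Anscombe zero-cell correction.
#' @param snp,model Labels carried into the result.
#' @return An [AssociationResult].
#'
#' @examples
#' or <- oddsRatioCI(rbind(case = c(4, 220), control = c(1, 121)))
#' as.data.frame(or)$oddsRatio  # ~2.2
#'
#' @export
oddsRatioCI <- function(tab, alpha = 0.05, correct = TRUE,
                        snp = NA_character_, model = NA_character_) {
    tab <- as.matrix(tab)
    stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0),
              !any(is.na(tab)))
    applied <- FALSE
    work <- tab
    if (any(work == 0)) {
        if (correct) {
            work <- work + 0.5
            applied <- TRUE
        } else if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
                   sum(tab == 0) > 0) {
            stop("odds ratio undefined: zero cell(s) with correction disabled")
        }
    }
    a <- work[1, 1]; b <- work[1, 2]; c <- work[2, 1]; d <- work[2, 2]
    or <- (a * d) / (b * c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    z <- qnorm(1 - alpha / 2)
    new("AssociationResult", snp = as.character(snp),
        model = as.character(model), table = tab, oddsRatio = or,
        ciLow = exp(log(or) - z * se), ciHigh = exp(log(or) + z * se),
        correctionApplied = applied)
}

#' Association table across SNPs and genetic models
#'
#' Runs [collapseModel()] + [oddsRatioCI()] for every combination of
#' SNP and model and binds the results into one data frame. No
#' multiple-testing adjustment is applied; the `nTests` attribute
#' records the number of rows so callers can apply their own.
#'
#' @param counts A list of [CaseControlCounts] (or a single one).
#' @param models Character subset of
#'   `c("allelic", "dominant", "recessive")`.
#' @param alpha,correct Passed to [oddsRatioCI()].
#' @return A `data.frame`, one row per SNP x model, with the columns of
#'   `as.data.frame(<AssociationResult>)`.
#'
#' @examples
#' cc <- CaseControlCounts("rs16830494",
#'     case = c(HOM_REF = 79L, HET = 29L, HOM_ALT = 3L),
#'     control = c(HOM_REF = 39L, HET = 21L, HOM_ALT = 1L),
#'     refAllele = "G", altAllele = "A")
#' assocTable(cc)
#'
#' @export
assocTable <- function(counts, models = c("allelic", "dominant", "recessive"),
                       alpha = 0.05, correct = TRUE) {
    if (is(counts, "CaseControlCounts"))
        counts <- list(counts)
    models <- match.arg(models, several.ok = TRUE)
    rows <- list()
    for (cc in counts) {
        for (m in models) {
            res <- oddsRatioCI(collapseModel(cc, m), alpha = alpha,
                               correct = correct, snp = cc@snp, model = m)
            rows[[length(rows) + 1L]] <- as.data.frame(res)
        }
    }
    out <- do.call(rbind, rows)
    attr(out, "nTests") <- nrow(out)
    out
}

#' Read a genotype-counts CSV into CaseControlCounts objects
#'
#' Expected columns: `snp`, `group` (`case`/`control`), `hom_ref`,
#' `het`, `hom_alt`, and optionally `ref_allele`, `alt_allele`.
#'
#' @param path CSV path.
#' @return Named list of [CaseControlCounts], one per SNP.
#' @export
readCaseControlCounts <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("snp", "group", "hom_ref", "het", "hom_alt")
    if (!all(need %in% colnames(tab)))
        stop("counts CSV '", path, "' must have columns: ",
             paste(need, collapse = ", "))
    out <- list()
    for (s in unique(tab$snp)) {
        sub <- tab[tab$snp == s, ]
        pick <- function(grp) {
            r <- sub[sub$group == grp, ]
            if (nrow(r) != 1L)
                stop("SNP '", s, "' needs exactly one '", grp,
                     "' row in '", path, "'")
            c(HOM_REF = r$hom_ref, HET = r$het, HOM_ALT = r$hom_alt)
        }
        out[[s]] <- CaseControlCounts(
            s, case = pick("case"), control = pick("control"),
            refAllele = if ("ref_allele" %in% colnames(sub))
                sub$ref_allele[1] else "REF",
            altAllele = if ("alt_allele" %in% colnames(sub))
                sub$alt_allele[1] else "ALT")
    }
    out
}
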