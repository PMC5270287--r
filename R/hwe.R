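#' Exact test of Hardy-Weinberg proportions
#'
#' Exact conditional test for a biallelic SNP: conditional on the
#' observed allele counts, the heterozygote count follows the
#' Levene-Haldane distribution, and the p-value is the total
#' probability of all heterozygote configurations no more probable
#' than the observed one (point-mass ordering). Used to validate the
#' synthetic case-control generator, whose genotypes are drawn under
#' Hardy-Weinberg proportions.
#'
#' The probabilities are accumulated with the standard two-sided
#' recurrence over heterozygote counts of matching parity, which is
#' numerically stable for cohort-sized counts.
#'
#' @param g Named integer vector of genotype counts (`HOM_REF`, `HET`,
#'   `HOM_ALT`).
#' @return The exact p-value in (0, 1]. Monomorphic or single-sample
#'   inputs have only one attainable configuration and return 1.
#'
#' @examples
#' hweExactCheck(c(HOM_REF = 25, HET = 50, HOM_ALT = 25))  # 1
#' hweExactCheck(c(HOM_REF = 0, HET = 40, HOM_ALT = 0))    # tiny
#'
#' @export
hweExactCheck <- function(g) {
    g <- g[.GENO_NAMES]
    stopifnot(!any(is.na(g)), all(g >= 0))
    obsHets <- as.integer(g[["HET"]])
    homR <- as.integer(g[["HOM_REF"]])
    homA <- as.integer(g[["HOM_ALT"]])
    n <- homR + obsHets + homA
    rare <- 2L * min(homR, homA) + obsHets
    if (n <= 1L || rare == 0L)
        return(1)
    ## attainable het counts share the parity of the rare-allele count
    hetLevels <- seq.int(rare %% 2L, rare, by = 2L)
    probs <- numeric(length(hetLevels))
    mid <- rare * (2L * n - rare) / (2L * n)
    midIdx <- which.min(abs(hetLevels - mid))
    probs[midIdx] <- 1
    ## downward recurrence: P(h-2)/P(h) = h(h-1) / (4 (rh+1) (ch+1))
    if (midIdx > 1L) {
        for (i in seq(midIdx, 2L)) {
            h <- hetLevels[i]
            rh <- (rare - h) / 2
            ch <- n - rh - h
            probs[i - 1L] <- probs[i] * h * (h - 1) /
                (4 * (rh + 1) * (ch + 1))
        }
    }
    ## upward recurrence: P(h+2)/P(h) = 4 rh ch / ((h+2)(h+1))
    if (midIdx < length(hetLevels)) {
        for (i in seq(midIdx, length(hetLevels) - 1L)) {
            h <- hetLevels[i]
            rh <- (rare - h) / 2
            ch <- n - rh - h
            probs[i + 1L] <- probs[i] * 4 * rh * ch /
                ((h + 2) * (h + 1))
        }
    }
    probs <- probs / sum(probs)
    pObs <- probs[match(obsHets, hetLevels)]
    min(1, sum(probs[probs <= pObs * (1 + 1e-10)]))
}
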