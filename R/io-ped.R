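#' Read a 6-column PED pedigree file
#'
#' Parses the standard whitespace-delimited PED layout (family id,
#' individual id, paternal id, maternal id, sex, phenotype). Phenotype
#' code 2 maps to affected, 1 to unaffected; any other code (including
#' the "missing" codes 0 and -9) is rejected — the segregation test
#' needs a definite status for every sample. Individuals whose parents
#' are both `0` are labelled `"founder"`, the rest `"offspring"`.
#'
#' A family without at least one affected and one unaffected member
#' yields a warning (segregation is vacuous there), not an error.
#'
#' @param path Path to a PED file.
#' @return A [Pedigree].
#'
#' @examples
#' f <- tempfile(fileext = ".ped")
#' writeLines(c("FamA A1 0 0 1 2", "FamA A2 0 0 2 1",
#'              "FamA A3 A1 A2 1 2", "FamA A4 A1 A2 2 1"), f)
#' readPedigree(f)
#'
#' @export
readPedigree <- function(path) {
    if (!file.exists(path))
        stop("PED file not found: '", path, "'")
    tab <- tryCatch(
        read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character"),
        error = function(e)
            stop("cannot parse PED file '", path, "': ",
                 conditionMessage(e), call. = FALSE))
    if (ncol(tab) < 6L)
        stop("PED file '", path, "' must have 6 columns ",
             "(family, individual, father, mother, sex, phenotype)")
    pheno <- tab[[6]]
    bad <- !pheno %in% c("1", "2")
    if (any(bad))
        stop("unsupported phenotype code(s) in '", path, "': ",
             paste(unique(pheno[bad]), collapse = ", "),
             " (expected 1 = unaffected, 2 = affected)")
    Pedigree(family = tab[[1]], sample = tab[[2]],
             affected = pheno == "2",
             role = ifelse(tab[[3]] == "0" & tab[[4]] == "0",
                           "founder", "offspring"))
}

#' Write a Pedigree as a 6-column PED file
#'
#' Parental ids and sex are not modelled by [Pedigree] and are written
#' as `0` (unknown); affection status becomes phenotype 2/1.
#'
#' @param ped A [Pedigree].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(ped, path) {
    df <- as.data.frame(ped)
    lines <- sprintf("%s\t%s\t0\t0\t0\t%d", df$family, df$sample,
                     ifelse(df$affected, 2L, 1L))
    writeLines(lines, path)
    invisible(path)
}

#' Read a BED-like linkage-locus file
#'
#' Reads a tab/whitespace-separated table of linkage loci with columns
#' chrom, start, end, name. Unlike true BED, coordinates are 1-based
#' inclusive on both ends. With `units = "Mb"` the coordinates are
#' megabase values (as printed in linkage-scan tables, e.g.
#' `chr3 122.2 129.5 3q21`) and are converted with the exact factor
#' 10^6. A start equal to its end is a legal width-1 locus; start
#' greater than end is an error naming the offending line.
#'
#' @param path Path to the locus file. Lines starting with `#` are
#'   ignored.
#' @param units `"bp"` (default) or `"Mb"`.
#' @return A [GenomicRanges::GRanges] with locus names as names and a
#'   `locus` metadata column.
#'
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr3\t122.2\t129.5\t3q21", "chr1\t143.2\t155.1\t1q21"), f)
#' readLoci(f, units = "Mb")
#'
#' @export
readLoci <- function(path, units = c("bp", "Mb")) {
    units <- match.arg(units)
    if (!file.exists(path))
        stop("locus file not found: '", path, "'")
    rawLines <- readLines(path)
    keep <- which(nzchar(trimws(rawLines)) & !startsWith(trimws(rawLines), "#"))
    if (!length(keep))
        stop("locus file '", path, "' contains no locus rows")
    scale <- if (units == "Mb") 1e6 else 1
    chrom <- character(length(keep)); nm <- character(length(keep))
    startBp <- integer(length(keep)); endBp <- integer(length(keep))
    for (i in seq_along(keep)) {
        ln <- keep[i]
        fields <- strsplit(trimws(rawLines[ln]), "[ \t]+")[[1]]
        if (length(fields) < 4L)
            stop("locus file '", path, "' line ", ln,
                 ": expected 4 fields (chrom start end name)")
        s <- suppressWarnings(as.numeric(fields[2]))
        e <- suppressWarnings(as.numeric(fields[3]))
        if (is.na(s) || is.na(e))
            stop("locus file '", path, "' line ", ln,
                 ": unparsable coordinate '",
                 fields[2 + is.na(e)], "'")
        s <- as.integer(round(s * scale))
        e <- as.integer(round(e * scale))
        if (s > e)
            stop("locus file '", path, "' line ", ln,
                 ": start (", s, ") exceeds end (", e, ")")
        chrom[i] <- fields[1]; startBp[i] <- s; endBp[i] <- e
        nm[i] <- fields[4]
    }
    gr <- GRanges(chrom, IRanges(startBp, endBp), locus = nm)
    names(gr) <- nm
    gr
}
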