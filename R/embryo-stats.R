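## Embryo quantitation statistics: batch-normalized fluorescence
## intensities, rank-sum tests, boxplot notch widths, scored proportions,
## and smFISH transcript-ratio comparisons.

.halfUp <- function(x) floor(x + 0.5)

.checkIntensityTable <- function(table) {
    need <- c("strain", "experiment", "intensity")
    if (!is.data.frame(table) || !all(need %in% colnames(table)))
        stop("intensity table needs columns: ", paste(need, collapse = ", "))
    if (!all(is.finite(table$intensity)))
        stop("intensities must be finite")
    invisible(table)
}

#' Normalize embryo intensities to a reference strain, per experiment
#'
#' Divides each background-corrected intensity by the mean intensity of
#' the reference strain measured in the same experiment batch, so that
#' the reference strain's normalized mean is exactly 1 in every batch.
#' Batch-wise normalization absorbs day-to-day staining and imaging
#' differences that pooled normalization would leak into strain contrasts.
#'
#' @param table A data.frame with columns `strain`, `experiment`,
#'   `intensity` (arbitrary fluorescence units, background-corrected) and
#'   optionally `embryo`.
#' @param referenceStrain Strain id to normalize against; must appear in
#'   every experiment.
#' @return The input data.frame with an added `normalized` column.
#' @export
normalizeIntensities <- function(table, referenceStrain) {
    .checkIntensityTable(table)
    out <- table
    out$normalized <- NA_real_
    for (ex in unique(table$experiment)) {
        sel <- table$experiment == ex
        refv <- table$intensity[sel & table$strain == referenceStrain]
        if (!length(refv))
            stop("reference strain '", referenceStrain,
                 "' absent from experiment '", ex, "'")
        out$normalized[sel] <- table$intensity[sel] / mean(refv)
    }
    out
}

#' Mean fold change and SD of normalized intensities for one strain
#'
#' @param normalized Output of [normalizeIntensities()].
#' @param strain Strain id to summarise.
#' @return Named numeric vector `c(mean = ..., sd = ...)` (sample SD,
#'   n - 1 denominator). At least two embryos are required.
#' @export
foldChangeSummary <- function(normalized, strain) {
    if (!"normalized" %in% colnames(normalized))
        stop("run normalizeIntensities() first")
    v <- normalized$normalized[normalized$strain == strain]
    if (length(v) < 2L)
        stop("need >= 2 embryos for strain '", strain, "'")
    c(mean = mean(v), sd = stats::sd(v))
}

#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' corrections. This is the test used to compare per-embryo intensity
#' distributions between strains.
#'
#' @param x,y Numeric samples, each non-empty.
#' @return Two-sided p-value.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))  # 0.1 by exact enumeration
#' @export
rankSumTest <- function(x, y) {
    if (!length(x) || !length(y))
        stop("both samples must be non-empty")
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- (length(x) + length(y) <= 20L) && !ties
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
}

#' Boxplot notch half-width
#'
#' The notch half-width 1.6 IQR / sqrt(n): two medians are judged
#' significantly different when their notches do not overlap. Quartiles
#' use linear-interpolation (type 7) quantiles.
#'
#' @param values Numeric sample, n >= 1.
#' @return Notch half-width in the units of `values`.
#' @examples
#' notchHalfwidth(rep(c(1, 3), 8))  # IQR 2, n 16 -> 0.8
#' @export
notchHalfwidth <- function(values) {
    stopifnot(is.numeric(values), length(values) >= 1L,
              all(is.finite(values)))
    1.6 * stats::IQR(values, type = 7) / sqrt(length(values))
}

#' Percent-positive summary of scored count data
#'
#' For each group, computes 100 x positive / (positive + negative),
#' rounded half-up to the nearest integer — the convention used for
#' gut-granule scoring tables.
#'
#' @param table A data.frame with columns `group`, `positive`, `negative`
#'   (non-negative integer counts; each group total must be > 0).
#' @return The input with added columns `n` (total scored) and
#'   `percent_positive` (integer percent).
#' @examples
#' proportionTable(data.frame(group = "N2", positive = 181, negative = 365))
#' @export
proportionTable <- function(table) {
    need <- c("group", "positive", "negative")
    if (!is.data.frame(table) || !all(need %in% colnames(table)))
        stop("count table needs columns: ", paste(need, collapse = ", "))
    pos <- table$positive; neg <- table$negative
    if (any(pos < 0) || any(neg < 0) || any(pos != round(pos)) ||
        any(neg != round(neg)))
        stop("counts must be non-negative integers")
    n <- pos + neg
    if (any(n == 0))
        stop("every group must have a positive total count")
    out <- table
    out$n <- as.integer(n)
    out$percent_positive <- as.integer(.halfUp(100 * pos / n))
    out
}

.checkSmfish <- function(embryos) {
    need <- c("genotype", "stage", "end1_count", "set3_count")
    if (!is.data.frame(embryos) || !all(need %in% colnames(embryos)))
        stop("smFISH table needs columns: ", paste(need, collapse = ", "))
    if (any(embryos$end1_count < 0) || any(embryos$set3_count < 0))
        stop("molecule counts must be non-negative")
    invisible(embryos)
}

#' Compare smFISH transcript ratios between genotypes at one stage
#'
#' Computes the per-embryo ratio of end-1 mRNA molecules to set-3 mRNA
#' molecules (set-3 is the ubiquitously expressed internal control) and
#' compares the two genotypes with a two-sided two-sample t test. The
#' default is the pooled-variance Student test; set `varEqual = FALSE`
#' for Welch. Embryos with a zero set-3 count have no defined ratio and
#' are dropped with a message.
#'
#' @param embryos A data.frame with columns `genotype`, `stage`,
#'   `end1_count`, `set3_count`.
#' @param genotypeA,genotypeB Genotype labels to compare.
#' @param stage Embryonic stage to restrict to (e.g. "8-cell").
#' @param varEqual Pool the variances (Student) or not (Welch).
#' @return Two-sided p-value.
#' @export
smfishRatioTest <- function(embryos, genotypeA, genotypeB, stage,
                            varEqual = TRUE) {
    .checkSmfish(embryos)
    sel <- embryos$stage == stage &
        embryos$genotype %in% c(genotypeA, genotypeB)
    e <- embryos[sel, , drop = FALSE]
    drop <- e$set3_count == 0
    if (any(drop)) {
        message("smfishRatioTest: dropping ", sum(drop),
                " embryo(s) with zero set-3 count")
        e <- e[!drop, , drop = FALSE]
    }
    ratio <- e$end1_count / e$set3_count
    a <- ratio[e$genotype == genotypeA]
    b <- ratio[e$genotype == genotypeB]
    if (length(a) < 2L || length(b) < 2L)
        stop("need >= 2 embryos per genotype at stage '", stage, "'")
    stats::t.test(a, b, var.equal = varEqual,
                  alternative = "two.sided")$p.value
}
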