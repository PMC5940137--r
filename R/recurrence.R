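## Mutability-calibrated recurrence scoring of multiply-hit genes.
##
## A gene hit in k of S independently mutagenized strains is suspicious
## only relative to how easily that gene collects mutations. The per-genome
## hit probability p for gene g is estimated from a sequenced mutagenized
## reference panel as p = m / N, where m is the number of panel strains
## with a coding hit in g and N the panel size. The chance of seeing the
## observed recurrence among S screened strains is then binomial in S and
## p. The "point" mode scores the probability of exactly k hit strains,
## C(S,k) p^k (1-p)^(S-k); the "tail" mode scores P(>= k hits). Point is
## the default because it reproduces the published candidate tables; the
## tail is the conventional enrichment formulation and is recommended for
## new screens (see the vignette).

#' Per-genome hit probability from panel counts
#'
#' @param m Number of panel strains with a coding hit in the gene.
#' @param panelSize Number of strains in the panel.
#' @return `m / panelSize`, the estimated probability that one comparably
#'   mutagenized genome carries a hit in the gene.
#' @examples
#' perGenomeProbability(6, 2007)
#' @export
perGenomeProbability <- function(m, panelSize = 2007) {
    stopifnot(is.numeric(m), is.numeric(panelSize), panelSize > 0)
    if (any(m < 0) || any(m > panelSize))
        stop("panel count m must satisfy 0 <= m <= panelSize")
    m / panelSize
}

#' Binomial probability of recurrent hits in a gene
#'
#' Probability that k of S screened strains carry a hit in a gene whose
#' per-genome hit probability is p = scale * m / panelSize. `mode =
#' "point"` gives the probability of exactly k hit strains; `mode = "tail"`
#' the probability of k or more. The optional `scale` deflates p when the
#' screen's mutagenesis is weaker than the panel's (with the default
#' scale = 1 the probabilities are conservative over-estimates in that
#' situation).
#'
#' @inheritParams perGenomeProbability
#' @param k Observed number of hit strains.
#' @param S Number of strains screened.
#' @param mode `"point"` (exactly k) or `"tail"` (at least k).
#' @param scale Mutagenesis-strength factor multiplying p (default 1).
#' @return A probability in \[0, 1\]; vectorized over `m` and `k`.
#' @examples
#' recurrenceProbability(m = 6, k = 4, S = 17, panelSize = 2007)
#' recurrenceProbability(m = 250, k = 2, S = 17, mode = "tail")
#' @export
recurrenceProbability <- function(m, k, S = 17L, panelSize = 2007,
                                  mode = c("point", "tail"), scale = 1) {
    mode <- match.arg(mode)
    stopifnot(is.numeric(k), is.numeric(S), length(S) == 1L, S >= 0,
              is.numeric(scale), length(scale) == 1L, scale > 0)
    if (any(k < 0) || any(k > S))
        stop("number of hit strains k must satisfy 0 <= k <= S")
    p <- perGenomeProbability(m, panelSize) * scale
    if (any(p > 1))
        stop("scaled per-genome probability exceeds 1")
    if (mode == "point")
        stats::dbinom(k, size = S, prob = p)
    else
        stats::pbinom(k - 1, size = S, prob = p, lower.tail = FALSE)
}

#' Format a probability with one significant digit
#'
#' Scientific notation in the candidate-table style: one significant
#' mantissa digit, rounded half-up with carry into the exponent when the
#' mantissa rounds to 10 (0.095 -> "1.E-01"), exponent printed with sign
#' and two digits ("2.E-07", "3.E-01").
#'
#' @param prob Probability (vectorized), each in \[0, 1\].
#' @return Character vector of formatted strings; 0 prints "0.E+00".
#' @examples
#' formatProbability(c(1.83e-7, 0.28685, 0.095))
#' @export
formatProbability <- function(prob) {
    stopifnot(is.numeric(prob))
    if (any(is.na(prob)) || any(prob < 0) || any(prob > 1))
        stop("probabilities must lie in [0, 1]")
    vapply(prob, function(p) {
        if (p == 0) return("0.E+00")
        e <- floor(log10(p) + 1e-12)
        d <- floor(p / 10^e + 0.5)
        if (d >= 10) { d <- 1; e <- e + 1 }
        sprintf("%d.E%+03d", as.integer(d), as.integer(e))
    }, character(1))
}

#' Parse a one-significant-digit probability string back to a number
#'
#' @param s Strings in the "D.E-XX" style produced by [formatProbability()].
#' @return Numeric vector.
#' @export
parseProbability <- function(s) {
    ok <- grepl("^[0-9]\\.E[+-][0-9]{2}$", s)
    if (!all(ok)) stop("not in 'D.E-XX' format: ",
                       paste(s[!ok], collapse = ", "))
    as.numeric(sub("\\.E", "e", s))
}

#' Rank multiply-hit genes by recurrence probability
#'
#' Builds one [RecurrenceResult][rankCandidates] row per gene hit in at
#' least `minK` strains, scored with [recurrenceProbability()] and sorted
#' by ascending probability (ties: descending k, then gene id). Genes
#' absent from the mutability table receive the table's median count as a
#' fallback and are flagged in `mmp_missing`, so candidates are never
#' silently dropped for lacking a panel entry.
#'
#' @param matrix A [GeneHitMatrix].
#' @param table A [MutabilityTable].
#' @param minK Minimum number of hit strains to report (default 2).
#' @inheritParams recurrenceProbability
#' @return A data.frame with columns `gene_id`, `k`, `S`, `m`, `p`,
#'   `prob`, `prob_text`, `rank`, `mmp_missing`.
#' @export
rankCandidates <- function(matrix, table, minK = 2L,
                           mode = c("point", "tail"), scale = 1) {
    stopifnot(methods::is(matrix, "GeneHitMatrix"),
              methods::is(table, "MutabilityTable"), minK >= 0L)
    mode <- match.arg(mode)
    k <- hitCounts(matrix)
    S <- ncol(hits(matrix))
    keep <- k >= minK
    if (!any(keep))
        return(data.frame(gene_id = character(0), k = integer(0),
                          S = integer(0), m = integer(0), p = numeric(0),
                          prob = numeric(0), prob_text = character(0),
                          rank = integer(0), mmp_missing = logical(0),
                          stringsAsFactors = FALSE))
    gene <- names(k)[keep]
    k <- unname(k[keep])
    cnt <- panelCounts(table)
    missing <- !(gene %in% names(cnt))
    fallback <- if (length(cnt)) as.integer(round(stats::median(cnt))) else 0L
    m <- ifelse(missing, fallback, cnt[gene])
    prob <- recurrenceProbability(m, k, S = S, panelSize = panelSize(table),
                                  mode = mode, scale = scale)
    out <- data.frame(gene_id = gene, k = k, S = S, m = as.integer(m),
                      p = perGenomeProbability(m, panelSize(table)) * scale,
                      prob = prob, prob_text = formatProbability(prob),
                      mmp_missing = missing, stringsAsFactors = FALSE)
    o <- order(out$prob, -out$k, out$gene_id)
    out <- out[o, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out[, c("gene_id", "k", "S", "m", "p", "prob", "prob_text", "rank",
            "mmp_missing")]
}

#' Expected number of genes recurrently hit by chance
#'
#' Sums, over every gene in the mutability table, the tail probability of
#' at least k hits among S strains — the expected count of genes that
#' would reach the recurrence threshold by mutability alone. This supplies
#' genome-wide context for per-gene probabilities without applying a
#' formal multiple-testing correction.
#'
#' @param table A [MutabilityTable].
#' @inheritParams recurrenceProbability
#' @return Expected number of genes with >= k hit strains.
#' @export
expectedMultihitGenes <- function(table, S = 17L, k = 2L, scale = 1) {
    stopifnot(methods::is(table, "MutabilityTable"), k >= 2L)
    cnt <- panelCounts(table)
    if (!length(cnt)) return(0)
    sum(recurrenceProbability(unname(cnt), k, S = S,
                              panelSize = panelSize(table),
                              mode = "tail", scale = scale))
}
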