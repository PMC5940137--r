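## Independent oracles used across the suite. These deliberately avoid the
## package's internal coordinate machinery: effects are derived by
## rebuilding the whole CDS, substituting the base at genomic level,
## translating both full proteins and diffing them.

.oracleRevComp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

.oracleTranslate <- function(cds) {
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    unname(Biostrings::GENETIC_CODE[codons])
}

## models: a GeneModelSet; genomeChar: named character vector of contigs.
## Returns the oracle effect of substituting `alt` at (contig, pos) with
## respect to gene `gid`, or "intronic"/"outside".
oracleEffect <- function(models, genomeChar, gid, contig, pos, alt) {
    gi <- match(gid, geneIds(models))
    span <- geneSpans(models)[gi]
    cds <- cdsRanges(models)[[gi]]
    strand <- as.character(GenomicRanges::strand(span))
    if (as.character(GenomicRanges::seqnames(span)) != contig ||
        pos < GenomicRanges::start(span) || pos > GenomicRanges::end(span))
        return("outside")
    starts <- GenomicRanges::start(cds); ends <- GenomicRanges::end(cds)
    if (!any(pos >= starts & pos <= ends)) return("intronic")
    seqc <- genomeChar[[contig]]
    getCds <- function(sq) {
        s <- paste(substring(sq, starts, ends), collapse = "")
        if (strand == "-") .oracleRevComp(s) else s
    }
    mut <- seqc
    substr(mut, pos, pos) <- alt
    aaRef <- .oracleTranslate(getCds(seqc))
    aaAlt <- .oracleTranslate(getCds(mut))
    if (identical(aaRef, aaAlt)) return("synonymous")
    i <- which(aaRef != aaAlt)[1]
    if (aaAlt[i] == "*") return("nonsense")
    if (aaRef[i] == "*") return("stop_loss")
    refCodon1 <- substring(getCds(seqc), 1, 3)
    if (i == 1 && refCodon1 == "ATG") return("start_loss")
    "missense"
}

## Exact two-sided rank-sum p-value by full enumeration of labelings.
## Valid without ties (the null W distribution is then symmetric, so the
## distance-from-mean definition coincides with the doubled tail).
enumRankSumP <- function(x, y) {
    n <- length(x); m <- length(y)
    r <- rank(c(x, y))
    mu <- n * m / 2
    wObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    combs <- utils::combn(n + m, n)
    ws <- apply(combs, 2, function(idx) sum(r[idx])) - n * (n + 1) / 2
    mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
}

## Naive motif census by substring enumeration.
enumMotifSites <- function(protein, alphabet) {
    s <- toupper(protein)
    stopAt <- regexpr("*", s, fixed = TRUE)
    if (stopAt > 0) s <- substring(s, 1, stopAt - 1)
    hits <- integer(0)
    if (nchar(s) >= 4) {
        for (i in seq_len(nchar(s) - 3)) {
            w <- substring(s, i, i + 3)
            if (substring(w, 1, 1) == "Q" &&
                substring(w, 2, 2) %in% alphabet &&
                substring(w, 3, 3) == "D" && substring(w, 4, 4) == "G")
                hits <- c(hits, i)
        }
    }
    hits
}

## Random strain variant set on a simple 1-contig "genome" of given length.
randomVariantSet <- function(id, n, contig = "chrT", len = 10000L,
                             genomeChar = NULL) {
    pos <- sample.int(len, n)
    if (is.null(genomeChar)) {
        ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    } else {
        ref <- substring(genomeChar[[contig]], pos, pos)
    }
    alt <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    StrainVariantSet(id, rep(contig, n), pos, ref, alt)
}
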