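## Taspase cleavage-motif scanning. The tetrad Q-x-D-G (cleavage between
## D and G) with x in {F, I, L, M} is the site determined for Drosophila
## Taspase; human Taspase1 additionally accepts V at the second position,
## so the alphabet is configurable.

.AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWYUOBXZJ*", "")[[1]]

#' Find taspase cleavage-site motifs in one protein
#'
#' Reports every 1-based start of a Q\[alphabet\]DG tetrad. Matching is
#' case-insensitive; scanning stops at the first stop character (`*`), so
#' sequence after a premature stop is never searched.
#'
#' @param protein A single amino-acid string (one-letter codes) or a
#'   [Biostrings::AAString].
#' @param alphabet Letters accepted at the second motif position.
#' @return Integer vector of match start positions (possibly empty).
#' @examples
#' findCleavageSites("AAQMDGAA")               # 3
#' findCleavageSites("QVDG")                   # none with the default
#' findCleavageSites("QVDG", c("F","I","L","M","V"))
#' @export
findCleavageSites <- function(protein, alphabet = c("F", "I", "L", "M")) {
    if (methods::is(protein, "AAString") || methods::is(protein, "XString"))
        protein <- as.character(protein)
    stopifnot(is.character(protein), length(protein) == 1L)
    stopifnot(length(alphabet) > 0L, all(nchar(alphabet) == 1L))
    alphabet <- toupper(alphabet)
    if (!all(alphabet %in% setdiff(.AA_LETTERS, "*")))
        stop("alphabet must be single-letter amino-acid codes")
    s <- toupper(protein)
    chars <- strsplit(s, "")[[1]]
    if (!all(chars %in% .AA_LETTERS))
        stop("non-amino-acid character(s) in protein sequence: ",
             paste(unique(chars[!chars %in% .AA_LETTERS]), collapse = ", "))
    stopAt <- regexpr("*", s, fixed = TRUE)
    if (stopAt > 0L) s <- substring(s, 1L, stopAt - 1L)
    if (nchar(s) < 4L) return(integer(0))
    ## zero-width lookahead reports every start, overlapping or not
    pat <- sprintf("(?=Q[%s]DG)", paste(alphabet, collapse = ""))
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Census a proteome for taspase cleavage motifs
#'
#' Scans every sequence with [findCleavageSites()] and counts proteins
#' carrying at least one site — each protein counts once however many
#' sites it has.
#'
#' @param proteome A named [Biostrings::AAStringSet] or named character
#'   vector of protein sequences.
#' @inheritParams findCleavageSites
#' @return A list with `count` (proteins with >= 1 site), `total`
#'   (proteins scanned) and `detail`, a data.frame of (protein, start) for
#'   every site found.
#' @export
motifCensus <- function(proteome, alphabet = c("F", "I", "L", "M")) {
    if (methods::is(proteome, "AAStringSet"))
        proteome <- stats::setNames(as.character(proteome), names(proteome))
    stopifnot(is.character(proteome))
    if (is.null(names(proteome)) || any(!nzchar(names(proteome))))
        stop("proteome sequences must be named")
    sites <- lapply(proteome, findCleavageSites, alphabet = alphabet)
    n <- lengths(sites)
    detail <- data.frame(
        protein = rep(names(proteome), n),
        start = as.integer(unlist(sites, use.names = FALSE)),
        stringsAsFactors = FALSE)
    rownames(detail) <- NULL
    list(count = sum(n > 0L), total = length(proteome), detail = detail)
}
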