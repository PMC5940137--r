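## Central S4 containers for the screen-analysis pipeline.

#' @rdname StrainVariantSet-class
#' @export
setGeneric("strainId", function(x) standardGeneric("strainId"))

#' @rdname StrainVariantSet-class
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneSpans", function(x) standardGeneric("geneSpans"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))

#' @rdname MutabilityTable-class
#' @export
setGeneric("panelSize", function(x) standardGeneric("panelSize"))

#' @rdname MutabilityTable-class
#' @export
setGeneric("panelCounts", function(x) standardGeneric("panelCounts"))

#' @rdname GeneHitMatrix-class
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))

#' @rdname GeneHitMatrix-class
#' @export
setGeneric("qualifyingEffects", function(x) standardGeneric("qualifyingEffects"))

#' @rdname GeneHitMatrix-class
#' @export
setGeneric("hitCounts", function(x) standardGeneric("hitCounts"))

#' Coding-effect vocabulary
#'
#' The effect categories assigned by [annotateVariants()], and the subset
#' counted as candidate-qualifying by default (coding changes that alter the
#' protein: missense, nonsense, stop-loss, start-loss).
#'
#' @return A character vector of effect labels.
#' @examples
#' codingEffects()
#' qualifyingEffectsDefault()
#' @export
codingEffects <- function() {
    c("intergenic", "intronic", "synonymous", "missense", "nonsense",
      "stop_loss", "start_loss")
}

#' @rdname codingEffects
#' @export
qualifyingEffectsDefault <- function() {
    c("missense", "nonsense", "stop_loss", "start_loss")
}

#' StrainVariantSet: homozygous SNVs called in one strain
#'
#' A container for the single-nucleotide variant calls of one sequenced
#' strain on a shared reference genome. Variants are kept sorted by
#' (contig, position) and deduplicated on the (contig, position, alt)
#' triple. Only single-base substitutions are modelled: strains in an EMS
#' screen are propagated for several generations before sequencing, so
#' calls are treated as homozygous and genotype fields are ignored.
#'
#' @slot strainId Single character identifier of the strain.
#' @slot calls A [GenomicRanges::GRanges] of width-1 positions with
#'   metadata columns `ref` and `alt` (single DNA bases, `ref != alt`).
#'
#' @param strainId Character scalar naming the strain.
#' @param contig,pos,ref,alt Parallel vectors describing the variant calls.
#' @param x A `StrainVariantSet`.
#'
#' @return `StrainVariantSet()` returns a validated object; `strainId()`
#'   the strain identifier; `variants()` the `GRanges` of calls.
#' @examples
#' svs <- StrainVariantSet("s1", c("chrI", "chrI"), c(100L, 50L),
#'                         c("G", "C"), c("A", "T"))
#' variants(svs)
#' @aliases strainId variants
#' @export StrainVariantSet
#' @exportClass StrainVariantSet
setClass("StrainVariantSet",
    slots = c(strainId = "character", calls = "GRanges"))

setValidity("StrainVariantSet", function(object) {
    msg <- character(0)
    if (length(object@strainId) != 1L || is.na(object@strainId) ||
        !nzchar(object@strainId))
        msg <- c(msg, "'strainId' must be a single non-empty string")
    gr <- object@calls
    mc <- S4Vectors::mcols(gr)
    if (!all(c("ref", "alt") %in% colnames(mc)))
        return(c(msg, "calls must carry 'ref' and 'alt' metadata columns"))
    ref <- mc$ref; alt <- mc$alt
    if (length(gr)) {
        if (any(GenomicRanges::start(gr) < 1L))
            msg <- c(msg, "positions must be >= 1")
        if (any(GenomicRanges::width(gr) != 1L))
            msg <- c(msg, "variant ranges must have width 1 (SNVs only)")
        if (!all(nchar(ref) == 1L & nchar(alt) == 1L))
            msg <- c(msg, "ref and alt alleles must be single bases")
        if (!all(ref %in% c("A", "C", "G", "T")) ||
            !all(alt %in% c("A", "C", "G", "T")))
            msg <- c(msg, "alleles must be A/C/G/T")
        if (any(ref == alt))
            msg <- c(msg, "ref and alt alleles must differ")
        key <- paste(as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr), alt)
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (contig, position, alt) triples")
        o <- order(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr))
        if (!identical(o, seq_along(gr)))
            msg <- c(msg, "calls must be sorted by (contig, position)")
    }
    if (length(msg)) msg else TRUE
})

StrainVariantSet <- function(strainId, contig = character(0),
                             pos = integer(0), ref = character(0),
                             alt = character(0)) {
    stopifnot(length(contig) == length(pos), length(pos) == length(ref),
              length(ref) == length(alt))
    contig <- as.character(contig)
    pos <- as.integer(pos)
    ref <- toupper(as.character(ref))
    alt <- toupper(as.character(alt))
    key <- paste(contig, pos, alt)
    keep <- !duplicated(key)
    contig <- contig[keep]; pos <- pos[keep]
    ref <- ref[keep]; alt <- alt[keep]
    o <- order(contig, pos)
    gr <- GenomicRanges::GRanges(contig[o], IRanges::IRanges(pos[o], width = 1L),
                                 ref = ref[o], alt = alt[o])
    methods::new("StrainVariantSet", strainId = strainId, calls = gr)
}

#' @rdname StrainVariantSet-class
#' @export
setMethod("strainId", "StrainVariantSet", function(x) x@strainId)

#' @rdname StrainVariantSet-class
#' @export
setMethod("variants", "StrainVariantSet", function(x) x@calls)

#' @rdname StrainVariantSet-class
#' @export
setMethod("length", "StrainVariantSet", function(x) length(x@calls))

setMethod("show", "StrainVariantSet", function(object) {
    cat("StrainVariantSet '", object@strainId, "' with ",
        length(object@calls), " SNV call(s)\n", sep = "")
    if (length(object@calls)) {
        df <- variantFrame(object)
        utils::head(df, 5L) |> print()
        if (nrow(df) > 5L) cat("... and", nrow(df) - 5L, "more\n")
    }
})

#' Variant calls as a plain data.frame
#'
#' @param x A [StrainVariantSet].
#' @return A data.frame with columns contig, pos, ref, alt.
#' @export
variantFrame <- function(x) {
    stopifnot(methods::is(x, "StrainVariantSet"))
    gr <- x@calls
    data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
               pos = GenomicRanges::start(gr),
               ref = S4Vectors::mcols(gr)$ref,
               alt = S4Vectors::mcols(gr)$alt,
               stringsAsFactors = FALSE)
}

#' GeneModelSet: CDS structures of protein-coding genes
#'
#' Gene models on named contigs: for each gene a strand, a gene span, and a
#' sorted set of non-overlapping CDS intervals (1-based, closed, as in
#' GFF3). A single CDS chain is kept per gene (no isoforms). Coordinates
#' stay 1-based closed throughout; conversion happens only when slicing
#' sequence.
#'
#' @slot genes A [GenomicRanges::GRanges] of gene spans, named by gene id,
#'   with strand `+` or `-`.
#' @slot cds A [GenomicRanges::GRangesList], parallel to `genes`, of CDS
#'   intervals sorted by start.
#'
#' @param genes,cds See slots; `cds` names must match `genes` names.
#' @param x A `GeneModelSet`.
#'
#' @return `GeneModelSet()` a validated object; `geneIds()` the gene
#'   identifiers; `geneSpans()` the span `GRanges`; `cdsRanges()` the CDS
#'   `GRangesList`.
#' @aliases geneIds geneSpans cdsRanges
#' @export GeneModelSet
#' @exportClass GeneModelSet
setClass("GeneModelSet",
    slots = c(genes = "GRanges", cds = "GRangesList"))

setValidity("GeneModelSet", function(object) {
    msg <- character(0)
    g <- object@genes
    cds <- object@cds
    if (length(g) != length(cds))
        return("genes and cds must be parallel")
    if (length(g)) {
        if (is.null(names(g)) || anyDuplicated(names(g)) ||
            !identical(names(g), names(cds)))
            msg <- c(msg, "genes and cds must share unique, matching names")
        if (!all(as.character(GenomicRanges::strand(g)) %in% c("+", "-")))
            msg <- c(msg, "strand must be '+' or '-' for every gene")
        for (i in seq_along(g)) {
            ci <- cds[[i]]
            if (!length(ci)) { msg <- c(msg, "gene without CDS"); next }
            s <- GenomicRanges::start(ci); e <- GenomicRanges::end(ci)
            if (is.unsorted(s, strictly = TRUE) && length(ci) > 1L)
                msg <- c(msg, "CDS intervals must be sorted by start")
            if (length(ci) > 1L && any(s[-1L] <= e[-length(e)]))
                msg <- c(msg, "CDS intervals must not overlap")
            if (min(s) < GenomicRanges::start(g)[i] ||
                max(e) > GenomicRanges::end(g)[i])
                msg <- c(msg, "gene span must contain all CDS intervals")
            if (!all(as.character(GenomicRanges::seqnames(ci)) ==
                     as.character(GenomicRanges::seqnames(g)[i])))
                msg <- c(msg, "CDS contig differs from gene contig")
        }
    }
    if (length(msg)) unique(msg) else TRUE
})

GeneModelSet <- function(genes, cds) {
    methods::new("GeneModelSet", genes = genes,
                 cds = methods::as(cds, "GRangesList"))
}

#' @rdname GeneModelSet-class
#' @export
setMethod("geneIds", "GeneModelSet", function(x) names(x@genes))

#' @rdname GeneModelSet-class
#' @export
setMethod("geneSpans", "GeneModelSet", function(x) x@genes)

#' @rdname GeneModelSet-class
#' @export
setMethod("cdsRanges", "GeneModelSet", function(x) x@cds)

#' @rdname GeneModelSet-class
#' @export
setMethod("length", "GeneModelSet", function(x) length(x@genes))

setMethod("show", "GeneModelSet", function(object) {
    cat("GeneModelSet with", length(object@genes), "gene model(s) on",
        length(unique(as.character(
            GenomicRanges::seqnames(object@genes)))), "contig(s)\n")
})

#' Total CDS length of each gene
#'
#' @param x A [GeneModelSet].
#' @return Named integer vector of summed CDS widths.
#' @export
cdsLengths <- function(x) {
    stopifnot(methods::is(x, "GeneModelSet"))
    vapply(x@cds, function(g) sum(GenomicRanges::width(g)), integer(1))
}

#' MutabilityTable: per-gene hit counts from a mutagenized reference panel
#'
#' Per-gene counts of strains carrying a coding hit in a sequenced,
#' mutagenized reference panel of known size (for C. elegans, the Million
#' Mutation Project panel of 2007 strains). The count m for gene g divided
#' by the panel size N estimates the per-genome probability p = m/N that a
#' comparably mutagenized genome carries a hit in g, which calibrates the
#' recurrence score.
#'
#' @slot panelSize Integer number of strains in the panel.
#' @slot counts Named non-negative integer vector, gene id -> panel hits.
#'
#' @param counts Named integer vector of per-gene panel hit counts.
#' @param panelSize Integer panel size; every count must be <= panelSize.
#' @param x A `MutabilityTable`.
#'
#' @return `MutabilityTable()` a validated object; `panelSize()` the panel
#'   size; `panelCounts()` the named count vector.
#' @examples
#' mt <- MutabilityTable(c(`K01G5.9` = 6L, `dig-1` = 250L), panelSize = 2007L)
#' panelCounts(mt)
#' @aliases panelSize panelCounts
#' @export MutabilityTable
#' @exportClass MutabilityTable
setClass("MutabilityTable",
    slots = c(panelSize = "integer", counts = "integer"))

setValidity("MutabilityTable", function(object) {
    msg <- character(0)
    if (length(object@panelSize) != 1L || is.na(object@panelSize) ||
        object@panelSize <= 0L)
        msg <- c(msg, "'panelSize' must be a single positive integer")
    cnt <- object@counts
    if (length(cnt)) {
        if (is.null(names(cnt)) || anyDuplicated(names(cnt)))
            msg <- c(msg, "counts must have unique gene-id names")
        if (any(is.na(cnt)) || any(cnt < 0L))
            msg <- c(msg, "counts must be non-negative")
        if (!any(is.na(object@panelSize)) && length(object@panelSize) == 1L &&
            any(cnt > object@panelSize, na.rm = TRUE))
            msg <- c(msg, "counts cannot exceed panelSize")
    }
    if (length(msg)) msg else TRUE
})

MutabilityTable <- function(counts, panelSize = 2007L) {
    methods::new("MutabilityTable",
                 panelSize = as.integer(panelSize),
                 counts = stats::setNames(as.integer(counts), names(counts)))
}

#' @rdname MutabilityTable-class
#' @export
setMethod("panelSize", "MutabilityTable", function(x) x@panelSize)

#' @rdname MutabilityTable-class
#' @export
setMethod("panelCounts", "MutabilityTable", function(x) x@counts)

setMethod("show", "MutabilityTable", function(object) {
    cat("MutabilityTable:", length(object@counts), "gene(s), panel of",
        object@panelSize, "strain(s)\n")
})

#' GeneHitMatrix: gene-by-strain incidence of qualifying coding hits
#'
#' Boolean incidence matrix over candidate genes (rows) and screened
#' strains (columns): `hits[g, s]` is TRUE when strain s carries at least
#' one variant in gene g whose coding effect is in the qualifying set.
#' Incidence, not multiplicity: several qualifying variants in the same
#' gene of one strain still count that strain once, so the per-gene hit
#' count k is a number of strains.
#'
#' @slot hits Logical matrix, rownames = gene ids, colnames = strain ids.
#' @slot qualifying Character vector of effects that were counted.
#'
#' @param hits,qualifying See slots.
#' @param x A `GeneHitMatrix`.
#'
#' @return `GeneHitMatrix()` a validated object; `hits()` the logical
#'   matrix; `hitCounts()` the per-gene strain counts k; `qualifyingEffects()`
#'   the counted effect subset.
#' @aliases hits hitCounts qualifyingEffects
#' @export GeneHitMatrix
#' @exportClass GeneHitMatrix
setClass("GeneHitMatrix",
    slots = c(hits = "matrix", qualifying = "character"))

setValidity("GeneHitMatrix", function(object) {
    msg <- character(0)
    h <- object@hits
    if (!is.logical(h) || any(is.na(h)))
        msg <- c(msg, "'hits' must be a logical matrix without NAs")
    if (is.null(rownames(h)) && nrow(h) > 0L)
        msg <- c(msg, "'hits' must have gene-id rownames")
    if (is.null(colnames(h)) && ncol(h) > 0L)
        msg <- c(msg, "'hits' must have strain-id colnames")
    if (anyDuplicated(rownames(h)) || anyDuplicated(colnames(h)))
        msg <- c(msg, "gene and strain ids must be unique")
    if (!all(object@qualifying %in% codingEffects()))
        msg <- c(msg, "unknown qualifying effect label")
    if (length(msg)) msg else TRUE
})

GeneHitMatrix <- function(hits, qualifying = qualifyingEffectsDefault()) {
    methods::new("GeneHitMatrix", hits = hits, qualifying = qualifying)
}

#' @rdname GeneHitMatrix-class
#' @export
setMethod("hits", "GeneHitMatrix", function(x) x@hits)

#' @rdname GeneHitMatrix-class
#' @export
setMethod("qualifyingEffects", "GeneHitMatrix", function(x) x@qualifying)

#' @rdname GeneHitMatrix-class
#' @export
setMethod("hitCounts", "GeneHitMatrix", function(x) {
    if (nrow(x@hits) == 0L) return(stats::setNames(integer(0), character(0)))
    apply(x@hits, 1L, sum) |> as.integer() |>
        stats::setNames(rownames(x@hits))
})

#' @rdname GeneHitMatrix-class
#' @export
setMethod("dim", "GeneHitMatrix", function(x) dim(x@hits))

setMethod("show", "GeneHitMatrix", function(object) {
    k <- hitCounts(object)
    cat("GeneHitMatrix:", nrow(object@hits), "gene(s) x",
        ncol(object@hits), "strain(s); qualifying effects:",
        paste(object@qualifying, collapse = ", "), "\n")
    if (length(k))
        cat("  genes hit in >1 strain:", sum(k >= 2L), "\n")
})
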