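## Variant triage: parental-background subtraction, coding-effect
## annotation against gene models + reference sequence, hit-matrix
## assembly.

#' Remove parental-background variant calls from a strain
#'
#' Drops every call of `strain` whose (contig, position, alt) triple is
#' also present in the parental set, keeping order. Calls shared with the
#' un-mutagenized parental strain are pre-existing background, not induced
#' mutations, so they are eliminated before candidate hunting. The
#' operation is idempotent and may return an empty set.
#'
#' @param strain,parental [StrainVariantSet] objects on the same reference.
#' @return A [StrainVariantSet] with the parental calls removed.
#' @examples
#' s <- StrainVariantSet("s1", c("chrI", "chrI"), c(10L, 20L),
#'                       c("G", "C"), c("A", "T"))
#' p <- StrainVariantSet("par", "chrI", 10L, "G", "A")
#' variantFrame(subtractParental(s, p))
#' @export
subtractParental <- function(strain, parental) {
    stopifnot(methods::is(strain, "StrainVariantSet"),
              methods::is(parental, "StrainVariantSet"))
    sdf <- variantFrame(strain)
    pdf <- variantFrame(parental)
    keep <- !(paste(sdf$contig, sdf$pos, sdf$alt) %in%
              paste(pdf$contig, pdf$pos, pdf$alt))
    StrainVariantSet(strainId(strain), sdf$contig[keep], sdf$pos[keep],
                     sdf$ref[keep], sdf$alt[keep])
}

## Map a transcript-orientation CDS position (1..CDS length) of one gene
## to its genomic coordinate. `gene` is a list(strand, starts, ends) with
## intervals ascending.
.cdsToGenomic <- function(gene, cdsPos) {
    w <- gene$ends - gene$starts + 1L
    if (gene$strand == "+") {
        cum <- cumsum(w)
        i <- findInterval(cdsPos - 1L, c(0L, cum), rightmost.closed = FALSE)
        off <- cdsPos - c(0L, cum)[i] - 1L
        gene$starts[i] + off
    } else {
        ## transcript order walks intervals from the last one leftwards
        wRev <- rev(w)
        cum <- cumsum(wRev)
        i <- findInterval(cdsPos - 1L, c(0L, cum), rightmost.closed = FALSE)
        off <- cdsPos - c(0L, cum)[i] - 1L
        rev(gene$ends)[i] - off
    }
}

## Inverse: genomic coordinate inside a CDS interval -> transcript position.
.genomicToCds <- function(gene, gpos) {
    w <- gene$ends - gene$starts + 1L
    i <- which(gpos >= gene$starts & gpos <= gene$ends)
    if (!length(i)) return(NA_integer_)
    if (gene$strand == "+") {
        before <- if (i > 1L) sum(w[seq_len(i - 1L)]) else 0L
        before + (gpos - gene$starts[i] + 1L)
    } else {
        n <- length(w)
        after <- if (i < n) sum(w[seq(i + 1L, n)]) else 0L
        after + (gene$ends[i] - gpos + 1L)
    }
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Plain-list view of a GeneModelSet for fast per-variant arithmetic.
.modelList <- function(models) {
    spans <- geneSpans(models)
    cds <- cdsRanges(models)
    lapply(seq_along(spans), function(i) {
        ci <- cds[[i]]
        list(gene_id = names(spans)[i],
             contig = as.character(GenomicRanges::seqnames(spans))[i],
             strand = as.character(GenomicRanges::strand(spans))[i],
             spanStart = GenomicRanges::start(spans)[i],
             spanEnd = GenomicRanges::end(spans)[i],
             starts = GenomicRanges::start(ci),
             ends = GenomicRanges::end(ci))
    })
}

.classifyOne <- function(contig, pos, ref, alt, gene, genomeChar) {
    seqc <- genomeChar[[gene$contig]]
    cdsPos <- .genomicToCds(gene, pos)
    if (is.na(cdsPos)) {
        return(list(effect = "intronic", codon_ref = NA_character_,
                    codon_alt = NA_character_, aa_change = NA_character_,
                    near_splice = .nearSplice(gene, pos)))
    }
    codonIdx <- (cdsPos - 1L) %/% 3L + 1L
    posInCodon <- (cdsPos - 1L) %% 3L + 1L
    codonCds <- (codonIdx - 1L) * 3L + 1:3
    gpos <- vapply(codonCds, function(cp) .cdsToGenomic(gene, cp), numeric(1))
    bases <- substring(seqc, gpos, gpos)
    if (gene$strand == "-") bases <- .COMPLEMENT[bases]
    refCodon <- paste(bases, collapse = "")
    obsRef <- if (gene$strand == "+") ref else .COMPLEMENT[[ref]]
    if (bases[posInCodon] != obsRef)
        stop("reference allele mismatch at ", contig, ":", pos)
    altBase <- if (gene$strand == "+") alt else .COMPLEMENT[[alt]]
    altBases <- bases
    altBases[posInCodon] <- altBase
    altCodon <- paste(altBases, collapse = "")
    gc <- Biostrings::GENETIC_CODE
    refAA <- unname(gc[refCodon])
    altAA <- unname(gc[altCodon])
    effect <-
        if (refAA == altAA) "synonymous"
        else if (altAA == "*") "nonsense"
        else if (refAA == "*") "stop_loss"
        else if (codonIdx == 1L && refCodon == "ATG") "start_loss"
        else "missense"
    list(effect = effect, codon_ref = refCodon, codon_alt = altCodon,
         aa_change = paste0(refAA, codonIdx, altAA),
         near_splice = .nearSplice(gene, pos))
}

## TRUE when pos lies within 2 bp of an internal exon/intron junction.
## Splice-site effects are not modelled; this flags candidates for manual
## review instead.
.nearSplice <- function(gene, pos) {
    n <- length(gene$starts)
    if (n < 2L) return(FALSE)
    junctions <- c(gene$ends[-n], gene$starts[-1L])
    any(abs(pos - junctions) <= 2L)
}

#' Classify the coding effect of each variant in a strain
#'
#' For every SNV, finds the gene span(s) containing it and assigns an
#' effect: `intergenic` (in no gene span), `intronic` (in a span but not
#' in CDS), or — for CDS positions — the codon-level consequence obtained
#' by substituting the base into the variant's codon and translating under
#' the standard nuclear code (minus-strand genes are handled in transcript
#' orientation): `synonymous`, `missense`, `nonsense` (alt codon is a
#' stop), `stop_loss` (reference stop destroyed), or `start_loss` (the
#' initial ATG destroyed without creating a stop). A variant inside
#' overlapping gene spans yields one row per gene, so incidence counting
#' never silently drops a candidate. A reference-allele mismatch with the
#' genome is a hard error: it indicates a coordinate-convention or
#' assembly-version problem that must not be papered over.
#'
#' @param x A [StrainVariantSet].
#' @param models A [GeneModelSet].
#' @param genome A named [Biostrings::DNAStringSet] covering all variant
#'   contigs.
#' @return A data.frame with one row per (variant, overlapping gene) pair —
#'   or a single row with `gene_id = NA` for intergenic variants — and
#'   columns `strain`, `contig`, `pos`, `ref`, `alt`, `gene_id`, `effect`,
#'   `codon_ref`, `codon_alt`, `aa_change`, `near_splice` (TRUE within 2 bp
#'   of an internal CDS junction).
#' @export
annotateVariants <- function(x, models, genome) {
    stopifnot(methods::is(x, "StrainVariantSet"),
              methods::is(models, "GeneModelSet"))
    df <- variantFrame(x)
    genomeChar <- .genomeAsChar(genome)
    bad <- !df$contig %in% names(genomeChar)
    if (any(bad))
        stop("variant contig(s) absent from genome: ",
             paste(unique(df$contig[bad]), collapse = ", "))
    genes <- .modelList(models)
    rows <- vector("list", nrow(df))
    for (v in seq_len(nrow(df))) {
        contig <- df$contig[v]; pos <- df$pos[v]
        ref <- df$ref[v]; alt <- df$alt[v]
        seqc <- genomeChar[[contig]]
        if (pos > nchar(seqc))
            stop("position ", pos, " beyond end of contig ", contig)
        if (substring(seqc, pos, pos) != ref)
            stop("reference allele mismatch at ", contig, ":", pos,
                 " (genome has ", substring(seqc, pos, pos),
                 ", VCF says ", ref, ")")
        inSpan <- which(vapply(genes, function(g)
            g$contig == contig && pos >= g$spanStart && pos <= g$spanEnd,
            logical(1)))
        if (!length(inSpan)) {
            rows[[v]] <- data.frame(
                strain = strainId(x), contig = contig, pos = pos,
                ref = ref, alt = alt, gene_id = NA_character_,
                effect = "intergenic", codon_ref = NA_character_,
                codon_alt = NA_character_, aa_change = NA_character_,
                near_splice = FALSE, stringsAsFactors = FALSE)
        } else {
            rows[[v]] <- do.call(rbind, lapply(inSpan, function(gi) {
                cl <- .classifyOne(contig, pos, ref, alt, genes[[gi]],
                                   genomeChar)
                data.frame(strain = strainId(x), contig = contig, pos = pos,
                           ref = ref, alt = alt,
                           gene_id = genes[[gi]]$gene_id,
                           effect = cl$effect, codon_ref = cl$codon_ref,
                           codon_alt = cl$codon_alt,
                           aa_change = cl$aa_change,
                           near_splice = cl$near_splice,
                           stringsAsFactors = FALSE)
            }))
        }
    }
    out <- if (nrow(df)) do.call(rbind, rows) else
        data.frame(strain = character(0), contig = character(0),
                   pos = integer(0), ref = character(0), alt = character(0),
                   gene_id = character(0), effect = character(0),
                   codon_ref = character(0), codon_alt = character(0),
                   aa_change = character(0), near_splice = logical(0),
                   stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' @rdname annotateVariants
#' @param contig,pos,ref,alt A single variant, given directly.
#' @export
classifyVariant <- function(contig, pos, ref, alt, models, genome) {
    annotateVariants(StrainVariantSet("query", contig, pos, ref, alt),
                     models, genome)
}

.genomeAsChar <- function(genome) {
    if (is.character(genome)) {
        stopifnot(!is.null(names(genome)))
        return(toupper(genome))
    }
    stopifnot(methods::is(genome, "DNAStringSet"))
    stats::setNames(as.character(genome), names(genome))
}

#' Assemble the gene-by-strain hit incidence matrix
#'
#' Marks `hits[g, s]` TRUE when strain s carries at least one annotated
#' variant in gene g whose effect is in the qualifying set. Multiple
#' qualifying variants in the same gene of one strain count once:
#' recurrence is measured in strains, not alleles. Synonymous and intronic
#' changes are excluded by default because candidate modifier alleles are
#' protein-altering; pass a different `qualifying` subset to widen the net.
#'
#' @param annotated A list of annotation data.frames (one per strain, as
#'   returned by [annotateVariants()]); strain ids are taken from the
#'   `strain` column and must be unique across list elements.
#' @param qualifying Character vector of effects to count.
#' @return A [GeneHitMatrix] over every gene with at least one qualifying
#'   hit and every input strain.
#' @export
buildHitMatrix <- function(annotated, qualifying = qualifyingEffectsDefault()) {
    stopifnot(is.list(annotated), length(annotated) > 0L,
              all(qualifying %in% codingEffects()))
    strains <- vapply(annotated, function(a) {
        s <- unique(a$strain)
        if (length(s) > 1L) stop("mixed strain ids within one annotation table")
        if (length(s) == 0L) NA_character_ else s
    }, character(1))
    if (!is.null(names(annotated)))
        strains[is.na(strains)] <- names(annotated)[is.na(strains)]
    if (any(is.na(strains)))
        stop("cannot determine strain id for empty, unnamed annotation table")
    if (anyDuplicated(strains))
        stop("strain ids must be unique")
    qual <- lapply(annotated, function(a)
        unique(a$gene_id[!is.na(a$gene_id) & a$effect %in% qualifying]))
    genes <- sort(unique(unlist(qual)))
    m <- matrix(FALSE, nrow = length(genes), ncol = length(strains),
                dimnames = list(genes, strains))
    for (s in seq_along(strains))
        m[qual[[s]], s] <- TRUE
    GeneHitMatrix(m, qualifying = qualifying)
}
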