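## File-format ingestion and emission: VCF, GFF3, FASTA, TSV tables.
## Coordinates are 1-based throughout; GFF3 intervals are closed.

#' Read one strain's SNV calls from a VCF file
#'
#' Parses a VCF 4.x file and keeps single-nucleotide substitution records
#' only. Multi-allelic records are split into one call per alt allele;
#' indels, MNVs and symbolic alleles are skipped with a message reporting
#' the skipped count. Genotype fields are ignored: calls are modelled as
#' homozygous, as appropriate for strains propagated several generations
#' after mutagenesis.
#'
#' @param path Path to a VCF file.
#' @param strainId Identifier to attach to the returned set.
#' @return A [StrainVariantSet], sorted and deduplicated.
#' @examples
#' svs <- StrainVariantSet("s1", "chrI", 100L, "G", "A")
#' f <- tempfile(fileext = ".vcf")
#' writeStrainVcf(svs, f)
#' readStrainVcf(f, "s1")
#' @export
readStrainVcf <- function(path, strainId) {
    if (!file.exists(path))
        stop("VCF file not found: ", path)
    vcf <- VariantAnnotation::readVcf(path)
    vcf <- VariantAnnotation::expand(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- as.character(VariantAnnotation::alt(vcf))
    snv <- nchar(ref) == 1L & nchar(alt) == 1L &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    nSkipped <- sum(!snv)
    if (nSkipped > 0L)
        message("readStrainVcf: skipped ", nSkipped,
                " non-SNV record(s) in ", basename(path))
    StrainVariantSet(strainId,
                     contig = as.character(GenomicRanges::seqnames(rr))[snv],
                     pos = GenomicRanges::start(rr)[snv],
                     ref = ref[snv], alt = alt[snv])
}

#' Write a StrainVariantSet as a minimal VCF 4.2 file
#'
#' Emits CHROM, POS, ID ".", REF, ALT, QUAL ".", FILTER "PASS", INFO "."
#' in coordinate order. Round-trips exactly through [readStrainVcf()].
#'
#' @param x A [StrainVariantSet].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeStrainVcf <- function(x, path) {
    stopifnot(methods::is(x, "StrainVariantSet"))
    df <- variantFrame(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 paste0("##source=modscreen strain=", strainId(x)),
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (nrow(df))
        writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                           df$contig, df$pos, df$ref, df$alt), con)
    invisible(path)
}

#' Read protein-coding gene models from a GFF3 file
#'
#' Expects `gene` features and `CDS` features parented (directly, or via an
#' `mRNA` feature) to a gene. One CDS chain is kept per gene; overlapping
#' CDS intervals within one gene are an error, as is a CDS with no
#' resolvable gene parent. Coordinates are kept 1-based closed, exactly as
#' in the file.
#'
#' @param path Path to a GFF3 file.
#' @return A [GeneModelSet].
#' @export
readGeneModels <- function(path) {
    if (!file.exists(path))
        stop("GFF3 file not found: ", path)
    gff <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gff$type)
    genes <- gff[type == "gene"]
    if (!length(genes))
        stop("no 'gene' features in ", path)
    gid <- as.character(genes$ID)
    if (any(is.na(gid)) || anyDuplicated(gid))
        stop("gene features must carry unique ID attributes")
    names(genes) <- gid
    ## map mRNA ID -> gene ID so CDS can be parented either way
    rna <- gff[type == "mRNA"]
    rnaParent <- vapply(rna$Parent, function(p)
        if (length(p)) p[[1L]] else NA_character_, character(1))
    rnaMap <- stats::setNames(rnaParent, as.character(rna$ID))
    cds <- gff[type == "CDS"]
    if (!length(cds))
        stop("no 'CDS' features in ", path)
    parent <- vapply(cds$Parent, function(p)
        if (length(p)) p[[1L]] else NA_character_, character(1))
    if (any(is.na(parent)))
        stop("CDS feature without a Parent attribute in ", path)
    viaRna <- parent %in% names(rnaMap)
    parent[viaRna] <- rnaMap[parent[viaRna]]
    if (!all(parent %in% gid))
        stop("CDS parent not resolvable to a gene: ",
             paste(unique(parent[!parent %in% gid]), collapse = ", "))
    S4Vectors::mcols(cds) <- NULL
    cdsList <- S4Vectors::split(cds, factor(parent, levels = gid))
    cdsList <- methods::as(lapply(cdsList, function(g)
        BiocGenerics::sort(g, ignore.strand = TRUE)), "GRangesList")
    S4Vectors::mcols(genes) <- NULL
    GeneModelSet(genes = genes, cds = cdsList)
}

#' Write a GeneModelSet as GFF3
#'
#' @param x A [GeneModelSet].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeGeneModels <- function(x, path) {
    stopifnot(methods::is(x, "GeneModelSet"))
    g <- geneSpans(x)
    g$type <- "gene"
    g$ID <- names(g)
    cds <- unlist(cdsRanges(x), use.names = TRUE)
    parent <- names(cds)
    names(cds) <- NULL
    cds$type <- "CDS"
    cds$ID <- NA_character_
    GenomicRanges::strand(cds) <- rep(as.character(GenomicRanges::strand(g)),
                                      lengths(cdsRanges(x)))
    cds$Parent <- parent
    ## GFF3 phase: bases to skip in this CDS piece to reach a codon start,
    ## accumulated in transcript order (reversed intervals on minus strand)
    cds$phase <- unlist(lapply(seq_along(g), function(i) {
        w <- GenomicRanges::width(cdsRanges(x)[[i]])
        minus <- as.character(GenomicRanges::strand(g))[i] == "-"
        wt <- if (minus) rev(w) else w
        ph <- (3L - cumsum(c(0L, utils::head(wt, -1L))) %% 3L) %% 3L
        if (minus) rev(ph) else ph
    }), use.names = FALSE)
    g$Parent <- NA_character_
    out <- c(g, cds)
    out$source <- "modscreen"
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}

#' Read a genome (or proteome) FASTA
#'
#' Thin validated wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::readAAStringSet()]. Sequence names are truncated at the
#' first whitespace, matching common contig-naming practice.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] (genome) or
#'   [Biostrings::AAStringSet] (proteome), named.
#' @export
readGenomeFasta <- function(path) {
    g <- Biostrings::readDNAStringSet(path)
    if (!length(g)) stop("empty FASTA: ", path)
    names(g) <- sub("\\s.*$", "", names(g))
    if (anyDuplicated(names(g))) stop("duplicate contig names in ", path)
    g
}

#' @rdname readGenomeFasta
#' @export
readProteomeFasta <- function(path) {
    p <- Biostrings::readAAStringSet(path)
    if (!length(p)) stop("empty FASTA: ", path)
    names(p) <- sub("\\s.*$", "", names(p))
    p
}

#' Read a gene-mutability panel table
#'
#' Reads a TSV with a header naming at least a gene-id column and a count
#' column (the per-gene number of panel strains with a coding hit), and
#' couples it with the panel size N. Counts above N or below zero are
#' rejected.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param panelSize Number of strains in the mutagenized panel (default
#'   2007, the Million Mutation Project strain count).
#' @param geneCol,countCol Column names holding gene ids and counts.
#' @return A [MutabilityTable].
#' @export
readMutabilityTable <- function(path, panelSize = 2007L,
                                geneCol = "gene_id", countCol = "count") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c(geneCol, countCol) %in% colnames(df)))
        stop("mutability table must have columns '", geneCol, "' and '",
             countCol, "'")
    cnt <- as.integer(df[[countCol]])
    if (any(is.na(cnt)))
        stop("non-integer panel counts in ", path)
    MutabilityTable(stats::setNames(cnt, df[[geneCol]]),
                    panelSize = panelSize)
}

#' @rdname readMutabilityTable
#' @param x A [MutabilityTable] to write.
#' @export
writeMutabilityTable <- function(x, path) {
    stopifnot(methods::is(x, "MutabilityTable"))
    utils::write.table(
        data.frame(gene_id = names(panelCounts(x)),
                   count = unname(panelCounts(x))),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
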