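test_that("parental subtraction removes shared triples and is idempotent", {
    s <- StrainVariantSet("s", rep("chrI", 3), c(10L, 20L, 30L),
                          c("G", "C", "A"), c("A", "T", "G"))
    p <- StrainVariantSet("p", "chrI", 20L, "C", "T")
    out <- subtractParental(s, p)
    expect_equal(variantFrame(out)$pos, c(10L, 30L))
    expect_identical(variantFrame(subtractParental(out, p)),
                     variantFrame(out))
    ## self-subtraction is empty, empty parental is identity
    expect_equal(length(subtractParental(s, s)), 0L)
    empty <- StrainVariantSet("p0")
    expect_identical(variantFrame(subtractParental(s, empty)),
                     variantFrame(s))
})

test_that("parental subtraction equals brute-force set difference", {
    set.seed(11)
    for (i in 1:10) {
        a <- randomVariantSet("a", sample(5:60, 1), len = 500L)
        b <- randomVariantSet("b", sample(5:60, 1), len = 500L)
        got <- variantFrame(subtractParental(a, b))
        adf <- variantFrame(a); bdf <- variantFrame(b)
        keep <- !(paste(adf$contig, adf$pos, adf$alt) %in%
                  paste(bdf$contig, bdf$pos, bdf$alt))
        expect_identical(got, {
            x <- adf[keep, , drop = FALSE]; rownames(x) <- NULL; x })
    }
})

test_that("a variant matching the parental position but not allele is kept", {
    s <- StrainVariantSet("s", "chrI", 10L, "G", "A")
    p <- StrainVariantSet("p", "chrI", 10L, "G", "T")
    expect_equal(length(subtractParental(s, p)), 1L)
})

## toy single-exon plus-strand gene: CDS ATG CAA GGA TAA at 11..22
.toyModels <- function(strand = "+") {
    gr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(11, 22),
                                 strand = strand)
    names(gr) <- "gT"
    GeneModelSet(gr, GenomicRanges::GRangesList(
        gT = GenomicRanges::GRanges("chrT", IRanges::IRanges(11, 22))))
}

test_that("coding effects are classified correctly on a toy gene", {
    genome <- c(chrT = paste0("AAAAAAAAAA", "ATGCAAGGATAA", "AAAAAAAAAA"))
    m <- .toyModels()
    ## C->T at CDS base 4: codon CAA -> TAA, a stop
    r <- classifyVariant("chrT", 14L, "C", "T", m, genome)
    expect_equal(r$effect, "nonsense")
    expect_equal(r$aa_change, "Q2*")
    ## A->G at CDS base 6: CAA -> CAG, still Gln
    r <- classifyVariant("chrT", 16L, "A", "G", m, genome)
    expect_equal(r$effect, "synonymous")
    ## G->A at CDS base 7: GGA -> AGA, Gly -> Arg
    r <- classifyVariant("chrT", 17L, "G", "A", m, genome)
    expect_equal(r$effect, "missense")
    expect_equal(r$codon_ref, "GGA")
    expect_equal(r$codon_alt, "AGA")
    ## T->C at CDS base 10: TAA -> CAA, stop lost
    r <- classifyVariant("chrT", 20L, "T", "C", m, genome)
    expect_equal(r$effect, "stop_loss")
    ## G->A at CDS base 3: ATG -> ATA, start destroyed
    r <- classifyVariant("chrT", 13L, "G", "A", m, genome)
    expect_equal(r$effect, "start_loss")
    ## outside every gene span
    r <- classifyVariant("chrT", 2L, "A", "G", m, genome)
    expect_equal(r$effect, "intergenic")
    expect_true(is.na(r$gene_id))
})

test_that("reference-allele mismatch is a hard error naming the position", {
    genome <- c(chrT = paste0("AAAAAAAAAA", "ATGCAAGGATAA", "AAAAAAAAAA"))
    expect_error(classifyVariant("chrT", 14L, "G", "T", .toyModels(), genome),
                 "mismatch at chrT:14")
})

test_that("classification agrees with the translate-and-diff oracle", {
    ## randomized multi-exon genes on both strands, every CDS position x
    ## every alt, including intron positions
    cfg <- screenSimConfig(seed = 303, nContigs = 1L, contigLength = 20000L,
                           nGenes = 5L)
    gm <- simulateGenome(cfg)
    genomeChar <- stats::setNames(as.character(gm$genome), names(gm$genome))
    strands <- as.character(GenomicRanges::strand(geneSpans(gm$models)))
    expect_setequal(unique(strands), c("+", "-"))
    nChecked <- 0L
    for (gid in geneIds(gm$models)) {
        cds <- cdsRanges(gm$models)[[gid]]
        contig <- as.character(GenomicRanges::seqnames(
            geneSpans(gm$models)[gid]))
        positions <- unlist(lapply(seq_along(cds), function(i)
            seq(GenomicRanges::start(cds)[i], GenomicRanges::end(cds)[i])))
        positions <- sample(positions, min(length(positions), 240L))
        vdf <- do.call(rbind, lapply(positions, function(pos) {
            ref <- substring(genomeChar[[contig]], pos, pos)
            data.frame(pos = pos, ref = ref,
                       alt = setdiff(c("A", "C", "G", "T"), ref))
        }))
        svs <- StrainVariantSet("q", rep(contig, nrow(vdf)), vdf$pos,
                                vdf$ref, vdf$alt)
        ann <- annotateVariants(svs, gm$models, gm$genome)
        ann <- ann[ann$gene_id == gid & !is.na(ann$gene_id), ]
        expect_equal(nrow(ann), nrow(vdf))
        want <- mapply(function(pos, alt)
            oracleEffect(gm$models, genomeChar, gid, contig, pos, alt),
            ann$pos, ann$alt)
        expect_identical(ann$effect, unname(want))
        nChecked <- nChecked + nrow(ann)
    }
    expect_gte(nChecked, 2000L)
})

test_that("intronic positions and near-splice flags are annotated", {
    cfg <- screenSimConfig(seed = 17, nContigs = 1L, contigLength = 20000L,
                           nGenes = 5L)
    gm <- simulateGenome(cfg)
    genomeChar <- stats::setNames(as.character(gm$genome), names(gm$genome))
    multi <- geneIds(gm$models)[lengths(cdsRanges(gm$models)) > 1L]
    skip_if(length(multi) == 0L, "no multi-exon gene drawn")
    gid <- multi[1L]
    cds <- cdsRanges(gm$models)[[gid]]
    contig <- as.character(GenomicRanges::seqnames(geneSpans(gm$models)[gid]))
    intronPos <- GenomicRanges::end(cds)[1L] + 1L
    ref <- substring(genomeChar[[contig]], intronPos, intronPos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
    r <- classifyVariant(contig, intronPos, ref, alt, gm$models, gm$genome)
    r <- r[r$gene_id == gid, ]
    expect_equal(r$effect, "intronic")
    expect_true(r$near_splice)  # 1 bp into the intron
    ## a CDS base 2 bp inside the junction is flagged too
    edgePos <- GenomicRanges::end(cds)[1L] - 1L
    ref <- substring(genomeChar[[contig]], edgePos, edgePos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
    r <- classifyVariant(contig, edgePos, ref, alt, gm$models, gm$genome)
    expect_true(r$near_splice[r$gene_id == gid])
})

test_that("hit matrix counts strain incidence, not allele multiplicity", {
    ann1 <- data.frame(strain = "s1", contig = "c", pos = c(1L, 2L),
                       ref = "G", alt = "A", gene_id = "gA",
                       effect = c("missense", "nonsense"),
                       stringsAsFactors = FALSE)
    ann2 <- data.frame(strain = "s2", contig = "c", pos = 3L, ref = "G",
                       alt = "A", gene_id = "gA", effect = "synonymous",
                       stringsAsFactors = FALSE)
    hm <- buildHitMatrix(list(ann1, ann2))
    expect_equal(unname(hitCounts(hm)[["gA"]]), 1L)  # two alleles, one strain
    expect_equal(dim(hm), c(1L, 2L))
    ## synonymous qualifies only when asked
    hm2 <- buildHitMatrix(list(ann1, ann2),
                          qualifying = c("missense", "nonsense",
                                         "synonymous"))
    expect_equal(unname(hitCounts(hm2)[["gA"]]), 2L)
    ## column sums never exceed the strain's count of qualifying genes
    expect_true(all(colSums(hits(hm)) <= c(1L, 1L)))
})

test_that("strain ids must be unique across annotation tables", {
    ann <- data.frame(strain = "s1", contig = "c", pos = 1L, ref = "G",
                      alt = "A", gene_id = "gA", effect = "missense",
                      stringsAsFactors = FALSE)
    expect_error(buildHitMatrix(list(ann, ann)), "unique")
})
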