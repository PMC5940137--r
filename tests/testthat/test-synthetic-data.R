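test_that("simulated genes are well-formed coding sequences", {
    cfg <- screenSimConfig(seed = 101, nGenes = 12L)
    gm <- simulateGenome(cfg)
    genomeChar <- stats::setNames(as.character(gm$genome), names(gm$genome))
    lens <- cdsLengths(gm$models)
    expect_true(all(lens %% 3L == 0L))
    for (gid in geneIds(gm$models)) {
        cds <- cdsRanges(gm$models)[[gid]]
        span <- geneSpans(gm$models)[gid]
        contig <- as.character(GenomicRanges::seqnames(span))
        s <- paste(substring(genomeChar[[contig]],
                             GenomicRanges::start(cds),
                             GenomicRanges::end(cds)), collapse = "")
        if (as.character(GenomicRanges::strand(span)) == "-")
            s <- chartr("ACGT", "TGCA",
                        paste(rev(strsplit(s, "")[[1]]), collapse = ""))
        aa <- .oracleTranslate(s)
        expect_equal(aa[1], "M")
        expect_equal(aa[length(aa)], "*")
        expect_false("*" %in% aa[-length(aa)])  # no internal stop
    }
    ## gene spans do not overlap
    ov <- GenomicRanges::findOverlaps(geneSpans(gm$models),
                                      drop.self = TRUE)
    expect_equal(length(ov), 0L)
})

test_that("a genome with no genes is allowed", {
    gm <- simulateGenome(screenSimConfig(seed = 1, nGenes = 0L))
    expect_equal(length(gm$models), 0L)
    expect_equal(length(gm$genome), 2L)
})

test_that("too-dense gene placement is an error", {
    expect_error(simulateGenome(screenSimConfig(seed = 1, nGenes = 400L,
                                                contigLength = 10000L)),
                 "cannot place")
})

test_that("the simulator is byte-reproducible for a fixed seed", {
    cfg <- screenSimConfig(seed = 77, nGenes = 10L,
                           injectedModifiers = c(gene003 = 3L))
    d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
    simulateScreen(cfg, dir = d1)
    simulateScreen(cfg, dir = d2)
    for (f in list.files(d1)) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), label = f)
    }
    ## a different seed gives a different variant landscape
    d3 <- file.path(tempdir(), "simC")
    simulateScreen(screenSimConfig(seed = 78, nGenes = 10L,
                                   injectedModifiers = c(gene003 = 3L)),
                   dir = d3)
    expect_false(identical(readLines(file.path(d1, "parental.vcf")),
                           readLines(file.path(d3, "parental.vcf"))))
})

test_that("emitted files re-parse into the in-memory truth objects", {
    cfg <- screenSimConfig(seed = 55, nGenes = 8L,
                           injectedModifiers = c(gene002 = 2L))
    d <- file.path(tempdir(), "simRT")
    sim <- simulateScreen(cfg, dir = d)
    g2 <- readGenomeFasta(sim$files$genome)
    expect_identical(as.character(g2), stats::setNames(
        as.character(sim$genome), names(sim$genome)))
    m2 <- readGeneModels(sim$files$gff)
    expect_identical(geneIds(m2), geneIds(sim$models))
    expect_equal(unname(cdsLengths(m2)), unname(cdsLengths(sim$models)))
    for (i in seq_along(sim$strains)) {
        back <- readStrainVcf(sim$files$strains[i],
                              strainId(sim$strains[[i]]))
        expect_identical(variantFrame(back), variantFrame(sim$strains[[i]]))
    }
    mt <- readMutabilityTable(sim$files$mutability, cfg$panelSize)
    expect_identical(panelCounts(mt), panelCounts(sim$mutability))
})

test_that("parental variants are present in every strain", {
    sim <- simulateScreen(screenSimConfig(seed = 12, nGenes = 6L))
    pdf <- variantFrame(sim$parental)
    pkey <- paste(pdf$contig, pdf$pos, pdf$alt)
    for (s in sim$strains) {
        sdf <- variantFrame(s)
        expect_true(all(pkey %in% paste(sdf$contig, sdf$pos, sdf$alt)))
    }
})

test_that("a pure-transition spectrum yields only G>A and C>T background", {
    sim <- simulateScreen(screenSimConfig(seed = 4, nGenes = 4L,
                                          emsTransitionFraction = 1))
    for (s in sim$strains) {
        df <- variantFrame(s)
        expect_true(all(paste(df$ref, df$alt) %in% c("G A", "C T")))
    }
})

test_that("zero mutations and no injections leave nothing after subtraction", {
    sim <- simulateScreen(screenSimConfig(seed = 6, nGenes = 4L,
                                          mutationsPerStrain = 0))
    for (s in sim$strains)
        expect_equal(length(subtractParental(s, sim$parental)), 0L)
})

test_that("injected modifiers produce the intended per-gene strain counts", {
    cfg <- screenSimConfig(seed = 91, injectedModifiers = c(gene005 = 4L,
                                                            gene010 = 2L))
    sim <- simulateScreen(cfg)
    ann <- lapply(sim$strains, function(s)
        annotateVariants(subtractParental(s, sim$parental), sim$models,
                         sim$genome))
    hm <- buildHitMatrix(ann)
    k <- hitCounts(hm)
    expect_gte(k[["gene005"]], 4L)  # background can only add strains
    expect_gte(k[["gene010"]], 2L)
    ## the injected variants themselves carry their promised effects
    tr <- sim$truth$injectedVariants
    expect_equal(nrow(tr), 6L)
    expect_setequal(unique(tr$effect), c("nonsense", "missense"))
    for (i in seq_len(nrow(tr))) {
        cl <- classifyVariant(tr$contig[i], tr$pos[i], tr$ref[i], tr$alt[i],
                              sim$models, sim$genome)
        expect_equal(cl$effect[cl$gene_id == tr$gene_id[i]], tr$effect[i])
    }
    ## exactly k distinct strains received an injection per gene
    expect_equal(as.integer(table(tr$gene_id)[c("gene005", "gene010")]),
                 c(4L, 2L))
    expect_false(anyDuplicated(paste(tr$gene_id, tr$strain)) > 0)
})

test_that("smFISH simulation honors its stage and control means", {
    em <- simulateSmfish(nPerGroup = 500L, seed = 33)
    m <- mean(em$set3_count)
    se <- stats::sd(em$set3_count) / sqrt(length(em$set3_count))
    expect_lt(abs(m - 444), 3 * se)
    means8 <- mean(em$end1_count[em$stage == "8-cell"])
    means32 <- mean(em$end1_count[em$stage == "32-cell"])
    expect_lt(abs(means8 - 47), 5)
    expect_lt(abs(means32 - 214), 10)
    em0 <- simulateSmfish(stageMeans = c("8-cell" = 0), set3Mean = 0,
                          nPerGroup = 10L, seed = 1)
    expect_true(all(em0$end1_count == 0) && all(em0$set3_count == 0))
})
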