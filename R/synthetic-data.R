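## Synthetic screen simulator: toy genomes and gene models, EMS-spectrum
## mutagenized strain variant sets with injected recurrent modifier hits,
## mutability panels, intensity tables and smFISH counts — all with
## recorded ground truth, so every pipeline stage can be validated
## end-to-end without real sequencing data.
##
## One random-number stream per run: simulateScreen() seeds once from the
## config and draws, in order, genome bases, gene structures, parental
## variants, per-strain background variants (strain by strain), injected
## modifier variants (gene by gene), then panel counts. Identical configs
## therefore give byte-identical output files.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

#' Configuration for the synthetic screen simulator
#'
#' Defaults emulate the published screen's downstream product at toy
#' scale: 17 mutagenized strains sharing a parental background, with a
#' handful of genes independently hit 2-4 times. The EMS substitution
#' spectrum defaults to 87% G:C -> A:T transitions, the standard EMS
#' signature. Per-strain background mutation counts are a toy-scale
#' placeholder (the screen's true per-strain SNV counts are not public);
#' they are scaled to the toy genome so that background multi-hit genes
#' stay rare but possible.
#'
#' @param seed Integer seed for the run's single RNG stream.
#' @param nContigs,contigLength Genome shape.
#' @param nGenes Number of protein-coding genes to place.
#' @param nStrains Number of mutagenized candidate strains S.
#' @param parentalVariantCount Background variants shared by all strains.
#' @param mutationsPerStrain Poisson mean of per-strain induced mutations.
#' @param emsTransitionFraction Probability an induced mutation is a
#'   G:C -> A:T transition.
#' @param injectedModifiers Named integer vector, gene id -> number of
#'   strains k in which to inject one qualifying coding variant.
#' @param injectedPanelCount Panel hit count assigned to injected genes in
#'   the synthetic mutability table (6 by default: injected modifiers are
#'   low-mutability genes, as the validated candidates were).
#' @param panelSize Size of the synthetic mutability panel.
#' @param panelHitsPerKb Expected panel hits per kb of CDS. Panel counts
#'   are drawn per gene as Binomial(panelSize, q) with q proportional to
#'   CDS length, so the same intrinsic mutability that drives background
#'   hits in the screen also drives the panel — the property the
#'   calibration relies on.
#' @return A validated list of class `ScreenSimConfig`.
#' @export
screenSimConfig <- function(seed = 1L, nContigs = 2L, contigLength = 100000L,
                            nGenes = 40L, nStrains = 17L,
                            parentalVariantCount = 50L,
                            mutationsPerStrain = 25,
                            emsTransitionFraction = 0.87,
                            injectedModifiers = integer(0),
                            injectedPanelCount = 6L,
                            panelSize = 2007L, panelHitsPerKb = 60) {
    stopifnot(emsTransitionFraction >= 0, emsTransitionFraction <= 1,
              nStrains >= 1L, nGenes >= 0L, nContigs >= 1L,
              contigLength >= 1000L, mutationsPerStrain >= 0,
              parentalVariantCount >= 0L, panelSize >= 1L)
    if (length(injectedModifiers)) {
        stopifnot(!is.null(names(injectedModifiers)),
                  all(injectedModifiers >= 1L))
        if (any(injectedModifiers > nStrains))
            stop("injected k cannot exceed the number of strains")
    }
    structure(list(seed = as.integer(seed), nContigs = as.integer(nContigs),
                   contigLength = as.integer(contigLength),
                   nGenes = as.integer(nGenes),
                   nStrains = as.integer(nStrains),
                   parentalVariantCount = as.integer(parentalVariantCount),
                   mutationsPerStrain = mutationsPerStrain,
                   emsTransitionFraction = emsTransitionFraction,
                   injectedModifiers = injectedModifiers,
                   injectedPanelCount = as.integer(injectedPanelCount),
                   panelSize = as.integer(panelSize),
                   panelHitsPerKb = panelHitsPerKb),
              class = "ScreenSimConfig")
}

.randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                              collapse = "")

## Gene structure in transcript orientation: ATG + non-stop codons + stop.
.randCds <- function(nCodons) {
    all3 <- apply(expand.grid(.BASES, .BASES, .BASES), 1L, paste,
                  collapse = "")
    sense <- setdiff(all3, .STOPS)
    paste0("ATG",
           paste(sample(sense, nCodons - 2L, replace = TRUE), collapse = ""),
           sample(.STOPS, 1L))
}

.revComp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

.simGenome <- function(config) {
    contigs <- stats::setNames(
        vapply(seq_len(config$nContigs), function(i)
            .randSeq(config$contigLength), character(1)),
        sprintf("chr%02d", seq_len(config$nContigs)))
    geneIds <- sprintf("gene%03d", seq_len(config$nGenes))
    cursor <- stats::setNames(rep(1L, config$nContigs), names(contigs))
    spans <- list(); cdsL <- list()
    for (gi in seq_len(config$nGenes)) {
        nCodons <- sample(60:160, 1L)
        nExons <- sample(1:3, 1L)
        cds <- .randCds(nCodons)
        L <- nchar(cds)
        ## split the CDS into exon pieces of >= 20 nt, cuts not
        ## codon-aligned so frame bookkeeping is exercised
        if (nExons > 1L) {
            repeat {
                cuts <- sort(sample(seq(2L, L - 1L), nExons - 1L))
                lens <- diff(c(0L, cuts, L))
                if (all(lens >= 20L)) break
            }
        } else lens <- L
        intr <- if (nExons > 1L) sample(40:80, nExons - 1L, replace = TRUE)
                else integer(0)
        strand <- sample(c("+", "-"), 1L)
        ## transcript-order exon offsets within the plus-layout region
        starts <- cumsum(c(1L, utils::head(lens, -1L) + intr))
        ends <- starts + lens - 1L
        regionLen <- sum(lens) + sum(intr)
        exonSeq <- substring(cds, cumsum(c(1L, utils::head(lens, -1L))),
                             cumsum(lens))
        pieces <- character(2L * nExons - 1L)
        pieces[seq(1L, by = 2L, length.out = nExons)] <- exonSeq
        if (nExons > 1L)
            pieces[seq(2L, by = 2L, length.out = nExons - 1L)] <-
                vapply(intr, .randSeq, character(1))
        region <- paste(pieces, collapse = "")
        if (strand == "-") {
            region <- .revComp(region)
            newStarts <- regionLen - ends + 1L
            newEnds <- regionLen - starts + 1L
            o <- order(newStarts)
            starts <- newStarts[o]; ends <- newEnds[o]
        }
        ## place on the contig with the most room left
        room <- nchar(contigs) - cursor - regionLen - 100L
        ct <- names(contigs)[which.max(room)]
        if (max(room) <= 0L)
            stop("cannot place ", config$nGenes,
                 " genes: genome too dense, increase contigLength")
        offset <- cursor[ct] + sample(100:400, 1L)
        if (offset + regionLen - 1L > nchar(contigs[ct]))
            stop("cannot place gene ", geneIds[gi], ": contig exhausted")
        substr(contigs[ct], offset, offset + regionLen - 1L) <- region
        cursor[ct] <- offset + regionLen
        ctf <- factor(ct, levels = names(contigs))
        spans[[gi]] <- GenomicRanges::GRanges(
            ctf, IRanges::IRanges(offset, offset + regionLen - 1L),
            strand = strand)
        cdsL[[gi]] <- GenomicRanges::GRanges(
            rep(ctf, length(starts)),
            IRanges::IRanges(offset + starts - 1L, offset + ends - 1L))
    }
    if (config$nGenes > 0L) {
        genes <- do.call(c, spans)
        names(genes) <- geneIds
        cds <- methods::as(stats::setNames(cdsL, geneIds), "GRangesList")
    } else {
        genes <- GenomicRanges::GRanges()
        cds <- methods::as(list(), "GRangesList")
    }
    list(genome = Biostrings::DNAStringSet(contigs),
         models = GeneModelSet(genes, cds))
}

#' Simulate a toy genome with annotated protein-coding genes
#'
#' Generates random contigs carrying non-overlapping, possibly multi-exon
#' genes on both strands. Every CDS starts with ATG, ends with a stop
#' codon, has length divisible by 3 and no internal stop; exon boundaries
#' deliberately fall off codon boundaries so annotation code must track
#' reading frame across introns.
#'
#' @param config A [screenSimConfig()].
#' @return A list with `genome` (named [Biostrings::DNAStringSet]) and
#'   `models` (a [GeneModelSet]).
#' @export
simulateGenome <- function(config = screenSimConfig()) {
    stopifnot(inherits(config, "ScreenSimConfig"))
    set.seed(config$seed)
    .simGenome(config)
}

## Sample one SNV uniformly on the genome; EMS-biased with prob emsFrac.
.sampleSnv <- function(genomeChar, emsFrac) {
    lens <- nchar(genomeChar)
    repeat {
        ct <- sample(names(genomeChar), 1L, prob = lens)
        pos <- sample.int(lens[[ct]], 1L)
        ref <- substring(genomeChar[[ct]], pos, pos)
        if (stats::runif(1) < emsFrac) {
            if (ref == "G") return(list(contig = ct, pos = pos, ref = "G",
                                        alt = "A"))
            if (ref == "C") return(list(contig = ct, pos = pos, ref = "C",
                                        alt = "T"))
            ## not a G/C site: resample
        } else {
            alt <- sample(setdiff(.BASES, ref), 1L)
            return(list(contig = ct, pos = pos, ref = ref, alt = alt))
        }
    }
}

## Find a substitution in `gene` (a .modelList element) with the desired
## coding effect; returns list(contig, pos, ref, alt) or errors.
.injectVariant <- function(gene, genomeChar, effect,
                           maxTries = 2000L) {
    cdsLen <- sum(gene$ends - gene$starts + 1L)
    for (try in seq_len(maxTries)) {
        ## skip the start codon and the stop codon
        cdsPos <- sample(seq(4L, cdsLen - 3L), 1L)
        gpos <- .cdsToGenomic(gene, cdsPos)
        ref <- substring(genomeChar[[gene$contig]], gpos, gpos)
        for (alt in sample(setdiff(.BASES, ref))) {
            cl <- .classifyOne(gene$contig, gpos, ref, alt, gene,
                               genomeChar)
            if (cl$effect == effect)
                return(list(contig = gene$contig, pos = gpos, ref = ref,
                            alt = alt, effect = effect,
                            aa_change = cl$aa_change))
        }
    }
    stop("could not construct a ", effect, " variant in gene ",
         gene$gene_id, " (gene too short?)")
}

#' Simulate a whole modifier screen with recorded ground truth
#'
#' Builds a toy genome and gene models, a parental background variant set
#' shared by all strains, per-strain EMS-spectrum background mutations,
#' and — for each entry of `injectedModifiers` — one qualifying coding
#' variant in exactly k distinct strains (nonsense in half of the injected
#' strains, missense in the rest, mirroring the published candidate
#' alleles). A synthetic mutability panel is drawn from a skewed
#' negative-binomial count model, with injected genes assigned
#' `injectedPanelCount`. When `dir` is given, all inputs the pipeline
#' needs are written there as FASTA / GFF3 / VCF / TSV plus a
#' `truth.json`.
#'
#' @param config A [screenSimConfig()].
#' @param dir Optional output directory for the emitted files.
#' @return Invisibly, a list with `genome`, `models`, `parental`
#'   ([StrainVariantSet]), `strains` (named list of [StrainVariantSet]),
#'   `mutability` ([MutabilityTable]), `truth` (injection and variant
#'   origin records) and, when `dir` was given, `files`.
#' @export
simulateScreen <- function(config = screenSimConfig(), dir = NULL) {
    stopifnot(inherits(config, "ScreenSimConfig"))
    set.seed(config$seed)
    gm <- .simGenome(config)
    genomeChar <- .genomeAsChar(gm$genome)
    modelL <- .modelList(gm$models)
    names(modelL) <- vapply(modelL, `[[`, character(1), "gene_id")
    if (length(config$injectedModifiers) &&
        !all(names(config$injectedModifiers) %in% names(modelL)))
        stop("injectedModifiers name genes absent from the simulated genome")

    newVariantFrame <- function(lst)
        do.call(rbind, lapply(lst, function(v)
            data.frame(contig = v$contig, pos = v$pos, ref = v$ref,
                       alt = v$alt, stringsAsFactors = FALSE)))

    ## parental background shared by every strain
    parentalL <- list(); seen <- character(0)
    while (length(parentalL) < config$parentalVariantCount) {
        v <- .sampleSnv(genomeChar, config$emsTransitionFraction)
        key <- paste(v$contig, v$pos)
        if (key %in% seen) next
        seen <- c(seen, key)
        parentalL[[length(parentalL) + 1L]] <- v
    }
    parentalDf <- if (length(parentalL)) newVariantFrame(parentalL) else
        data.frame(contig = character(0), pos = integer(0),
                   ref = character(0), alt = character(0))
    parental <- StrainVariantSet("parental", parentalDf$contig,
                                 parentalDf$pos, parentalDf$ref,
                                 parentalDf$alt)

    strainIds <- sprintf("strain_%02d", seq_len(config$nStrains))
    strainDfs <- stats::setNames(vector("list", config$nStrains), strainIds)
    for (s in seq_len(config$nStrains)) {
        nBg <- stats::rpois(1L, config$mutationsPerStrain)
        bg <- list(); seenS <- seen
        while (length(bg) < nBg) {
            v <- .sampleSnv(genomeChar, config$emsTransitionFraction)
            key <- paste(v$contig, v$pos)
            if (key %in% seenS) next
            seenS <- c(seenS, key)
            bg[[length(bg) + 1L]] <- v
        }
        df <- rbind(
            cbind(parentalDf,
                  origin = rep("parental", nrow(parentalDf))),
            if (length(bg)) cbind(newVariantFrame(bg),
                                  origin = rep("background", length(bg))))
        strainDfs[[s]] <- df
    }

    ## injected recurrent modifiers: one qualifying variant per chosen
    ## strain; nonsense in the first half of the injected strains
    injectedTruth <- list()
    for (g in names(config$injectedModifiers)) {
        k <- config$injectedModifiers[[g]]
        chosen <- sample(strainIds, k)
        effects <- rep(c("nonsense", "missense"), length.out = k)
        for (j in seq_len(k)) {
            v <- .injectVariant(modelL[[g]], genomeChar, effects[j])
            sdf <- strainDfs[[chosen[j]]]
            clash <- sdf$contig == v$contig & sdf$pos == v$pos
            if (any(clash)) sdf <- sdf[!clash, , drop = FALSE]
            sdf <- rbind(sdf, data.frame(contig = v$contig, pos = v$pos,
                                         ref = v$ref, alt = v$alt,
                                         origin = paste0("injected:", g),
                                         stringsAsFactors = FALSE))
            strainDfs[[chosen[j]]] <- sdf
            injectedTruth[[length(injectedTruth) + 1L]] <-
                data.frame(gene_id = g, strain = chosen[j],
                           contig = v$contig, pos = v$pos, ref = v$ref,
                           alt = v$alt, effect = v$effect,
                           aa_change = v$aa_change,
                           stringsAsFactors = FALSE)
        }
    }
    injectedDf <- if (length(injectedTruth)) do.call(rbind, injectedTruth)
        else data.frame(gene_id = character(0), strain = character(0),
                        contig = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        effect = character(0), aa_change = character(0),
                        stringsAsFactors = FALSE)

    strains <- lapply(strainIds, function(s) {
        df <- strainDfs[[s]]
        StrainVariantSet(s, df$contig, df$pos, df$ref, df$alt)
    })
    names(strains) <- strainIds

    ## synthetic mutability panel: per-gene hit probability proportional
    ## to CDS length, so panel counts reflect the same mutability that
    ## generates background hits
    gids <- geneIds(gm$models)
    q <- pmin(1, cdsLengths(gm$models) / 1000 * config$panelHitsPerKb /
                  config$panelSize)
    counts <- stats::rbinom(length(gids), size = config$panelSize,
                            prob = unname(q))
    names(counts) <- gids
    counts[names(config$injectedModifiers)] <- config$injectedPanelCount
    mutability <- MutabilityTable(counts, panelSize = config$panelSize)

    truth <- list(
        injected = stats::setNames(as.integer(config$injectedModifiers),
                                   names(config$injectedModifiers)),
        injectedVariants = injectedDf,
        parental = parentalDf,
        strainVariants = strainDfs)

    out <- list(genome = gm$genome, models = gm$models, parental = parental,
                strains = strains, mutability = mutability, truth = truth,
                config = config)

    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        files <- list(
            genome = file.path(dir, "genome.fa"),
            gff = file.path(dir, "models.gff3"),
            parental = file.path(dir, "parental.vcf"),
            mutability = file.path(dir, "mutability.tsv"),
            truth = file.path(dir, "truth.json"),
            strains = file.path(dir, paste0(strainIds, ".vcf")))
        Biostrings::writeXStringSet(gm$genome, files$genome)
        writeGeneModels(gm$models, files$gff)
        writeStrainVcf(parental, files$parental)
        for (s in seq_along(strains))
            writeStrainVcf(strains[[s]], files$strains[s])
        writeMutabilityTable(mutability, files$mutability)
        jsonlite::write_json(
            list(injected = as.list(truth$injected),
                 injectedVariants = truth$injectedVariants,
                 parental = truth$parental),
            files$truth, auto_unbox = TRUE, digits = NA)
        out$files <- files
    }
    invisible(out)
}

#' Simulate a reference-normalized intensity experiment
#'
#' Draws per-embryo fluorescence intensities with lognormal noise around
#' strain-specific fold changes, in batches with arbitrary batch scales
#' (which [normalizeIntensities()] must remove). The reference strain sits
#' at fold 1. The lognormal is mean-parameterized: the expected raw
#' intensity of a strain is batchScale x fold.
#'
#' @param folds Named numeric vector of true fold changes per test strain.
#' @param referenceStrain Name for the fold-1 reference strain.
#' @param nPerStrain Embryos per strain per batch.
#' @param sdlog Lognormal noise on the log scale (0.6 by default, matching
#'   the large embryo-to-embryo spread typical of immunostaining).
#' @param nBatches Number of experiment batches.
#' @param seed RNG seed.
#' @return A data.frame with columns `strain`, `experiment`, `embryo`,
#'   `intensity`, plus a `true_fold` attribute.
#' @export
simulateIntensityData <- function(folds = c(multicopy = 5.5),
                                  referenceStrain = "reference",
                                  nPerStrain = 30L, sdlog = 0.6,
                                  nBatches = 2L, seed = 1L) {
    stopifnot(all(folds > 0), nPerStrain >= 1L, sdlog >= 0)
    set.seed(seed)
    allFolds <- c(stats::setNames(1, referenceStrain), folds)
    rows <- list()
    for (b in seq_len(nBatches)) {
        batchScale <- stats::runif(1, 100, 300)
        for (s in names(allFolds)) {
            val <- batchScale * allFolds[[s]] *
                stats::rlnorm(nPerStrain, meanlog = -sdlog^2 / 2,
                              sdlog = sdlog)
            rows[[length(rows) + 1L]] <- data.frame(
                strain = s, experiment = sprintf("exp%02d", b),
                embryo = seq_len(nPerStrain), intensity = val,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "true_fold") <- allFolds
    out
}

#' Simulate smFISH transcript counts per embryo
#'
#' Draws negative-binomial molecule counts around stage-specific end-1
#' means and a stage-constant set-3 control mean. A multiplicative
#' `effect` on the end-1 mean distinguishes the second genotype; with
#' `effect = 1` the two genotypes are exchangeable (the null).
#'
#' @param stageMeans Named numeric vector of end-1 means per stage.
#' @param set3Mean Mean set-3 molecules per embryo at every stage.
#' @param nPerGroup Embryos per genotype per stage.
#' @param effect Multiplier on the end-1 mean for `genotypes[2]`.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson); 20 by default, a moderate extra-Poisson embryo-to-embryo
#'   variability.
#' @param genotypes Two genotype labels.
#' @param seed RNG seed.
#' @return A data.frame with columns `genotype`, `stage`, `end1_count`,
#'   `set3_count`.
#' @export
simulateSmfish <- function(stageMeans = c("8-cell" = 47, "16-cell" = 109,
                                          "32-cell" = 214),
                           set3Mean = 444, nPerGroup = 20L, effect = 1,
                           dispersion = 20, genotypes = c("N2", "mutant"),
                           seed = 1L) {
    stopifnot(all(stageMeans >= 0), set3Mean >= 0, effect >= 0,
              nPerGroup >= 1L, length(genotypes) == 2L)
    set.seed(seed)
    rows <- list()
    for (st in names(stageMeans)) {
        for (g in genotypes) {
            mu1 <- stageMeans[[st]] * if (g == genotypes[2L]) effect else 1
            end1 <- if (mu1 == 0) rep(0L, nPerGroup) else
                stats::rnbinom(nPerGroup, size = dispersion, mu = mu1)
            set3 <- if (set3Mean == 0) rep(0L, nPerGroup) else
                stats::rnbinom(nPerGroup, size = dispersion, mu = set3Mean)
            rows[[length(rows) + 1L]] <- data.frame(
                genotype = g, stage = st, end1_count = end1,
                set3_count = set3, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
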