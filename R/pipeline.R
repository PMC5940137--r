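## End-to-end orchestration: subtract -> annotate -> hit matrix -> rank,
## from files on disk to a candidate table plus a machine-readable run
## report. This is the programmatic entry point that ties the modules
## together; each stage failure is re-raised with the stage name.

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "': ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full modifier-screen analysis pipeline
#'
#' Reads the parental and per-strain VCFs, the gene models, the reference
#' genome and the mutability panel; subtracts the parental background
#' from every strain; annotates the remaining SNVs for coding effect;
#' assembles the gene-by-strain hit matrix; and ranks multiply-hit genes
#' by their mutability-calibrated recurrence probability. The run report
#' logs the variant counts at each stage per strain.
#'
#' @param parentalVcf Path to the parental (un-mutagenized) strain's VCF.
#' @param strainVcfs Named character vector of per-strain VCF paths;
#'   names are the strain ids.
#' @param gffPath Path to the GFF3 gene models.
#' @param genomePath Path to the reference genome FASTA.
#' @param mutabilityPath Path to the mutability panel TSV.
#' @param panelSize Mutability panel size (default 2007).
#' @param minK Minimum hit-strain count for a candidate (default 2).
#' @param qualifying Coding effects that count as hits.
#' @param mode,scale Passed to [recurrenceProbability()].
#' @param outDir Optional directory; when given, `candidates.tsv` and
#'   `report.json` are written there.
#' @return A list with `candidates` (the ranked data.frame from
#'   [rankCandidates()]), `hitMatrix` (the [GeneHitMatrix]), `annotated`
#'   (per-strain annotation tables) and `report` (per-stage counts).
#' @export
runPipeline <- function(parentalVcf, strainVcfs, gffPath, genomePath,
                        mutabilityPath, panelSize = 2007L, minK = 2L,
                        qualifying = qualifyingEffectsDefault(),
                        mode = c("point", "tail"), scale = 1,
                        outDir = NULL) {
    mode <- match.arg(mode)
    if (!length(strainVcfs))
        stop("no strain VCFs given")
    if (is.null(names(strainVcfs)) || any(!nzchar(names(strainVcfs))))
        stop("strainVcfs must be a named vector (names = strain ids)")

    parental <- .stage("read", readStrainVcf(parentalVcf, "parental"))
    strains <- .stage("read", lapply(names(strainVcfs), function(s)
        readStrainVcf(strainVcfs[[s]], s)))
    names(strains) <- names(strainVcfs)
    models <- .stage("read", readGeneModels(gffPath))
    genome <- .stage("read", readGenomeFasta(genomePath))
    mutability <- .stage("read",
                         readMutabilityTable(mutabilityPath,
                                             panelSize = panelSize))

    cleaned <- .stage("subtract", lapply(strains, subtractParental,
                                         parental = parental))
    annotated <- .stage("annotate", lapply(cleaned, annotateVariants,
                                           models = models,
                                           genome = genome))
    matrix <- .stage("hit-matrix", buildHitMatrix(annotated,
                                                  qualifying = qualifying))
    candidates <- .stage("rank", rankCandidates(matrix, mutability,
                                                minK = minK, mode = mode,
                                                scale = scale))

    report <- list(
        strains = length(strains),
        panel_size = panelSize,
        qualifying_effects = qualifying,
        variants_read = vapply(strains, length, integer(1)),
        after_subtraction = vapply(cleaned, length, integer(1)),
        coding_qualifying = vapply(annotated, function(a)
            sum(a$effect %in% qualifying), integer(1)),
        genes_multihit = sum(hitCounts(matrix) >= minK))

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(candidates, file.path(outDir, "candidates.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(report, file.path(outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    list(candidates = candidates, hitMatrix = matrix,
         annotated = annotated, report = report)
}
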