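## Screen-sizing arithmetic: genomes screened, expected detections,
## detection probabilities under a Poisson model.

#' Haploid genomes screened in an F1 mutagenesis screen
#'
#' Each surviving fertile F1 carries two independently mutagenized haploid
#' genomes (one per parental gamete), so G = n_P0 x fertile-per-P0 x 2.
#'
#' @param nP0 Number of mutagenized P0 animals.
#' @param fertilePerP0 Surviving fertile F1 produced per P0 (may be a
#'   vector, e.g. a low/high range).
#' @param genomesPerF1 Mutagenized haploid genomes per F1 (default 2).
#' @return Haploid genome count(s).
#' @examples
#' haploidGenomes(400, 17.5)        # ~14,000
#' haploidGenomes(400, c(15, 20))   # 12,000 - 16,000
#' @export
haploidGenomes <- function(nP0, fertilePerP0, genomesPerF1 = 2) {
    stopifnot(is.numeric(nP0), is.numeric(fertilePerP0),
              is.numeric(genomesPerF1))
    if (any(nP0 < 0) || any(fertilePerP0 < 0) || any(genomesPerF1 < 0))
        stop("screen-design inputs must be non-negative")
    nP0 * fertilePerP0 * genomesPerF1
}

#' Expected detections of a mutable gene across a screen
#'
#' With G haploid genomes screened and a per-gene loss-of-function rate r
#' (mutations per gene per gamete), a gene whose knockout scores in the
#' screen is expected to be recovered G x r times. The classical EMS
#' benchmark is a forward rate of 5e-4 per gene at 50 mM; half of that,
#' 2.5e-4, is the default for a 25 mM regime.
#'
#' @param genomes Haploid genomes screened.
#' @param ratePerGene Loss-of-function rate per gene per haploid genome.
#' @return Expected number of independent detections.
#' @examples
#' expectedDetections(14000)  # 3.5
#' @export
expectedDetections <- function(genomes, ratePerGene = 2.5e-4) {
    stopifnot(is.numeric(genomes), is.numeric(ratePerGene))
    if (any(genomes < 0) || any(ratePerGene < 0))
        stop("screen-design inputs must be non-negative")
    genomes * ratePerGene
}

#' Probability of detecting a gene at least k times
#'
#' Poisson companion to [expectedDetections()]: detections across G
#' independent genomes at rate r are modelled as X ~ Poisson(G r), and
#' the function returns P(X >= k).
#'
#' @inheritParams expectedDetections
#' @param k Minimum number of detections.
#' @return P(X >= k); vectorized over `k`.
#' @examples
#' detectionProbability(14000, k = 1)  # 1 - exp(-3.5)
#' @export
detectionProbability <- function(genomes, ratePerGene = 2.5e-4, k = 1L) {
    stopifnot(is.numeric(k), all(k >= 0))
    lambda <- expectedDetections(genomes, ratePerGene)
    stats::ppois(k - 1, lambda, lower.tail = FALSE)
}
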