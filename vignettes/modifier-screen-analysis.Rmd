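---
title: "Recurrence analysis of sequenced modifier screens"
author: "modscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence analysis of sequenced modifier screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modscreen)
```

## The problem

In a *C. elegans* modifier screen, a strain carrying a lethal genotype is
kept alive by a rescuing transgene, mutagenized with EMS, and propagated
until modifier mutations homozygose and the rescuing array is lost;
counterselection then leaves only strains whose survival no longer
depends on the array. Whole-genome sequencing of the surviving strains,
without outcrossing or mapping, identifies candidate modifier genes as
the genes mutated independently in more than one strain.

The statistical difficulty is that genes differ enormously in how easily
they collect mutations (length, base composition, EMS target density).
Two hits in a gigantic, mutation-prone gene mean little; two hits in a
small, rarely hit gene are striking. This package calibrates recurrence
against a mutagenized reference panel and implements the supporting
pipeline and quantitation statistics.

## The model

Let N be the panel size (2007 for the Million Mutation Project), m_g the
number of panel strains with a coding hit in gene g, S the number of
screened candidate strains, and k_g the number of those carrying a
qualifying coding variant in g. The per-genome hit probability is
estimated as p_g = m_g/N, and hits across the S independent strains are
Bernoulli, so

$$P(k_g;\,S, p_g) \;=\; \binom{S}{k_g}\, p_g^{k_g} (1-p_g)^{S-k_g}.$$

Two formulations are offered:

* **point** (default): the probability of *exactly* k hit strains. This
  is the form that reproduces the published candidate table at its
  printed one-significant-digit precision on every row, including the two
  diagnostic rows (m = 12 prints `4.E-03`, where the upper tail rounds to
  `5.E-03`; m = 250 prints `3.E-01`, where the tail is ≈ 0.64).
* **tail**: P(at least k hit strains), the conventional enrichment
  formulation, monotone in m and preferable for scoring new screens
  because it does not reward extra hits with a *smaller* point mass.

The inference that the published table used the point mass follows from
reproducing all 19 rows; it is recorded here as this package's
reconstruction, not as a claim about the original authors' code.

Supporting choices:

* `scale` multiplies p_g (default 1) to deflate panel-derived
  probabilities when the screen's mutagenesis is weaker than the panel's;
  at the default the probabilities are conservative over-estimates in
  that situation.
* N is a required, overridable parameter (`panelSize = 2007` by default),
  since a published table typically prints m but not N.
* Genes hit in the screen but absent from the panel table get the panel's
  median count as fallback and an `mmp_missing` flag — candidates are
  never silently dropped.
* No multiple-testing correction is applied: per-gene probabilities are
  reported raw, as screens report them, and `expectedMultihitGenes()`
  (the sum of per-gene tail probabilities) gives the genome-wide expected
  number of chance multi-hit genes as context.

Probabilities are formatted with one significant digit, half-up, with
carry into the exponent (0.095 → `1.E-01`), matching candidate-table
style; `parseProbability()` inverts the format.

## Variant triage

`subtractParental()` removes every call whose (contig, position, alt)
triple occurs in the un-mutagenized parental strain — shared calls are
pre-existing background. The operation is an exact set difference,
idempotent, and order-preserving.

`annotateVariants()` classifies each SNV by rebuilding its codon from the
gene's CDS chain: intergenic (outside all gene spans), intronic (inside a
span, outside CDS), or a codon-level effect — synonymous, missense,
nonsense (alt codon is a stop), stop-loss, start-loss (initial ATG
destroyed without creating a stop). Minus-strand genes are handled in
transcript orientation with reading frame tracked across introns, which
the simulator deliberately exercises by cutting exons off codon
boundaries. Degenerate rules worth stating: a stop codon mutated to a
different stop codon leaves the protein unchanged and is synonymous; an
ATG start mutated *to* a stop is nonsense (the stop rule wins). These
match a whole-protein translate-and-diff oracle, which the test suite
enforces over every CDS position × every alternate base of randomized
multi-exon genes on both strands (≥ 10⁴ cases).

Three data-integrity stances: a reference-allele mismatch with the genome
is a hard error (it flags coordinate or assembly-version bugs that must
not be papered over); a variant inside overlapping gene spans is assigned
to *every* overlapping gene; positions within 2 bp of an internal
exon/intron junction carry a `near_splice` flag because splice-site
effects are not modelled in this version.

`buildHitMatrix()` counts strain incidence, not allele multiplicity; the
default qualifying set {missense, nonsense, stop_loss, start_loss}
excludes synonymous and intronic changes, since candidate modifier
alleles are protein-altering. Whether the original screen's coding-variant
tables included synonymous changes is not stated anywhere we know of, so
the set is a parameter rather than a guess.

## Screen-sizing arithmetic

Each fertile F1 surviving mutagenesis carries two independently
mutagenized haploid genomes, so G = nP0 × fertileF1PerP0 × 2; with 400 P0
and 15–20 fertile F1 each, G is 12,000–16,000 (14,000 at the 17.5
midpoint). At the classical EMS benchmark — a forward loss-of-function
rate of 5 × 10⁻⁴ per gene at 50 mM, halved to 2.5 × 10⁻⁴ for a 25 mM
regime — a scorable gene is expected G × r ≈ 3.5 times, and
`detectionProbability()` gives the Poisson tail P(X ≥ k) for X ~
Poisson(G r).

## Motif scanning

`findCleavageSites()` reports all starts of the taspase cleavage tetrad
Q\[F/I/L/M\]D↓G (cleavage between D and G); the position-2 alphabet is
configurable because human Taspase1 additionally accepts V. Matching is
case-insensitive and stops at a premature `*`. `motifCensus()` counts
proteins with at least one site (once each). A proteome-release census
(e.g. the 239 WormBase WS250 proteins with a site) depends on the
database release and is deliberately not a validation target; the scanner
is validated against substring enumeration on synthetic proteomes.

## Embryo quantitation statistics

* `normalizeIntensities()` divides each embryo's background-corrected
  fluorescence by the mean of the reference strain *in the same
  experiment batch*; the reference mean is exactly 1 per batch, and
  normalization is invariant to rescaling a batch. Batch-wise (not
  pooled) normalization absorbs staining/imaging drift between sessions.
* `foldChangeSummary()` reports mean and sample SD (n − 1).
* `rankSumTest()` is the two-sided Wilcoxon–Mann–Whitney test: exact
  enumeration when combined n ≤ 20 without ties, otherwise the normal
  approximation with tie and continuity corrections.
* `notchHalfwidth()` is 1.6 · IQR/√n with type-7 (linear interpolation)
  quantiles; the 1.6 constant is the conventional approximation for
  non-overlap of median notches, so the quantile rule is documented
  rather than agonized over.
* `proportionTable()` rounds percent-positive half-up to integers. One
  published gut-granule row prints 63% where its own counts give 62.5% →
  62% under half-up rounding; that cell is excluded from validation.
* `smfishRatioTest()` compares per-embryo end-1/set-3 molecule ratios
  between genotypes with a two-sided t test, pooled-variance by default
  (the test the screen's smFISH analysis names), Welch by flag. Embryos
  with zero control counts have no defined ratio and are dropped with a
  message.

Brood-size/survival summary tables are not given a dedicated operation:
whether published per-strain percentages average per-brood percentages or
pool counts is ambiguous, so survival-style data are covered only by the
generic summaries and the simulators.

## What the simulator emulates — and what it does not

`simulateScreen()` generates the downstream product of such a screen at
toy scale: a 2 × 100 kb genome with 40 non-overlapping multi-exon genes
(CDS starts ATG, ends with a stop, no internal stops, exon cuts off codon
boundaries), a parental background of 50 shared SNVs, Poisson(25)
induced mutations per strain with an 87% G:C→A:T EMS spectrum, optional
injected modifiers (one qualifying variant in exactly k distinct strains;
nonsense in half of them, missense in the rest, mirroring validated
candidate alleles), and a mutability panel drawn as
Binomial(N, q_g) with q_g proportional to CDS length
(`panelHitsPerKb = 60`), so the panel reflects the same intrinsic
mutability that drives background hits — the property the calibration
relies on. Injected genes get a fixed low panel count (6) like the
screen's strongest real candidate. One RNG stream per run, seeded from
the config, makes outputs byte-reproducible.

Deliberate departures from real data: the genome is ~500× smaller than
*C. elegans*' with ~500× fewer genes, so per-gene background hit rates
are far higher than real ones (a realistic trickle of chance double-hits
at toy scale); per-strain mutation counts are a placeholder, since the
screen's true per-strain SNV counts are not public; there is no
sequencing error, coverage variation, heterozygosity or isoform
structure. Passing tests therefore demonstrate correctness of the
*computation* on screen-shaped data, not calling performance on real
sequencing output.

`simulateIntensityData()` draws mean-parameterized lognormal intensities
(default sdlog 0.6, matching the large embryo-to-embryo spread of
immunostaining) around per-strain fold changes with arbitrary batch
scales; `simulateSmfish()` draws negative-binomial molecule counts
(size 20, moderate extra-Poisson variability) around the published stage
means (end-1: 47/109/214 at 8/16/32-cell; set-3: 444).

## Numerical and testing choices

Coordinates are 1-based closed everywhere (VCF and GFF3 native),
converted only when slicing sequence. Half-up rounding uses
floor(x + 0.5). Candidate ranking sorts ascending probability, ties by
descending k then gene id. The test suite sizes its simulations to run in
minutes on one core: ~1.2 × 10⁴ oracle classification cases, 10⁶
Monte Carlo screens for the binomial check (3 SE agreement), 10³
replicates for the smFISH type-I calibration (rejection rate within
[3%, 7%] at α = 0.05), and n = 200 embryos for 20%-accurate fold
recovery.

## Known limitations

Single-nucleotide substitutions only (no indels/MNVs/SVs); one CDS chain
per gene (no isoforms); no splice-site effect model (flag only); genotype
fields ignored (homozygosed strains assumed); generic GFF3 without
WormBase-dialect attributes; mutability calibration inherits whatever
ascertainment biases the reference panel has, and with `scale = 1` the
probabilities are over-estimates when the screen's mutagenesis is weaker
than the panel's.
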