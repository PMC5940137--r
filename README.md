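# modscreen

Analysis of whole-genome-sequenced forward-genetic modifier screens, built
around the *C. elegans* screening strategy in which a lethal mutant is kept
alive by a counterselectable extrachromosomal transgene array, survivors of
mutagenesis are sequenced, and candidate modifier genes are the ones hit
independently in more than one surviving strain.

The package is for geneticists who have per-strain variant calls (VCF),
gene models (GFF3) and a reference genome (FASTA) from such a screen and
want to go from raw calls to a ranked candidate table, plus the companion
calculations such screens use: screen-sizing arithmetic, protease
cleavage-motif censuses, and embryo-quantitation statistics.

## The statistic at the core

A gene g hit in k of S independently mutagenized strains is only
interesting relative to how easily g collects mutations. Its intrinsic
mutability is estimated from a sequenced mutagenized reference panel (the
Million Mutation Project panel of N = 2007 strains): if m_g panel strains
carry a coding hit in g, the per-genome hit probability is

    p_g = m_g / N

and the probability that exactly k of S screened strains carry a hit in g
by chance is the binomial point mass

    P(k; S, p_g) = C(S, k) · p_g^k · (1 − p_g)^(S−k)

reported in one-significant-digit scientific notation (e.g. `2.E-07`).
This point-mass form reproduces the published candidate table row for row;
the conventional upper-tail form P(X ≥ k) is available via
`mode = "tail"` and is the better choice for new screens (see the
vignette). `expectedMultihitGenes()` supplies genome-wide context: the
expected number of genes reaching k hits by mutability alone.

The variant triage upstream mirrors screen practice: calls shared with the
un-mutagenized parental strain are subtracted, the remaining SNVs are
classified by codon substitution (synonymous / missense / nonsense /
stop-loss / start-loss, with minus-strand genes handled in transcript
orientation), and a gene × strain incidence matrix is assembled counting
strains, not alleles.

## Worked example

A fully synthetic screen with a known answer — a modifier gene injected
into 4 of 17 strains — analysed end to end:

```r
library(modscreen)

cfg <- screenSimConfig(seed = 42,
                       injectedModifiers = c(gene005 = 4L, gene010 = 2L))
sim <- simulateScreen(cfg, dir = "sim")   # writes FASTA/GFF3/VCF/TSV + truth

res <- runPipeline(
    parentalVcf    = sim$files$parental,
    strainVcfs     = setNames(sim$files$strains, names(sim$strains)),
    gffPath        = sim$files$gff,
    genomePath     = sim$files$genome,
    mutabilityPath = sim$files$mutability,
    panelSize      = 2007L)

head(res$candidates, 3)
```

```
  gene_id k  S  m           p         prob prob_text rank mmp_missing
1 gene005 4 17  6 0.002989537 1.828474e-07    2.E-07    1       FALSE
2 gene010 2 17  6 0.002989537 1.162097e-03    1.E-03    2       FALSE
3 gene016 2 17 10 0.004982561 3.132597e-03    3.E-03    3       FALSE
```

The injected 4-hit gene tops the table at `2.E-07` — the same probability
a real screen reports for a gene with panel count 6 hit four times among
17 strains — while chance double-hits in more mutable genes trail with
probabilities of 10⁻³ and above. The screen-design side:

```r
haploidGenomes(400, c(15, 20))        # 12000 16000 haploid genomes
expectedDetections(14000, 2.5e-4)     # 3.5 expected recoveries of a gene
detectionProbability(14000, k = 2)    # 0.864: chance of seeing it twice
findCleavageSites("AAQMDGAA")         # 3: a taspase Q[F/I/L/M]D^G site
```

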