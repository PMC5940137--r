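## Published candidate table of the 17-strain modifier screen: gene,
## mutability-panel hit count m (panel of 2007 strains), number of hit
## strains k, and the printed one-significant-digit recurrence probability.
refCandidateTable <- data.frame(
    gene = c("K01G5.9", "Y18H1A.8", "pqn-82", "wrt-7", "clec-6", "B0462.1",
             "col-180", "ptr-1", "ptr-19", "panl-2", "odr-1", "wnk-1",
             "rrf-3", "pgp-9", "gei-3", "trr-1", "T06D8.1", "let-805",
             "dig-1"),
    m = c(6L, 3L, 4L, 6L, 9L, 12L, 15L, 18L, 30L, 30L, 33L, 35L, 36L,
          38L, 38L, 76L, 82L, 121L, 250L),
    k = c(4L, rep(2L, 18L)),
    printed = c("2.E-07", "3.E-04", "5.E-04", "1.E-03", "3.E-03", "4.E-03",
                "7.E-03", "1.E-02", "2.E-02", "2.E-02", "3.E-02", "3.E-02",
                "3.E-02", "4.E-02", "4.E-02", "1.E-01", "1.E-01", "2.E-01",
                "3.E-01"),
    stringsAsFactors = FALSE)

## Gut-granule scoring counts (strain, granule-positive, granule-negative)
## with the printed percent-positive values used for validation. The
## tasp-1 row prints 63% although its counts give 62.5%; that row is kept
## out of the percent check (see the vignette).
refGranuleTable <- data.frame(
    group = c("N2", "pqn-82(gk3768)"),
    positive = c(181L, 145L),
    negative = c(365L, 325L),
    printedPercent = c(33L, 31L),
    stringsAsFactors = FALSE)
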