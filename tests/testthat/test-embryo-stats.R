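.toyIntensity <- function() {
    data.frame(
        strain = c("ref", "ref", "mut", "ref", "ref", "mut"),
        experiment = c("e1", "e1", "e1", "e2", "e2", "e2"),
        embryo = 1:6,
        intensity = c(150, 250, 500, 80, 120, 400),
        stringsAsFactors = FALSE)
}

test_that("intensities normalize against the per-batch reference mean", {
    norm <- normalizeIntensities(.toyIntensity(), "ref")
    ## batch e1: reference mean 200 -> test value 500 becomes 2.5
    expect_equal(norm$normalized[3], 2.5)
    ## batch e2: reference mean 100 -> 400 becomes 4.0
    expect_equal(norm$normalized[6], 4.0)
    ## reference strain's normalized mean is 1 in every batch
    for (ex in c("e1", "e2"))
        expect_equal(mean(norm$normalized[norm$experiment == ex &
                                          norm$strain == "ref"]), 1)
})

test_that("batch-wise normalization differs from pooled and is scale-invariant", {
    tab <- .toyIntensity()
    norm <- normalizeIntensities(tab, "ref")
    pooledRef <- mean(tab$intensity[tab$strain == "ref"])
    expect_false(isTRUE(all.equal(norm$normalized[6],
                                  tab$intensity[6] / pooledRef)))
    ## multiplying one batch by a constant changes nothing after norm
    tab2 <- tab
    sel <- tab2$experiment == "e2"
    tab2$intensity[sel] <- tab2$intensity[sel] * 37
    norm2 <- normalizeIntensities(tab2, "ref")
    expect_equal(norm2$normalized, norm$normalized)
})

test_that("a batch without the reference strain is an error", {
    tab <- .toyIntensity()
    tab$strain[tab$experiment == "e2" & tab$strain == "ref"] <- "other"
    expect_error(normalizeIntensities(tab, "ref"), "absent from experiment")
})

test_that("fold-change summaries use the sample SD", {
    tab <- data.frame(strain = "m", experiment = "e1", embryo = 1:3,
                      intensity = 1, stringsAsFactors = FALSE)
    tab$normalized <- c(1, 1, 1)
    expect_equal(foldChangeSummary(tab, "m"), c(mean = 1, sd = 0))
    tab2 <- tab[1:2, ]; tab2$normalized <- c(2, 4)
    expect_equal(foldChangeSummary(tab2, "m"), c(mean = 3, sd = sqrt(2)))
    expect_error(foldChangeSummary(tab[1, ], "m"), ">= 2 embryos")
})

test_that("intensity simulation at fold 5.5 is recovered within 20%", {
    tab <- simulateIntensityData(folds = c(multicopy = 5.5),
                                 referenceStrain = "ref",
                                 nPerStrain = 100L, nBatches = 2L,
                                 sdlog = 0.6, seed = 88)
    norm <- normalizeIntensities(tab, "ref")
    fc <- foldChangeSummary(norm, "multicopy")
    expect_lt(abs(fc[["mean"]] - 5.5) / 5.5, 0.2)
    ## noise-free generation returns the fold exactly
    tab0 <- simulateIntensityData(folds = c(m = 3), referenceStrain = "ref",
                                  nPerStrain = 5L, sdlog = 0, seed = 1)
    norm0 <- normalizeIntensities(tab0, "ref")
    expect_equal(unique(norm0$normalized[norm0$strain == "m"]), 3)
})

test_that("rank-sum exact branch equals full enumeration", {
    expect_equal(rankSumTest(c(1, 2, 3), c(4, 5, 6)), 0.1)
    set.seed(9)
    for (i in 1:8) {
        x <- sample(seq(1, 1000), sample(3:6, 1))
        y <- sample(seq(1001, 2000), sample(3:6, 1)) / 1.7
        expect_equal(rankSumTest(x, y), enumRankSumP(x, y),
                     tolerance = 1e-12)
    }
})

test_that("identical samples give p near 1 and the null p-values are uniform", {
    x <- c(1, 2, 3)
    expect_equal(rankSumTest(x, x), 1)
    set.seed(41)
    ps <- replicate(400, rankSumTest(stats::rnorm(50), stats::rnorm(50)))
    ## p-values are mildly discrete, so silence the KS tie warning
    expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("exact and approximate rank-sum branches agree for moderate n", {
    set.seed(13)
    for (i in 1:5) {
        x <- stats::rnorm(10); y <- stats::rnorm(10)
        pExact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
        pApprox <- stats::wilcox.test(x, y, exact = FALSE,
                                      correct = TRUE)$p.value
        expect_lt(abs(pExact - pApprox), 0.02)
    }
})

test_that("notch half-width follows 1.6 IQR / sqrt(n)", {
    v <- rep(c(1, 3), 8)  # IQR 2, n 16
    expect_equal(notchHalfwidth(v), 1.6 * 2 / 4)
    expect_equal(notchHalfwidth(rep(7, 10)), 0)
    set.seed(2)
    x <- stats::rlnorm(37)
    q <- stats::quantile(x, c(0.25, 0.75), type = 7)
    expect_equal(notchHalfwidth(x),
                 1.6 * unname(q[2] - q[1]) / sqrt(37))
})

test_that("proportion tables round percent positive half-up", {
    tab <- data.frame(group = c("N2", "mutA", "mutB"),
                      positive = c(181L, 145L, 0L),
                      negative = c(365L, 325L, 12L),
                      stringsAsFactors = FALSE)
    out <- proportionTable(tab)
    expect_equal(out$n, c(546L, 470L, 12L))
    expect_equal(out$percent_positive, c(33L, 31L, 0L))
    ## half-up at the boundary: 62.5% -> 63%
    out2 <- proportionTable(data.frame(group = "g", positive = 5L,
                                       negative = 3L))
    expect_equal(out2$percent_positive, 63L)
    expect_error(proportionTable(data.frame(group = "g", positive = 0L,
                                            negative = 0L)), "total")
})

test_that("smFISH ratio test compares per-embryo end-1/set-3 ratios", {
    base <- data.frame(
        genotype = rep(c("N2", "mut"), each = 3),
        stage = "8-cell",
        end1_count = c(10, 20, 30, 10, 20, 30),
        set3_count = 10,
        stringsAsFactors = FALSE)
    expect_equal(smfishRatioTest(base, "N2", "mut", "8-cell"), 1)
    shifted <- base
    shifted$end1_count[shifted$genotype == "mut"] <-
        shifted$end1_count[shifted$genotype == "mut"] + 100
    p <- smfishRatioTest(shifted, "N2", "mut", "8-cell")
    tref <- stats::t.test(c(1, 2, 3), c(11, 12, 13),
                          var.equal = TRUE)$p.value
    expect_equal(p, tref)
    expect_lt(p, 1e-3)
    expect_error(smfishRatioTest(base[-1, ], "N2", "mut", "16-cell"),
                 ">= 2 embryos")
})

test_that("smFISH null simulation rejects near the nominal rate", {
    nRep <- 300
    rej <- vapply(seq_len(nRep), function(i) {
        em <- simulateSmfish(nPerGroup = 20L, effect = 1, seed = 5000 + i)
        smfishRatioTest(em, "N2", "mutant", "8-cell") < 0.05
    }, logical(1))
    rate <- mean(rej)
    expect_gte(rate, 0.02)
    expect_lte(rate, 0.08)
})
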