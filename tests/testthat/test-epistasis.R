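test_that("pairwise epistasis is the double-mutant deviation from additivity", {
    expect_equal(pairwiseEpistasis(sliceFromW(0, 0.2, -0.1, 0.1)), 0)
    # resistance mutation masking a deleterious knock-out
    expect_equal(pairwiseEpistasis(sliceFromW(0, 2, -1, 2)), 1)
    set.seed(1)
    for (k in 1:25) {
        w <- rnorm(4)
        c0 <- rnorm(1)
        expect_equal(pairwiseEpistasis(sliceFromW(w[1] + c0, w[2] + c0,
                                                  w[3] + c0, w[4] + c0)),
                     pairwiseEpistasis(sliceFromW(w[1], w[2], w[3], w[4])))
    }
})

test_that("mutation effects enumerate every (mutation, background) pair", {
    fl <- summarizeFitness(additiveGridRecords(nrep = 3L))
    eff <- mutationEffects(fl, antibiotic = 4, temperature = 40)
    expect_equal(nrow(eff), 38L)  # 3 ABR x 6 + 5 KO x 4
    expect_equal(sum(eff$class == "ABR"), 18L)
    expect_false(any(eff$mutation %in% c("WT", "none")))
    effAll <- mutationEffects(fl)
    expect_equal(nrow(effAll), 38L * 12L)
    # minimal 1 ABR x 1 KO grid: 4 effects
    rec <- additiveGridRecords(nrep = 3L)
    tiny <- rec[rec$abr_allele %in% c("WT", "S512F") &
                rec$ko_allele %in% c("none", "marR") &
                rec$antibiotic == 0 & rec$temperature == 37, ]
    expect_equal(nrow(mutationEffects(summarizeFitness(tiny))), 4L)
})

test_that("gamma is 1 on additive landscapes and matches the Pearson oracle", {
    fl <- summarizeFitness(additiveGridRecords(nrep = 3L))
    eff <- mutationEffects(fl, antibiotic = 0, temperature = 37)
    expect_equal(as.numeric(gammaStatistic(eff)), 1)
    # 2-ABR x 1-KO landscape; expected pairs enumerated by hand:
    # A1: (1, 0.5); A2: (2, 2.5); B on WT/A1/A2: (1, 0.5), (1, 1.5)
    df <- data.frame(abr = c("WT", "A1", "A2", "WT", "A1", "A2"),
                     ko = c("none", "none", "none", "B", "B", "B"),
                     antibiotic = 0, temperature = 37, replicate = 1,
                     w = c(0, 1, 2, 1, 1.5, 3.5))
    fl2 <- summarizeFitness(recordsFromW(df))
    g <- gammaStatistic(mutationEffects(fl2))
    oracle <- cor(c(1, 2, 1, 1), c(0.5, 2.5, 0.5, 1.5))
    expect_equal(as.numeric(g), oracle)
    expect_equal(as.numeric(g), 0.870, tolerance = 5e-4)
    # per-class restriction keeps only the focal class's pairs
    gABR <- gammaStatistic(mutationEffects(fl2), "ABR")
    expect_equal(as.numeric(gABR), cor(c(1, 2), c(0.5, 2.5)))
})

test_that("gamma hits -1 when effect ordering reverses across backgrounds", {
    df <- data.frame(abr = c("WT", "A1", "A2", "WT", "A1", "A2"),
                     ko = c("none", "none", "none", "B", "B", "B"),
                     antibiotic = 0, temperature = 37, replicate = 1,
                     # A1 effect 1 -> 2, A2 effect 2 -> 1: ordering reverses
                     w = c(0, 1, 2, 1, 3, 2))
    fl <- summarizeFitness(recordsFromW(df))
    expect_equal(as.numeric(gammaStatistic(mutationEffects(fl), "ABR")), -1)
})

test_that("gamma flags degenerate zero-variance cases", {
    # all mutations have the same effect everywhere: identical vectors -> 1
    df <- expand.grid(abr = c("WT", "A1", "A2"), ko = c("none", "B"),
                      antibiotic = 0, temperature = 37, replicate = 1,
                      stringsAsFactors = FALSE)
    df$w <- 0.5 * (df$abr != "WT") + 0.5 * (df$ko != "none")
    g <- gammaStatistic(mutationEffects(summarizeFitness(recordsFromW(df))),
                        "ABR")
    expect_equal(as.numeric(g), 1)
    expect_true(isTRUE(attr(g, "degenerate")))
})

test_that("sign-epistasis classification follows the effect-sign rules", {
    expect_equal(classifySignEpistasis(sliceFromW(0, 0.5, 0.1, -0.1)),
                 "reciprocal")
    expect_equal(classifySignEpistasis(sliceFromW(0, 0.3, -0.5, -0.9)),
                 "simple")
    expect_equal(classifySignEpistasis(sliceFromW(0, 0.3, 0.5, 0.8)), "none")
    # exact zero effects carry no sign
    expect_equal(classifySignEpistasis(sliceFromW(0, 0, 0.5, 0.5)), "none")
    # tolerance turns small flips into no-calls
    expect_equal(classifySignEpistasis(sliceFromW(0, 0.01, 0.5, 0.4)), "simple")
    expect_equal(classifySignEpistasis(sliceFromW(0, 0.01, 0.5, 0.4),
                                       tol = 0.05), "none")
})

test_that("reciprocal sign epistasis forces non-zero pairwise epistasis", {
    set.seed(3)
    found <- 0L
    for (k in 1:500) {
        w <- rnorm(4, 0, 1)
        s <- sliceFromW(w[1], w[2], w[3], w[4])
        if (classifySignEpistasis(s) == "reciprocal") {
            found <- found + 1L
            expect_true(abs(pairwiseEpistasis(s)) > 0)
        }
    }
    expect_gt(found, 10L)  # the property was actually exercised
})

test_that("roughness-to-slope matches its closed form and edge cases", {
    expect_equal(roughnessToSlope(sliceFromW(0, 0.3, 0.5, 0.8)), 0)
    expect_equal(roughnessToSlope(sliceFromW(0, 1, 1, 1.5)), 1 / 6)
    s <- sliceFromW(0, 1, 1, 1.5)
    expect_equal(roughnessToSlope(sliceFromW(0, 3, 3, 4.5)), 1 / 6) # scaling
    # flat fitted plane with non-zero residuals: infinite ratio
    expect_equal(roughnessToSlope(sliceFromW(1, 0, 0, 1)), Inf)
    # completely flat landscape: defined as 0
    expect_equal(roughnessToSlope(sliceFromW(1, 1, 1, 1)), 0)
})

test_that("zero-SE fractions are deterministic", {
    fl <- summarizeFitness(additiveGridRecords(nrep = 3L))
    # zero SEs, additive point estimates: fractions identically 0
    fr <- signEpistasisFractions(fl, bootParam(50, seed = 1))
    expect_true(all(fr$byEnvironment$frac_simple == 0))
    expect_true(all(fr$byEnvironment$frac_reciprocal == 0))
    expect_true(all(fr$byEnvironment$frac_reciprocal_lo == 0 &
                    fr$byEnvironment$frac_reciprocal_hi == 0))
    # inject one reciprocal slice at one environment: exactly 1/15
    df <- expand.grid(abr = c("WT", "S512F", "H526Y", "I572S"),
                      ko = c("none", "marR", "nuoC", "waaP", "yidK", "ybfG"),
                      antibiotic = 0, temperature = 37, replicate = 1:3,
                      stringsAsFactors = FALSE)
    df$w <- 0.3 * (df$abr == "S512F") + 0.2 * (df$ko == "marR") -
        0.9 * (df$abr == "S512F" & df$ko == "marR")
    fr1 <- signEpistasisFractions(summarizeFitness(recordsFromW(df)),
                                  bootParam(50, seed = 1))
    expect_equal(fr1$byEnvironment$frac_reciprocal, 1 / 15)
    det <- fr1$bySlice
    expect_equal(det$detected_reciprocal,
                 det$abr_allele == "S512F" & det$ko_allele == "marR")
})

test_that("injected reciprocal slices are detected; clean slices rarely are", {
    hits <- 0L; clean <- 0L
    nrep <- 10L
    for (s in seq_len(nrep)) {
        p <- scenario("reciprocal_sign_at_zero_ab", seed = s)
        fl <- summarizeFitness(simulateCompetitions(p)$records)
        det <- signEpistasisFractions(fl, bootParam(500, seed = s))$bySlice
        inj <- det$antibiotic == 0 & det$abr_allele == "I572S" &
            det$ko_allele %in% c("marR", "ybfG")
        if (all(det$detected_reciprocal[inj])) hits <- hits + 1L
        if (mean(det$rate_reciprocal[det$antibiotic > 0]) < 0.05)
            clean <- clean + 1L
    }
    expect_gte(hits, 9L)
    expect_gte(clean, 9L)
})

test_that("diminishing-returns regression recovers exact and null structure", {
    # constant effects (exact dyadic inputs): slope exactly 0, not significant
    df0 <- expand.grid(abr = c("WT", "S512F", "H526Y", "I572S"),
                       ko = c("none", "marR", "nuoC"),
                       antibiotic = c(0, 4), temperature = 37,
                       stringsAsFactors = FALSE)
    aAbr <- c(WT = 0, S512F = 0.25, H526Y = 0.5, I572S = 0.75)
    aKo <- c(none = 0, marR = -0.125, nuoC = -0.375)
    df0$w <- aAbr[df0$abr] + aKo[df0$ko]; df0$se <- 0; df0$n <- 3L
    dr <- diminishingReturns(flFromW(df0), "ABR", bootParam(100, seed = 2))
    expect_equal(dr$slope, c(0, 0))
    expect_false(any(dr$significant))
    # exact line: three backgrounds (0, 0.5, 1.0), effects (0.6, 0.3, 0.0)
    df <- expand.grid(abr = c("WT", "A"), ko = c("none", "k1", "k2"),
                      antibiotic = 0, temperature = 37,
                      stringsAsFactors = FALSE)
    bg <- c(none = 0, k1 = 0.5, k2 = 1.0)
    effect <- c(none = 0.6, k1 = 0.3, k2 = 0.0)
    df$w <- bg[df$ko] + (df$abr == "A") * effect[df$ko]
    df$se <- 0; df$n <- 3L
    fl2 <- flFromW(df)
    dr2 <- diminishingReturns(fl2, "ABR", bootParam(50, seed = 2))
    expect_equal(dr2$slope, -0.6)
    expect_equal(c(dr2$slope_lo, dr2$slope_hi), c(-0.6, -0.6))
    expect_true(dr2$significant)
})

test_that("background exclusion removes the requested points", {
    fl <- summarizeFitness(additiveGridRecords(nrep = 3L))
    dr <- diminishingReturns(fl, "ABR", bootParam(20, seed = 1))
    drEx <- diminishingReturns(fl, "ABR", bootParam(20, seed = 1),
                               excludeBackgrounds = "waaP")
    expect_equal(unique(dr$n_points), 18L)
    expect_equal(unique(drEx$n_points), 15L)
})

test_that("epistasis metrics are invariant under fitness translation and scaling", {
    p <- scenario("paper_like", seed = 5)
    fl <- summarizeFitness(simulateCompetitions(p)$records)
    w <- wMean(fl)
    eff0 <- mutationEffects(fl, 0, 37)
    slices <- allSlices(fl)[1:15]
    flShift <- fl; SummarizedExperiment::assay(flShift, "w_mean") <- w + 1.3
    flScale <- fl; SummarizedExperiment::assay(flScale, "w_mean") <- w * 2.6
    effShift <- mutationEffects(flShift, 0, 37)
    effScale <- mutationEffects(flScale, 0, 37)
    expect_equal(as.numeric(gammaStatistic(effShift)),
                 as.numeric(gammaStatistic(eff0)))
    expect_equal(as.numeric(gammaStatistic(effScale)),
                 as.numeric(gammaStatistic(eff0)))
    for (s in slices[c(1, 7, 13)]) {
        sShift <- landscapeSlice(flShift, s@abrAllele, s@koAllele,
                                 s@antibiotic, s@temperature)
        sScale <- landscapeSlice(flScale, s@abrAllele, s@koAllele,
                                 s@antibiotic, s@temperature)
        expect_equal(pairwiseEpistasis(sShift), pairwiseEpistasis(s))
        expect_equal(pairwiseEpistasis(sScale), 2.6 * pairwiseEpistasis(s))
        expect_equal(roughnessToSlope(sShift), roughnessToSlope(s))
        expect_equal(roughnessToSlope(sScale), roughnessToSlope(s))
        expect_equal(classifySignEpistasis(sShift), classifySignEpistasis(s))
    }
})

test_that("bootstrap fractions respect the simplex constraint in every sample", {
    p <- scenario("paper_like", seed = 8)
    fl <- summarizeFitness(simulateCompetitions(p)$records)
    fr <- signEpistasisFractions(fl, bootParam(200, seed = 8))$byEnvironment
    expect_true(all(fr$frac_simple >= 0 & fr$frac_reciprocal >= 0))
    expect_true(all(fr$frac_simple + fr$frac_reciprocal <= 1))
    expect_true(all(fr$frac_reciprocal_lo <= fr$frac_reciprocal_hi))
    expect_true(all(fr$frac_simple_lo >= 0 & fr$frac_simple_hi <= 1))
})
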