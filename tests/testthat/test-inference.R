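test_that("parametric bootstrap is reproducible and degenerate at zero SE", {
    fl <- summarizeFitness(additiveGridRecords(nrep = 3L))  # zero spread
    pb <- parametricBootstrap(fl, bootParam(5, seed = 1))
    for (b in 1:5) expect_equal(pb$samples[, , b], wMean(fl))
    p <- scenario("paper_like", seed = 2)
    fl2 <- summarizeFitness(simulateCompetitions(p)$records)
    s1 <- parametricBootstrap(fl2, bootParam(20, seed = 9))$samples
    s2 <- parametricBootstrap(fl2, bootParam(20, seed = 9))$samples
    expect_identical(s1, s2)
    s3 <- parametricBootstrap(fl2, bootParam(20, seed = 10))$samples
    expect_false(identical(s1, s3))
})

test_that("bootstrap draws match the cell's normal distribution", {
    df <- expand.grid(abr = c("WT", "A"), ko = c("none", "B"),
                      antibiotic = 0, temperature = 37, replicate = 1:2,
                      stringsAsFactors = FALSE)
    df$w <- 0
    fl <- flFromW(data.frame(abr = df$abr[1:4], ko = df$ko[1:4],
                             antibiotic = 0, temperature = 37,
                             w = 0, se = 1, n = 4L))
    pb <- parametricBootstrap(fl, bootParam(10000, seed = 4))
    draws <- pb$samples[1, 1, ]
    expect_lt(abs(mean(draws)), 0.03)
    expect_gt(sd(draws), 0.97); expect_lt(sd(draws), 1.03)
})

test_that("single-replicate cells borrow the environment's median SE, flagged", {
    df <- expand.grid(abr = c("WT", "A"), ko = c("none", "B"),
                      antibiotic = 0, temperature = 37,
                      stringsAsFactors = FALSE)
    df$w <- c(0, 0.5, -0.2, 0.4)
    df$se <- c(0.1, 0.2, 0.3, NA)
    df$n <- c(3L, 3L, 3L, 1L)
    fl <- flFromW(df)
    pb <- parametricBootstrap(fl, bootParam(2000, seed = 5))
    expect_equal(sum(pb$seImputed), 1L)
    row <- which(pb$seImputed, arr.ind = TRUE)[1, "row"]
    # borrowed SE is the environment's median of (0.1, 0.2, 0.3) = 0.2
    expect_equal(sd(pb$samples[row, 1, ]), 0.2, tolerance = 0.02)
})

test_that("percentile CIs behave like normal-theory intervals for a single cell", {
    df <- data.frame(abr = c("WT", "A"), ko = "none", antibiotic = 0,
                     temperature = 37, w = c(0, 1), se = c(0.2, 0.5), n = 4L)
    fl <- flFromW(df)
    ci <- bootstrapCI(function(z) wMean(z)["A|none", 1], fl,
                      bootParam(4000, seed = 6))
    expect_equal(ci$point, 1)
    expect_equal(ci$lo, 1 - 1.96 * 0.5, tolerance = 0.03)
    expect_equal(ci$hi, 1 + 1.96 * 0.5, tolerance = 0.03)
    # zero-SE metric: degenerate interval at the point
    df$se <- 0
    ci0 <- bootstrapCI(function(z) wMean(z)["A|none", 1], flFromW(df),
                       bootParam(100, seed = 6))
    expect_equal(unname(c(ci0$lo, ci0$point, ci0$hi)), c(1, 1, 1))
})

test_that("percentile CIs are equivariant under monotone transformations", {
    df <- data.frame(abr = c("WT", "A"), ko = "none", antibiotic = 0,
                     temperature = 37, w = c(0, 1), se = 0.3, n = 4L)
    fl <- flFromW(df)
    ci <- bootstrapCI(function(z) wMean(z)["A|none", 1], fl,
                      bootParam(500, seed = 11))
    ciExp <- bootstrapCI(function(z) exp(wMean(z)["A|none", 1]), fl,
                         bootParam(500, seed = 11))
    expect_equal(ciExp$lo, exp(ci$lo))
    expect_equal(ciExp$hi, exp(ci$hi))
})

test_that("trend regression matches the closed-form least-squares oracle", {
    ev <- expand.grid(antibiotic = c(0, 4, 8, 10),
                      temperature = c(37, 40, 42))
    set.seed(12)
    vals <- data.frame(ev, value = 0.5 - 0.03 * ev$antibiotic +
                           rnorm(12, 0, 0.05))
    tf <- trendVsEnvironment(vals, "antibiotic")
    # independent oracle: closed-form simple regression + lm
    x <- ev$antibiotic; y <- vals$value
    slopeOracle <- cov(x, y) / var(x)
    expect_equal(tf$slope, slopeOracle, tolerance = 1e-10)
    m <- summary(lm(y ~ x))
    expect_equal(tf$f, unname(m$fstatistic[1]), tolerance = 1e-8)
    expect_equal(tf$adjR2, m$adj.r.squared, tolerance = 1e-8)
    expect_equal(tf$p, unname(pf(m$fstatistic[1], 1, 10, lower.tail = FALSE)),
                 tolerance = 1e-8)
})

test_that("trend regression handles exact and degenerate inputs", {
    ev <- expand.grid(antibiotic = c(0, 4, 8, 10),
                      temperature = c(37, 40, 42))
    exact <- data.frame(ev, value = 2 - 0.1 * ev$antibiotic)
    tf <- trendVsEnvironment(exact, "antibiotic")
    expect_equal(tf$adjR2, 1)
    expect_equal(tf$slope, -0.1)
    const <- data.frame(ev, value = 1)
    tf0 <- trendVsEnvironment(const, "antibiotic")
    expect_equal(tf0$slope, 0)
    expect_equal(tf0$f, 0)
    one <- data.frame(antibiotic = 4, temperature = c(37, 40, 42), value = 1:3)
    expect_error(trendVsEnvironment(one, "antibiotic"),
                 class = "epiScape_data_error")
})

test_that("environmental quality measures mean competitor growth", {
    df <- expand.grid(abr = c("WT", "A"), ko = c("none", "B"),
                      antibiotic = c(0, 4), temperature = 37, replicate = 1:2,
                      stringsAsFactors = FALSE)
    df$w <- 0
    rec <- recordsFromW(df, growth = 2)   # every strain exactly doubles
    q <- environmentalQuality(rec)
    expect_equal(q$quality, rep(log(2), 2))
    # halving growth in one environment shifts quality by log(1/2)
    rec2 <- rec
    half <- rec2$antibiotic == 4
    rec2$d_comp_final[half] <- rec2$d_comp_final[half] / 2
    q2 <- environmentalQuality(rec2)
    expect_equal(q2$quality[q2$antibiotic == 4] -
                 q2$quality[q2$antibiotic == 0], log(1 / 2))
    # reference metric is unaffected by the competitor channel
    qRef <- environmentalQuality(rec2, metric = "reference")
    expect_equal(qRef$quality, rep(log(2), 2))
})

test_that("quality declines with antibiotic when susceptibles are suppressed", {
    p <- scenario("gxe_only", seed = 13)
    sim <- simulateCompetitions(p)
    q <- environmentalQuality(sim$records)
    for (tmp in unique(q$temperature)) {
        qt <- q[q$temperature == tmp, ]
        qt <- qt[order(qt$antibiotic), ]
        expect_true(all(diff(qt$quality) < 0))
    }
})

test_that("cost of resistance contrasts resistant vs susceptible at zero antibiotic", {
    df <- expand.grid(abr = c("WT", "A"), ko = c("none", "B"),
                      antibiotic = c(0, 4), temperature = 37,
                      stringsAsFactors = FALSE)
    df$w <- 0; df$se <- 0; df$n <- 3L
    fl <- flFromW(df)
    cr <- costOfResistance(fl, bootParam(100, seed = 14))
    expect_equal(nrow(cr), 2L)          # two backgrounds, one ABR allele
    expect_equal(cr$contrast, c(0, 0))
    expect_false(any(cr$cost))
    # a true cost with zero SE is flagged
    df$w[df$abr == "A"] <- -0.4
    cr2 <- costOfResistance(flFromW(df), bootParam(100, seed = 14))
    expect_equal(cr2$contrast, c(-0.4, -0.4))
    expect_true(all(cr2$cost))
    # no antibiotic-free environment: error
    df4 <- df[df$antibiotic == 4, ]
    expect_error(costOfResistance(flFromW(df4), bootParam(10, seed = 1)),
                 class = "epiScape_data_error")
})

test_that("cost flags are rare when resistance is truly free", {
    # no-cost truth: every resistance allele shares the susceptible allele's
    # effect, so each contrast is 0; only measurement noise remains
    flagged <- 0L; total <- 0L
    set.seed(99)
    for (s in 1:20) {
        df <- expand.grid(abr = c("WT", "S512F", "H526Y", "I572S"),
                          ko = c("none", "marR", "nuoC"),
                          antibiotic = 0, temperature = 37, replicate = 1:4,
                          stringsAsFactors = FALSE)
        aKo <- c(none = 0, marR = 0.2, nuoC = -0.3)
        df$w <- aKo[df$ko] + rnorm(nrow(df), 0, 0.07)
        fl <- summarizeFitness(recordsFromW(df))
        cr <- costOfResistance(fl, bootParam(300, seed = s))
        flagged <- flagged + sum(cr$cost)
        total <- total + nrow(cr)
    }
    expect_lte(flagged / total, 0.10)
})
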