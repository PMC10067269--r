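#' Pairwise epistasis of a two-locus landscape
#'
#' Classical pairwise epistasis: the deviation of the double mutant from the
#' additive expectation of its single mutants, with the wild type as baseline:
#' \deqn{\epsilon = w_{AB} - w_A - w_B + w_{WT}}
#' It is invariant to adding a constant to all four fitness values and zero on
#' any additive landscape.
#'
#' @param slice a \linkS4class{LandscapeSlice}
#' @return dimensionless real
#' @export
pairwiseEpistasis <- function(slice) {
    unname(slice@w["double"] - slice@w["abr"] - slice@w["ko"] + slice@w["wt"])
}

# one row per (mutation, background) pair of the design: ABR mutations on
# every KO background, KO mutations on every ABR background. `base` marks the
# background with no mutation at the other locus.
effectPlan <- function(x) {
    gids <- genotypeId(abrAlleles(x), koAlleles(x))
    wtA <- abrWildType(x); wtK <- koWildType(x)
    abrs <- setdiff(unique(abrAlleles(x)), wtA)
    kos <- setdiff(unique(koAlleles(x)), wtK)
    bgA <- expand.grid(mutation = abrs, bg_ko = c(wtK, kos),
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    bgA$class <- "ABR"; bgA$bg_abr <- wtA; bgA$base <- bgA$bg_ko == wtK
    bgA$from <- match(genotypeId(wtA, bgA$bg_ko), gids)
    bgA$to <- match(genotypeId(bgA$mutation, bgA$bg_ko), gids)
    bgK <- expand.grid(mutation = kos, bg_abr = c(wtA, abrs),
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    bgK$class <- "KO"; bgK$bg_ko <- wtK; bgK$base <- bgK$bg_abr == wtA
    bgK$from <- match(genotypeId(bgK$bg_abr, wtK), gids)
    bgK$to <- match(genotypeId(bgK$bg_abr, bgK$mutation), gids)
    cols <- c("mutation", "class", "bg_abr", "bg_ko", "base", "from", "to")
    plan <- rbind(bgA[cols], bgK[cols])
    if (anyNA(plan$from) || anyNA(plan$to))
        epiStop("epiScape_grid_error", "incomplete genotype grid")
    plan
}

#' Fitness effects of every single mutation on every background
#'
#' For each non-wild-type allele m and each genotype g lacking m (a
#' "background"), the effect is w(g plus m) - w(g). For the default design each
#' of the 3 resistance mutations appears on 6 knock-out backgrounds and each of
#' the 5 knock-outs on 4 resistance backgrounds: 38 effects per environment.
#'
#' @param x a \linkS4class{FitnessLandscape}
#' @param antibiotic,temperature environment; if both NULL, all environments.
#' @return data.frame with columns \code{mutation}, \code{class} ("ABR"/"KO"),
#'   \code{bg_abr}, \code{bg_ko} (the background genotype), \code{base}
#'   (TRUE when the background has no mutation at the other locus),
#'   \code{antibiotic}, \code{temperature}, \code{bg_w} (background fitness)
#'   and \code{effect}.
#' @export
mutationEffects <- function(x, antibiotic = NULL, temperature = NULL) {
    ev <- environments(x)
    cols <- seq_len(nrow(ev))
    if (!is.null(antibiotic) || !is.null(temperature)) {
        cols <- which(ev$antibiotic == antibiotic &
                      ev$temperature == temperature)
        if (length(cols) != 1L)
            epiStop("epiScape_grid_error",
                    "environment (%s, %s) not in the table",
                    antibiotic, temperature)
    }
    plan <- effectPlan(x)
    w <- wMean(x)
    do.call(rbind, lapply(cols, function(j) {
        data.frame(plan[c("mutation", "class", "bg_abr", "bg_ko", "base")],
                   antibiotic = ev$antibiotic[j],
                   temperature = ev$temperature[j],
                   bg_w = w[plan$from, j],
                   effect = w[plan$to, j] - w[plan$from, j],
                   row.names = NULL)
    }))
}

# mutationEffects for an arbitrary fitness vector over the object's genotypes
# (bootstrap inner loop; avoids rebuilding containers)
mutationEffectsVec <- function(plan, wj) {
    data.frame(plan[c("mutation", "class", "base")],
               bg_w = wj[plan$from], effect = wj[plan$to] - wj[plan$from],
               row.names = NULL)
}

# For each focal mutation, pair its effect on the base background (no mutation
# at the other locus) with its effect on each single-mutant background at the
# other locus. With two loci this is the only available pairing.
gammaPairs <- function(effects) {
    base <- effects[effects$base, c("mutation", "effect")]
    others <- effects[!effects$base, c("mutation", "effect")]
    m <- match(others$mutation, base$mutation)
    data.frame(mutation = others$mutation,
               base = base$effect[m], added = others$effect)
}

#' Gamma statistic: background correlation of mutational effects
#'
#' Pools, over every focal mutation m of the requested class, the ordered
#' pairs (effect of m on the base background g, effect of m on g plus d)
#' where d is a single mutation at the other locus, and returns the Pearson
#' correlation of the pooled pairs. Gamma near 1 means effects are preserved
#' across backgrounds (no gene-by-gene interaction); near 0 or negative means
#' strong epistasis.
#'
#' @param effects data.frame from [mutationEffects()], restricted to one
#'   environment.
#' @param focalClass which mutations' effects are correlated: "all" (default),
#'   "ABR" or "KO".
#' @return correlation in [-1, 1]. If either pooled vector has zero variance
#'   the value is degenerate: 1 when the two vectors are identical (perfectly
#'   preserved effects), otherwise NA; the result then carries attribute
#'   \code{degenerate = TRUE}.
#' @export
gammaStatistic <- function(effects, focalClass = c("all", "ABR", "KO")) {
    focalClass <- match.arg(focalClass)
    if (!is.null(effects$antibiotic) &&
        length(unique(paste(effects$antibiotic, effects$temperature))) > 1L)
        epiStop("epiScape_data_error",
                "gammaStatistic expects effects from a single environment")
    if (focalClass != "all")
        effects <- effects[effects$class == focalClass, , drop = FALSE]
    p <- gammaPairs(effects)
    p <- p[complete.cases(p), , drop = FALSE]
    if (nrow(p) < 2L)
        epiStop("epiScape_data_error",
                "need >= 2 effect pairs for the gamma statistic")
    gammaFromPairs(p$base, p$added)
}

gammaFromPairs <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) {
        val <- if (isTRUE(all.equal(x, y))) 1 else NA_real_
        return(structure(val, degenerate = TRUE))
    }
    cor(x, y)
}

#' Classify sign epistasis of a slice
#'
#' A mutation shows sign epistasis when its fitness effect changes sign
#' depending on the background. With effects sA0 = w_abr - w_wt,
#' sA1 = w_double - w_ko (resistance mutation) and sB0 = w_ko - w_wt,
#' sB1 = w_double - w_abr (knock-out), the slice is \code{"reciprocal"} when
#' both mutations change sign, \code{"simple"} when exactly one does and
#' \code{"none"} otherwise. Effects within \code{tol} of zero carry no sign.
#'
#' @param slice a \linkS4class{LandscapeSlice}
#' @param tol absolute tolerance below which an effect is treated as zero
#'   (default 0: exact comparison of point estimates; uncertainty is handled
#'   by the bootstrap layer, see [signEpistasisFractions()]).
#' @return one of \code{"none"}, \code{"simple"}, \code{"reciprocal"}.
#' @export
classifySignEpistasis <- function(slice, tol = 0) {
    w <- slice@w
    classifySignW(w["wt"], w["abr"], w["ko"], w["double"], tol)
}

# vectorized classifier core shared with the bootstrap layer
classifySignW <- function(wt, abr, ko, dbl, tol = 0) {
    sgn <- function(v) ifelse(abs(v) <= tol, 0L, sign(v))
    sA0 <- sgn(abr - wt); sA1 <- sgn(dbl - ko)
    sB0 <- sgn(ko - wt); sB1 <- sgn(dbl - abr)
    aFlip <- sA0 != 0L & sA1 != 0L & sA0 != sA1
    bFlip <- sB0 != 0L & sB1 != 0L & sB0 != sB1
    out <- rep("none", length(aFlip))
    out[xor(aFlip, bFlip)] <- "simple"
    out[aFlip & bFlip] <- "reciprocal"
    out
}

#' Roughness-to-slope ratio of a slice
#'
#' Fits the best additive plane w ~ intercept + 1(resistance mutation) +
#' 1(knock-out) over the four genotypes by least squares. Roughness is the
#' root-mean-square residual (residual sum of squares divided by the number of
#' genotypes, 4); slope is the mean of the absolute values of the two locus
#' coefficients. The ratio is 0 for a purely additive landscape and grows with
#' ruggedness. For two loci the closed form is |pairwise epistasis| / 4 over
#' the mean absolute slope.
#'
#' @param slice a \linkS4class{LandscapeSlice}
#' @return non-negative real; \code{Inf} when the fitted plane is flat but the
#'   landscape is not additive; 0/0 (completely flat landscape) is defined as 0.
#' @export
roughnessToSlope <- function(slice) {
    w <- slice@w
    roughnessToSlopeW(w["wt"], w["abr"], w["ko"], w["double"])
}

# vectorized core: closed form of the 4-point OLS
roughnessToSlopeW <- function(wt, abr, ko, dbl) {
    eps <- dbl - abr - ko + wt
    betaA <- (abr + dbl - wt - ko) / 2
    betaB <- (ko + dbl - wt - abr) / 2
    roughness <- abs(eps) / 4
    slope <- (abs(betaA) + abs(betaB)) / 2
    out <- roughness / slope
    out[roughness == 0 & slope == 0] <- 0
    unname(out)
}

#' Bootstrap fractions of simple and reciprocal sign epistasis per environment
#'
#' In every parametric-bootstrap sample all slices of an environment are
#' classified by [classifySignEpistasis()] and the fraction of slices in each
#' category is recorded. The per-environment summary reports the mean fraction
#' over samples with a percentile confidence interval. Additionally, each
#' slice is flagged "detected" for a category when that category occurs in
#' more than \code{detectThreshold} of the bootstrap samples.
#'
#' @param x a \linkS4class{FitnessLandscape} on the complete grid
#' @param boot a \linkS4class{BootParam}
#' @param detectThreshold per-slice detection rule: a category is called when
#'   it occurs in more than this fraction of samples (default 0.05).
#' @return list with \code{byEnvironment} (data.frame: antibiotic, temperature,
#'   frac_simple, frac_reciprocal with CI bounds, n_boot) and \code{bySlice}
#'   (data.frame per slice: bootstrap rate of each category and detection
#'   flags).
#' @export
signEpistasisFractions <- function(x, boot = bootParam(),
                                   detectThreshold = 0.05) {
    si <- sliceIndexMatrix(x)
    ev <- environments(x)
    se <- usableSE(x)$se
    w <- wMean(x)
    B <- boot@nSamples
    alpha <- 1 - boot@ciLevel
    nSlice <- nrow(si$idx)

    byEnv <- vector("list", nrow(ev))
    bySlice <- vector("list", nrow(ev))
    draws <- withSeed(boot@seed,
        array(rnorm(length(w) * B), dim = c(nrow(w), ncol(w), B)))
    for (j in seq_len(nrow(ev))) {
        wj <- w[, j] + se[, j] * matrix(draws[, j, ], nrow = nrow(w))  # genotypes x B
        cls <- matrix(classifySignW(wj[si$idx[, "wt"], ], wj[si$idx[, "abr"], ],
                                    wj[si$idx[, "ko"], ], wj[si$idx[, "double"], ]),
                      nrow = nSlice)
        fracSimple <- colMeans(cls == "simple")
        fracRecip <- colMeans(cls == "reciprocal")
        ciS <- quantile(fracSimple, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 1)
        ciR <- quantile(fracRecip, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 1)
        byEnv[[j]] <- data.frame(
            antibiotic = ev$antibiotic[j], temperature = ev$temperature[j],
            frac_simple = mean(fracSimple),
            frac_simple_lo = ciS[1], frac_simple_hi = ciS[2],
            frac_reciprocal = mean(fracRecip),
            frac_reciprocal_lo = ciR[1], frac_reciprocal_hi = ciR[2],
            n_boot = B)
        rateS <- rowMeans(cls == "simple")
        rateR <- rowMeans(cls == "reciprocal")
        bySlice[[j]] <- data.frame(
            abr_allele = si$pairs$abr, ko_allele = si$pairs$ko,
            antibiotic = ev$antibiotic[j], temperature = ev$temperature[j],
            rate_simple = rateS, rate_reciprocal = rateR,
            detected_simple = rateS > detectThreshold,
            detected_reciprocal = rateR > detectThreshold)
    }
    list(byEnvironment = do.call(rbind, byEnv),
         bySlice = do.call(rbind, bySlice))
}

#' Per-slice epistasis tables for all environments
#'
#' Point estimates of pairwise epistasis and the roughness-to-slope ratio for
#' every slice of the landscape, with optional percentile bootstrap CIs.
#'
#' @param x a \linkS4class{FitnessLandscape}
#' @param boot a \linkS4class{BootParam}, or NULL for point estimates only
#' @return data.frame, one row per slice per environment, with columns
#'   \code{pairwise}, \code{rs_ratio} and (with \code{boot}) their CI bounds.
#' @export
sliceMetrics <- function(x, boot = NULL) {
    si <- sliceIndexMatrix(x)
    ev <- environments(x)
    w <- wMean(x)
    out <- do.call(rbind, lapply(seq_len(nrow(ev)), function(j) {
        wj <- w[, j]
        data.frame(abr_allele = si$pairs$abr, ko_allele = si$pairs$ko,
                   antibiotic = ev$antibiotic[j],
                   temperature = ev$temperature[j],
                   pairwise = wj[si$idx[, "double"]] - wj[si$idx[, "abr"]] -
                       wj[si$idx[, "ko"]] + wj[si$idx[, "wt"]],
                   rs_ratio = roughnessToSlopeW(
                       wj[si$idx[, "wt"]], wj[si$idx[, "abr"]],
                       wj[si$idx[, "ko"]], wj[si$idx[, "double"]]),
                   row.names = NULL)
    }))
    if (is.null(boot)) return(out)
    se <- usableSE(x)$se
    B <- boot@nSamples
    alpha <- 1 - boot@ciLevel
    draws <- withSeed(boot@seed,
        array(rnorm(length(w) * B), dim = c(nrow(w), ncol(w), B)))
    ci <- do.call(rbind, lapply(seq_len(nrow(ev)), function(j) {
        wj <- w[, j] + se[, j] * matrix(draws[, j, ], nrow = nrow(w))
        epsB <- wj[si$idx[, "double"], ] - wj[si$idx[, "abr"], ] -
            wj[si$idx[, "ko"], ] + wj[si$idx[, "wt"], ]
        epsB <- matrix(epsB, nrow = nrow(si$idx))
        rsB <- matrix(roughnessToSlopeW(
            wj[si$idx[, "wt"], ], wj[si$idx[, "abr"], ],
            wj[si$idx[, "ko"], ], wj[si$idx[, "double"], ]),
            nrow = nrow(si$idx))
        t(vapply(seq_len(nrow(si$idx)), function(i) c(
            quantile(epsB[i, ], c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 1),
            quantile(rsB[i, ], c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 1)),
            numeric(4)))
    }))
    out$pairwise_lo <- ci[, 1]; out$pairwise_hi <- ci[, 2]
    out$rs_ratio_lo <- ci[, 3]; out$rs_ratio_hi <- ci[, 4]
    out
}

#' Per-environment epistasis summary
#'
#' Computes, for every environment: the gamma statistic over all mutations and
#' per mutational class (with percentile bootstrap CIs), the bootstrap mean
#' fractions of simple and reciprocal sign epistasis (with CIs), and the mean
#' roughness-to-slope ratio over slices (with CI).
#'
#' @param x a \linkS4class{FitnessLandscape} on the complete grid
#' @param boot a \linkS4class{BootParam}
#' @return data.frame, one row per environment.
#' @export
epistasisSummary <- function(x, boot = bootParam()) {
    ev <- environments(x)
    w <- wMean(x)
    se <- usableSE(x)$se
    si <- sliceIndexMatrix(x)
    plan <- effectPlan(x)
    B <- boot@nSamples
    alpha <- 1 - boot@ciLevel
    frac <- signEpistasisFractions(x, boot)$byEnvironment
    draws <- withSeed(boot@seed + 1L,
        array(rnorm(length(w) * B), dim = c(nrow(w), ncol(w), B)))

    gammaOfVec <- function(wj, cls) {
        pl <- if (cls == "all") plan else plan[plan$class == cls, , drop = FALSE]
        base <- wj[pl$to[pl$base]] - wj[pl$from[pl$base]]
        names(base) <- pl$mutation[pl$base]
        added <- wj[pl$to[!pl$base]] - wj[pl$from[!pl$base]]
        as.numeric(gammaFromPairs(unname(base[pl$mutation[!pl$base]]), added))
    }
    rows <- lapply(seq_len(nrow(ev)), function(j) {
        wj <- w[, j]
        wB <- w[, j] + se[, j] * matrix(draws[, j, ], nrow = nrow(w))
        res <- data.frame(antibiotic = ev$antibiotic[j],
                          temperature = ev$temperature[j])
        for (cls in c("all", "ABR", "KO")) {
            pt <- gammaOfVec(wj, cls)
            bs <- vapply(seq_len(B), function(b) gammaOfVec(wB[, b], cls),
                         numeric(1))
            ci <- quantile(bs, c(alpha / 2, 1 - alpha / 2),
                           names = FALSE, na.rm = TRUE, type = 1)
            nm <- paste0("gamma_", tolower(cls))
            res[[nm]] <- pt
            res[[paste0(nm, "_lo")]] <- ci[1]
            res[[paste0(nm, "_hi")]] <- ci[2]
        }
        rs <- roughnessToSlopeW(wj[si$idx[, "wt"]], wj[si$idx[, "abr"]],
                                wj[si$idx[, "ko"]], wj[si$idx[, "double"]])
        rsB <- colMeans(matrix(roughnessToSlopeW(
            wB[si$idx[, "wt"], ], wB[si$idx[, "abr"], ],
            wB[si$idx[, "ko"], ], wB[si$idx[, "double"], ]),
            nrow = nrow(si$idx)))
        ci <- quantile(rsB, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 1)
        res$rs_mean <- mean(rs); res$rs_mean_lo <- ci[1]; res$rs_mean_hi <- ci[2]
        res
    })
    out <- do.call(rbind, rows)
    out <- merge(out, frac, by = c("antibiotic", "temperature"), sort = FALSE)
    out[order(out$antibiotic, out$temperature), ]
}

#' Diminishing-returns regression of mutational effects on background fitness
#'
#' For one mutational class and one environment, regresses the effect of each
#' focal mutation on the fitness of the background carrying it, pooling all
#' mutations of the class in a single regression. The slope is summarized over
#' parametric-bootstrap samples: reported is the mean slope with a percentile
#' confidence interval; the effect is "significant" when the interval excludes
#' zero. A negative significant slope is diminishing-returns epistasis.
#'
#' @param x a \linkS4class{FitnessLandscape}
#' @param focalClass "ABR" or "KO"
#' @param boot a \linkS4class{BootParam}
#' @param excludeBackgrounds optional allele labels whose backgrounds are
#'   dropped (sensitivity analysis, e.g. removing a hypersusceptible knock-out)
#' @return data.frame, one row per environment: \code{slope} (bootstrap mean),
#'   \code{slope_lo}, \code{slope_hi}, \code{point} (point-estimate slope),
#'   \code{significant}, \code{n_points}.
#' @export
diminishingReturns <- function(x, focalClass = c("ABR", "KO"),
                               boot = bootParam(),
                               excludeBackgrounds = NULL) {
    focalClass <- match.arg(focalClass)
    ev <- environments(x)
    w <- wMean(x)
    se <- usableSE(x)$se
    plan <- effectPlan(x)
    plan <- plan[plan$class == focalClass, , drop = FALSE]
    if (!is.null(excludeBackgrounds))
        plan <- plan[!(plan$bg_ko %in% excludeBackgrounds |
                       plan$bg_abr %in% excludeBackgrounds), , drop = FALSE]
    if (nrow(plan) < 3L)
        epiStop("epiScape_data_error",
                "need >= 3 (background, effect) points, have %d", nrow(plan))
    B <- boot@nSamples
    alpha <- 1 - boot@ciLevel
    slopeOf <- function(wv) {
        xs <- wv[plan$from]
        ys <- wv[plan$to] - wv[plan$from]
        vx <- sum((xs - mean(xs))^2)
        if (vx == 0) return(NA_real_)
        sum((xs - mean(xs)) * (ys - mean(ys))) / vx
    }
    draws <- withSeed(boot@seed + 2L,
        array(rnorm(length(w) * B), dim = c(nrow(w), ncol(w), B)))
    out <- do.call(rbind, lapply(seq_len(nrow(ev)), function(j) {
        point <- slopeOf(w[, j])
        wB <- w[, j] + se[, j] * matrix(draws[, j, ], nrow = nrow(w))
        bs <- vapply(seq_len(B), function(b) slopeOf(wB[, b]), numeric(1))
        ci <- quantile(bs, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                       na.rm = TRUE, type = 1)
        data.frame(antibiotic = ev$antibiotic[j],
                   temperature = ev$temperature[j],
                   slope = mean(bs, na.rm = TRUE),
                   slope_lo = ci[1], slope_hi = ci[2], point = point,
                   significant = ci[1] > 0 || ci[2] < 0,
                   n_points = nrow(plan))
    }))
    out
}
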