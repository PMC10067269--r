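#' Parametric bootstrap of a fitness table
#'
#' Draws bootstrap replicates of the whole genotype-by-environment fitness
#' table: every cell is redrawn independently from Normal(w_mean, w_se).
#' Cells with a single replicate have no sample SE and borrow the median SE
#' of their environment (flagged in the result). Streams are reproducible:
#' identical seed, table and sample count give identical draws.
#'
#' @param x a \linkS4class{FitnessLandscape}
#' @param boot a \linkS4class{BootParam}
#' @return list with \code{samples} (array genotype x environment x nSamples),
#'   \code{seImputed} (logical matrix of borrowed SEs).
#' @export
parametricBootstrap <- function(x, boot = bootParam()) {
    w <- wMean(x)
    if (any(!is.finite(w)))
        epiStop("epiScape_data_error", "non-finite fitness means")
    u <- usableSE(x)
    B <- boot@nSamples
    draws <- withSeed(boot@seed,
        array(rnorm(length(w) * B), dim = c(dim(w), B)))
    samples <- array(w, dim = c(dim(w), B)) +
        array(u$se, dim = c(dim(w), B)) * draws
    dimnames(samples) <- c(dimnames(w), list(NULL))
    list(samples = samples, seImputed = u$imputed)
}

# replace the w_mean assay of a FitnessLandscape (bootstrap plumbing)
replaceW <- function(x, w) {
    SummarizedExperiment::assay(x, "w_mean", withDimnames = FALSE) <- w
    x
}

#' Percentile bootstrap confidence interval for any fitness-table metric
#'
#' Evaluates \code{metric} on the observed table (the point estimate) and on
#' every parametric-bootstrap replicate, and reports the percentile interval
#' at the configured level. Metric evaluations that fail are dropped, but an
#' error is raised if more than 10 percent of samples fail.
#'
#' @param metric function taking a \linkS4class{FitnessLandscape} and
#'   returning a numeric scalar
#' @param x a \linkS4class{FitnessLandscape}
#' @param boot a \linkS4class{BootParam}
#' @return list with \code{point}, \code{lo}, \code{hi}, \code{samples}
#'   (numeric vector of bootstrap metric values) and \code{nFailed}.
#' @export
bootstrapCI <- function(metric, x, boot = bootParam()) {
    point <- metric(x)
    pb <- parametricBootstrap(x, boot)
    B <- boot@nSamples
    vals <- vapply(seq_len(B), function(b) {
        wb <- matrix(pb$samples[, , b], nrow(x), ncol(x))
        tryCatch(as.numeric(metric(replaceW(x, wb))),
                 error = function(e) NA_real_)
    }, numeric(1))
    nFailed <- sum(is.na(vals))
    if (nFailed > 0.1 * B)
        epiStop("epiScape_data_error",
                "metric failed on %d of %d bootstrap samples", nFailed, B)
    ok <- vals[!is.na(vals)]
    alpha <- 1 - boot@ciLevel
    ci <- quantile(ok, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 1)
    list(point = point, lo = ci[1], hi = ci[2], samples = ok,
         nFailed = nFailed)
}

#' Regression of a per-environment metric on an environmental gradient
#'
#' Ordinary least-squares regression of one value per environment on a
#' continuous predictor: antibiotic concentration, temperature, or a supplied
#' environmental-quality mapping. Reports the slope, the F-test of the slope,
#' and adjusted R-squared, the form in which epistasis-versus-gradient trends
#' are summarized.
#'
#' @param values data.frame with columns \code{antibiotic},
#'   \code{temperature} and \code{value} (one row per environment)
#' @param predictor \code{"antibiotic"}, \code{"temperature"}, or
#'   \code{"quality"} (requires \code{quality})
#' @param quality optional data.frame (antibiotic, temperature, quality) used
#'   when \code{predictor = "quality"}
#' @return object of class \code{trendFit}: list with \code{slope},
#'   \code{intercept}, \code{f}, \code{df1}, \code{df2}, \code{p},
#'   \code{adjR2}, \code{n}.
#' @export
trendVsEnvironment <- function(values,
                               predictor = c("antibiotic", "temperature",
                                             "quality"),
                               quality = NULL) {
    predictor <- match.arg(predictor)
    if (!all(c("antibiotic", "temperature", "value") %in% names(values)))
        epiStop("epiScape_schema_error",
                "values needs columns antibiotic, temperature, value")
    if (nrow(values) < 3L)
        epiStop("epiScape_data_error", "need >= 3 environments, have %d",
                nrow(values))
    xv <- switch(predictor,
        antibiotic = values$antibiotic,
        temperature = values$temperature,
        quality = {
            if (is.null(quality))
                epiStop("epiScape_schema_error",
                        "predictor 'quality' needs the quality mapping")
            m <- match(paste(values$antibiotic, values$temperature),
                       paste(quality$antibiotic, quality$temperature))
            if (anyNA(m))
                epiStop("epiScape_grid_error",
                        "quality mapping lacks some environments")
            quality$quality[m]
        })
    if (sd(xv) == 0)
        epiStop("epiScape_data_error", "constant predictor '%s'", predictor)
    yv <- values$value
    keep <- is.finite(yv)
    xv <- xv[keep]; yv <- yv[keep]
    n <- length(yv)
    slope <- sum((xv - mean(xv)) * (yv - mean(yv))) / sum((xv - mean(xv))^2)
    intercept <- mean(yv) - slope * mean(xv)
    fitted <- intercept + slope * xv
    ssTot <- sum((yv - mean(yv))^2)
    ssRes <- sum((yv - fitted)^2)
    ssReg <- ssTot - ssRes
    df1 <- 1L; df2 <- n - 2L
    f <- if (ssReg <= 0) 0 else (ssReg / df1) / (ssRes / df2)
    r2 <- if (ssTot == 0) 0 else ssReg / ssTot
    structure(class = "trendFit", list(
        slope = slope, intercept = intercept, f = f, df1 = df1, df2 = df2,
        p = pf(f, df1, df2, lower.tail = FALSE),
        adjR2 = 1 - (1 - r2) * (n - 1) / (n - 2), r2 = r2, n = n,
        predictor = predictor))
}

#' @export
print.trendFit <- function(x, ...) {
    cat(sprintf(
        "Trend on %s: slope %.4g, F(%d,%d) = %.2f, p = %.3g, adj R2 = %.3f (n = %d)\n",
        x$predictor, x$slope, x$df1, x$df2, x$f, x$p, x$adjR2, x$n))
    invisible(x)
}

#' Environmental quality metric
#'
#' Summarizes each environment by the mean growth of the assayed strains over
#' one competition cycle. The default metric averages the log growth of all
#' competitor strains, ln(final/initial competitor density), across genotypes
#' and replicates; the reference-strain and combined variants are selectable.
#'
#' @param records competition records (see \link{competition-records})
#' @param metric \code{"competitor"} (default), \code{"reference"} or
#'   \code{"combined"}
#' @return data.frame with columns \code{antibiotic}, \code{temperature},
#'   \code{quality}, one row per environment.
#' @export
environmentalQuality <- function(records,
                                 metric = c("competitor", "reference",
                                            "combined")) {
    metric <- match.arg(metric)
    checkRecords(records)
    g <- switch(metric,
        competitor = log(records$d_comp_final / records$d_comp_initial),
        reference = log(records$d_ref_final / records$d_ref_initial),
        combined = log((records$d_comp_final + records$d_ref_final) /
                       (records$d_comp_initial + records$d_ref_initial)))
    key <- paste(records$antibiotic, records$temperature, sep = "\r")
    agg <- tapply(g, key, mean)
    meta <- records[!duplicated(key), c("antibiotic", "temperature")]
    meta <- meta[match(names(agg), unique(key)), ]
    out <- data.frame(antibiotic = meta$antibiotic,
                      temperature = meta$temperature,
                      quality = as.numeric(agg), row.names = NULL)
    out[order(out$antibiotic, out$temperature), ]
}

#' Cost of resistance in antibiotic-free environments
#'
#' For every knock-out background and temperature at antibiotic concentration
#' zero, contrasts the fitness of each resistance mutation against the
#' susceptible wild-type allele on the same background:
#' contrast = w(abr, ko) - w(WT, ko). A percentile parametric-bootstrap
#' interval accompanies each contrast; a "cost" is flagged only when the whole
#' interval lies below zero.
#'
#' @param x a \linkS4class{FitnessLandscape} containing antibiotic-free
#'   environments
#' @param boot a \linkS4class{BootParam}
#' @return data.frame with one row per (knock-out background, resistance
#'   allele, temperature): \code{contrast}, \code{lo}, \code{hi}, \code{cost}.
#' @export
costOfResistance <- function(x, boot = bootParam()) {
    ev <- environments(x)
    cols <- which(ev$antibiotic == 0)
    if (!length(cols))
        epiStop("epiScape_data_error", "no antibiotic-free environment present")
    w <- wMean(x)
    se <- usableSE(x)$se
    gids <- genotypeId(abrAlleles(x), koAlleles(x))
    wtA <- abrWildType(x)
    abrs <- setdiff(unique(abrAlleles(x)), wtA)
    kos <- unique(koAlleles(x))
    B <- boot@nSamples
    alpha <- 1 - boot@ciLevel
    draws <- withSeed(boot@seed + 3L,
        array(rnorm(length(w) * B), dim = c(dim(w), B)))
    out <- list(); k <- 0L
    for (j in cols) for (ko in kos) for (a in abrs) {
        rAbr <- match(genotypeId(a, ko), gids)
        rWt <- match(genotypeId(wtA, ko), gids)
        if (is.na(rAbr) || is.na(rWt)) next
        contrast <- w[rAbr, j] - w[rWt, j]
        bs <- (w[rAbr, j] + se[rAbr, j] * draws[rAbr, j, ]) -
              (w[rWt, j] + se[rWt, j] * draws[rWt, j, ])
        ci <- quantile(bs, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 1)
        k <- k + 1L
        out[[k]] <- data.frame(
            ko_allele = ko, abr_allele = a,
            temperature = ev$temperature[j], contrast = contrast,
            lo = ci[1], hi = ci[2], cost = ci[2] < 0)
    }
    do.call(rbind, out)
}
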