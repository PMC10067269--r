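#' Build a design matrix for the competitive-index regressions
#'
#' Builds the model matrix for per-replicate competitive indices with the
#' package's standard factor coding: treatment contrasts with wild-type
#' reference levels for the two genotype factors, orthogonal polynomial
#' contrasts (linear, quadratic) for the ordered temperature factor, and the
#' antibiotic concentration coded either as an unordered factor (default, as
#' in the interaction model suite) or as a continuous covariate.
#'
#' @param data data.frame of per-replicate indices from [replicateIndices()]
#'   (columns \code{abr_allele}, \code{ko_allele}, \code{antibiotic},
#'   \code{temperature}, \code{w})
#' @param terms character vector of model terms over \code{"abr"}, \code{"ko"},
#'   \code{"antibiotic"}, \code{"temperature"} and \code{:} interactions,
#'   e.g. \code{c("abr", "ko", "antibiotic", "temperature", "abr:antibiotic")}
#' @param abCoding \code{"factor"} or \code{"continuous"}
#' @param abrWildType,koWildType reference levels of the genotype factors
#' @return list with \code{X} (design matrix), \code{y} (response),
#'   \code{formula}, and the model \code{frame}.
#' @export
buildDesign <- function(data,
                        terms = c("abr", "ko", "antibiotic", "temperature"),
                        abCoding = c("factor", "continuous"),
                        abrWildType = "WT", koWildType = "none") {
    abCoding <- match.arg(abCoding)
    need <- c("abr_allele", "ko_allele", "antibiotic", "temperature", "w")
    miss <- setdiff(need, names(data))
    if (length(miss))
        epiStop("epiScape_schema_error", "missing columns: %s",
                paste(miss, collapse = ", "))
    frame <- data.frame(
        abr = stats::relevel(factor(data$abr_allele), ref = abrWildType),
        ko = stats::relevel(factor(data$ko_allele), ref = koWildType),
        antibiotic = if (abCoding == "factor") factor(data$antibiotic)
                     else data$antibiotic,
        temperature = factor(data$temperature, ordered = TRUE),
        w = data$w)
    fml <- as.formula(paste("w ~", paste(terms, collapse = " + ")))
    X <- model.matrix(fml, frame)
    list(X = X, y = frame$w, formula = fml, frame = frame)
}

#' Ordinary least-squares fit with coefficient inference
#'
#' QR-based least-squares solve of a design matrix against a response, with
#' coefficient standard errors and t-statistics from the residual variance,
#' R-squared and adjusted R-squared. Rank-deficient designs are rejected with
#' the names of the collinear columns.
#'
#' @param X design matrix (including the intercept column)
#' @param y response vector
#' @return object of class \code{olsFit}: coefficient table, residuals,
#'   fitted values, residual df, \code{r2}, \code{adjR2}, \code{sigma},
#'   overall F-statistic, and the \code{X} column names.
#' @export
fitOLS <- function(X, y) {
    if (nrow(X) < ncol(X))
        epiStop("epiScape_data_error", "fewer rows (%d) than columns (%d)",
                nrow(X), ncol(X))
    fit <- lm.fit(X, y)
    if (fit$rank < ncol(X)) {
        dropped <- colnames(X)[is.na(fit$coefficients)]
        epiStop("epiScape_data_error",
                "rank-deficient design; collinear columns: %s",
                paste(dropped, collapse = ", "))
    }
    res <- fit$residuals
    n <- nrow(X); p <- ncol(X)
    df <- n - p
    ssRes <- sum(res^2)
    hasInt <- any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0))
    ssTot <- if (hasInt) sum((y - mean(y))^2) else sum(y^2)
    r2 <- 1 - ssRes / ssTot
    sigma2 <- ssRes / df
    XtXinv <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
    seCoef <- numeric(p)
    seCoef[fit$qr$pivot] <- sqrt(diag(XtXinv) * sigma2)
    tval <- fit$coefficients / seCoef
    dfModel <- p - hasInt
    fOverall <- if (dfModel > 0) (r2 / dfModel) / ((1 - r2) / df) else NA_real_
    structure(class = "olsFit", list(
        coefficients = data.frame(
            term = colnames(X), estimate = unname(fit$coefficients),
            se = unname(seCoef), t = unname(tval),
            p = unname(2 * pt(abs(tval), df, lower.tail = FALSE))),
        residuals = res, fitted = unname(y - res), df = df, ssRes = ssRes,
        r2 = r2, adjR2 = 1 - (1 - r2) * (n - 1) / df,
        sigma = sqrt(sigma2),
        f = fOverall, dfModel = dfModel,
        terms = colnames(X), n = n))
}

#' @export
print.olsFit <- function(x, ...) {
    cat(sprintf("OLS fit: n = %d, p = %d, R2 = %.4f, adj R2 = %.4f\n",
                x$n, length(x$terms), x$r2, x$adjR2))
    if (is.finite(x$f))
        cat(sprintf("  overall F(%d,%d) = %.2f\n", x$dfModel, x$df, x$f))
    print(x$coefficients, digits = 4, row.names = FALSE)
    invisible(x)
}

#' F-test comparing two nested OLS fits
#'
#' Nestedness is required: the reduced model's columns must be a subset of the
#' full model's terms (by column name) and both fits must share the response
#' (equal row counts). The statistic is
#' F = ((SSR_reduced - SSR_full) / df_diff) / (SSR_full / df_full).
#'
#' @param reduced,full \code{olsFit} objects from [fitOLS()]
#' @return list with \code{f}, \code{df1}, \code{df2}, \code{p}.
#' @export
compareNested <- function(reduced, full) {
    if (!inherits(reduced, "olsFit") || !inherits(full, "olsFit"))
        epiStop("epiScape_schema_error", "both arguments must be olsFit objects")
    if (reduced$n != full$n)
        epiStop("epiScape_data_error", "fits have different row counts")
    if (!all(reduced$terms %in% full$terms))
        epiStop("epiScape_data_error",
                "models are not nested: reduced terms %s absent from full model",
                paste(setdiff(reduced$terms, full$terms), collapse = ", "))
    df1 <- reduced$df - full$df
    if (df1 < 0)
        epiStop("epiScape_data_error", "full model has more residual df")
    if (df1 == 0L)
        return(list(f = 0, df1 = 0L, df2 = full$df, p = 1))
    f <- ((reduced$ssRes - full$ssRes) / df1) / (full$ssRes / full$df)
    f <- max(f, 0)
    list(f = f, df1 = df1, df2 = full$df,
         p = pf(f, df1, full$df, lower.tail = FALSE))
}

#' Nested interaction-model suite for the competitive index
#'
#' Fits the ladder of linear models for per-replicate competitive indices:
#' \enumerate{
#'   \item additive: \code{w ~ abr + ko + antibiotic + temperature}
#'   \item + genotype-by-antibiotic interaction (\code{abr:antibiotic})
#'   \item + genotype-by-genotype interaction (\code{abr:ko})
#' }
#' with nested F-tests between consecutive models, the adjusted R-squared
#' ladder, and residual diagnostics by resistance genotype (sum of squared
#' residuals of the additive model attributed to each resistance allele).
#'
#' @param data per-replicate index table from [replicateIndices()]
#' @param abCoding antibiotic coding, \code{"factor"} (default) or
#'   \code{"continuous"}
#' @param abrWildType,koWildType reference levels
#' @return object of class \code{modelSuite}: \code{fits} (named list of
#'   \code{olsFit}: additive, gxe, gxe_gxg), \code{comparisons} (named list:
#'   additive_vs_gxe, gxe_vs_gxe_gxg), \code{adjR2} (named vector) and
#'   \code{residualsByAbr}.
#' @export
modelSuite <- function(data, abCoding = c("factor", "continuous"),
                       abrWildType = "WT", koWildType = "none") {
    abCoding <- match.arg(abCoding)
    base <- c("abr", "ko", "antibiotic", "temperature")
    specs <- list(additive = base,
                  gxe = c(base, "abr:antibiotic"),
                  gxe_gxg = c(base, "abr:antibiotic", "abr:ko"))
    fits <- lapply(specs, function(tm) {
        d <- buildDesign(data, tm, abCoding, abrWildType, koWildType)
        fitOLS(d$X, d$y)
    })
    comparisons <- list(
        additive_vs_gxe = compareNested(fits$additive, fits$gxe),
        gxe_vs_gxe_gxg = compareNested(fits$gxe, fits$gxe_gxg))
    resid <- fits$additive$residuals
    byAbr <- tapply(resid^2, data$abr_allele, sum)
    structure(class = "modelSuite", list(
        fits = fits, comparisons = comparisons,
        adjR2 = vapply(fits, `[[`, numeric(1), "adjR2"),
        residualsByAbr = byAbr / sum(resid^2)))
}

#' @export
print.modelSuite <- function(x, ...) {
    cat("Nested model suite for the competitive index\n")
    for (nm in names(x$fits)) {
        f <- x$fits[[nm]]
        cat(sprintf("  %-9s adj R2 = %.3f (overall F(%d,%d) = %.1f)\n",
                    nm, f$adjR2, f$dfModel, f$df, f$f))
    }
    for (nm in names(x$comparisons)) {
        cmp <- x$comparisons[[nm]]
        cat(sprintf("  %s: F(%d,%d) = %.2f, p = %.3g\n",
                    nm, cmp$df1, cmp$df2, cmp$f, cmp$p))
    }
    cat("  share of additive-model residual SS by ABR allele:\n")
    print(round(x$residualsByAbr, 3))
    invisible(x)
}
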