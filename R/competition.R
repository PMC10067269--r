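#' Competition-assay record schema
#'
#' Long-format competition records carry one assay replicate per row. The
#' required columns (and the CSV schema read by [readCompetitionRecords()])
#' are: \code{abr_allele}, \code{ko_allele}, \code{antibiotic} (ug/ml),
#' \code{temperature} (degrees C), \code{replicate} (positive integer),
#' \code{orientation} (one of \code{"competitor-GFP"},
#' \code{"competitor-mCherry"}), and four strictly positive densities
#' \code{d_comp_initial}, \code{d_ref_initial}, \code{d_comp_final},
#' \code{d_ref_final} (flow-cytometry events per volume).
#'
#' @name competition-records
NULL

recordColumns <- c("abr_allele", "ko_allele", "antibiotic", "temperature",
                   "replicate", "orientation",
                   "d_comp_initial", "d_ref_initial",
                   "d_comp_final", "d_ref_final")
densityColumns <- c("d_comp_initial", "d_ref_initial",
                    "d_comp_final", "d_ref_final")
orientationLevels <- c("competitor-GFP", "competitor-mCherry")

checkRecords <- function(records) {
    if (!is.data.frame(records) || nrow(records) == 0L)
        epiStop("epiScape_schema_error",
                "competition records must be a non-empty data.frame")
    miss <- setdiff(recordColumns, names(records))
    if (length(miss))
        epiStop("epiScape_schema_error", "missing record columns: %s",
                paste(miss, collapse = ", "))
    bad <- !records$orientation %in% orientationLevels
    if (any(bad))
        epiStop("epiScape_schema_error",
                "invalid orientation in rows %s (allowed: %s)",
                paste(head(which(bad), 5), collapse = ", "),
                paste(orientationLevels, collapse = ", "))
    for (col in densityColumns) {
        v <- records[[col]]
        bad <- !is.finite(v) | v <= 0
        if (any(bad))
            epiStop("epiScape_record_error",
                    "non-positive density in column '%s', rows %s",
                    col, paste(head(which(bad), 5), collapse = ", "),
                    data = list(column = col, rows = which(bad)))
    }
    invisible(records)
}

#' Competitive index of competition-assay records
#'
#' The competitive index, a proxy for relative fitness, is the log change in
#' the competitor:reference density ratio over one competition cycle:
#' \deqn{\hat w = \ln\frac{D^f_{comp}/D^f_{ref}}{D^i_{comp}/D^i_{ref}}}
#' It is zero when competitor and reference grow equally, antisymmetric under
#' exchanging competitor and reference, and invariant to dilution (multiplying
#' all four densities by a positive constant).
#'
#' @param records data.frame of competition records (see
#'   \link{competition-records}); only the four density columns are used.
#' @return numeric vector, one index per record.
#' @examples
#' r <- data.frame(abr_allele = "S512F", ko_allele = "none",
#'                 antibiotic = 0, temperature = 37, replicate = 1,
#'                 orientation = "competitor-GFP",
#'                 d_comp_initial = 500, d_ref_initial = 500,
#'                 d_comp_final = 2000, d_ref_final = 1000)
#' competitiveIndex(r)  # log(2)
#' @export
competitiveIndex <- function(records) {
    if (!is.data.frame(records))
        records <- as.data.frame(records)
    for (col in densityColumns) {
        if (is.null(records[[col]]))
            epiStop("epiScape_schema_error", "missing density column '%s'", col)
        v <- records[[col]]
        bad <- !is.finite(v) | v <= 0
        if (any(bad))
            epiStop("epiScape_record_error",
                    "non-positive density in column '%s', rows %s",
                    col, paste(head(which(bad), 5), collapse = ", "),
                    data = list(column = col, rows = which(bad)))
    }
    log((records$d_comp_final / records$d_ref_final) /
        (records$d_comp_initial / records$d_ref_initial))
}

#' Per-replicate competitive indices with design metadata
#'
#' Convenience wrapper returning one row per record with the genotype and
#' environment columns plus the computed index \code{w}; this is the response
#' table consumed by the linear-model suite ([modelSuite()]).
#'
#' @inheritParams competitiveIndex
#' @return data.frame with columns \code{abr_allele}, \code{ko_allele},
#'   \code{antibiotic}, \code{temperature}, \code{replicate},
#'   \code{orientation}, \code{w}.
#' @export
replicateIndices <- function(records) {
    checkRecords(records)
    out <- records[c("abr_allele", "ko_allele", "antibiotic", "temperature",
                     "replicate", "orientation")]
    out$w <- competitiveIndex(records)
    out
}

#' Summarize competition records into a FitnessLandscape
#'
#' Computes per-replicate competitive indices and aggregates them per
#' genotype-by-environment cell as an unweighted mean with standard error
#' sample SD / sqrt(n). Cells with a single replicate get \code{w_se = NA}
#' (undefined). By default the two fluorophore orientations are pooled; run
#' [dyeSwapCheck()] first to confirm marker neutrality.
#'
#' @inheritParams competitiveIndex
#' @param poolOrientations pool dye orientations into one cell (default TRUE).
#'   With \code{FALSE}, only \code{"competitor-GFP"} records are summarized.
#' @param abrWildType,koWildType labels of the two wild-type alleles.
#' @param reference optional label of the reference strain's resistance allele,
#'   recorded in metadata.
#' @return a \linkS4class{FitnessLandscape}.
#' @export
summarizeFitness <- function(records, poolOrientations = TRUE,
                             abrWildType = "WT", koWildType = "none",
                             reference = NA_character_) {
    checkRecords(records)
    key <- paste(records$abr_allele, records$ko_allele, records$antibiotic,
                 records$temperature, records$replicate, records$orientation,
                 sep = "\r")
    if (anyDuplicated(key))
        epiStop("epiScape_schema_error",
                "duplicated (genotype, environment, replicate, orientation) keys: rows %s",
                paste(head(which(duplicated(key)), 5), collapse = ", "))
    if (!poolOrientations)
        records <- records[records$orientation == "competitor-GFP", , drop = FALSE]
    if (nrow(records) == 0L)
        epiStop("epiScape_schema_error", "no records left to summarize")

    w <- competitiveIndex(records)
    gid <- genotypeId(records$abr_allele, records$ko_allele)
    eid <- environmentId(records$antibiotic, records$temperature)

    gtab <- unique(data.frame(gid = gid, abrAllele = records$abr_allele,
                              koAllele = records$ko_allele,
                              stringsAsFactors = FALSE))
    gtab <- gtab[order(match(gtab$abrAllele, unique(records$abr_allele)),
                       match(gtab$koAllele, unique(records$ko_allele))), ]
    etab <- unique(data.frame(eid = eid, antibiotic = records$antibiotic,
                              temperature = records$temperature))
    etab <- etab[order(etab$antibiotic, etab$temperature), ]

    cell <- interaction(factor(gid, gtab$gid), factor(eid, etab$eid),
                        drop = FALSE)
    nMat <- matrix(as.integer(tapply(w, cell, length)),
                   nrow = nrow(gtab), dimnames = list(gtab$gid, etab$eid))
    meanMat <- matrix(tapply(w, cell, mean),
                      nrow = nrow(gtab), dimnames = dimnames(nMat))
    sdMat <- matrix(tapply(w, cell, sd), nrow = nrow(gtab),
                    dimnames = dimnames(nMat))
    if (anyNA(nMat)) {
        missing <- which(is.na(nMat), arr.ind = TRUE)
        epiStop("epiScape_grid_error",
                "genotype x environment grid incomplete: %d empty cells (e.g. %s in %s)",
                nrow(missing), rownames(nMat)[missing[1, 1]],
                colnames(nMat)[missing[1, 2]],
                data = list(cells = data.frame(
                    genotype = rownames(nMat)[missing[, 1]],
                    environment = colnames(nMat)[missing[, 2]])))
    }
    seMat <- sdMat / sqrt(nMat)
    seMat[nMat < 2L] <- NA_real_

    methods::new("FitnessLandscape", SummarizedExperiment::SummarizedExperiment(
        assays = list(w_mean = meanMat, w_se = seMat, n = nMat),
        rowData = S4Vectors::DataFrame(abrAllele = gtab$abrAllele,
                                       koAllele = gtab$koAllele,
                                       row.names = gtab$gid),
        colData = S4Vectors::DataFrame(antibiotic = etab$antibiotic,
                                       temperature = etab$temperature,
                                       row.names = etab$eid),
        metadata = list(abrWildType = abrWildType, koWildType = koWildType,
                        reference = reference,
                        pooledOrientations = poolOrientations)))
}

#' Dye-swap neutrality check
#'
#' Fluorescent markers must not themselves affect fitness. This check pairs
#' the orientation-wise mean competitive indices per genotype-by-environment
#' cell and regresses the GFP-competitor index on the mCherry-competitor
#' index; a neutral marker gives slope near 1 and intercept near 0. Incremental
#' F-tests report whether adding environment, then genotype, factors explains
#' additional variation beyond the paired index.
#'
#' @inheritParams competitiveIndex
#' @return object of class \code{dyeSwapReport}: a list with \code{slope},
#'   \code{intercept}, \code{adjR2}, \code{slopeCI} (95\% Wald), \code{nPairs},
#'   \code{fTests} (data.frame of incremental F-tests for environment and
#'   genotype), and the fitted \code{model}.
#' @export
dyeSwapCheck <- function(records) {
    checkRecords(records)
    w <- competitiveIndex(records)
    cellKey <- paste(records$abr_allele, records$ko_allele,
                     records$antibiotic, records$temperature, sep = "\r")
    agg <- function(or) {
        keep <- records$orientation == or
        tapply(w[keep], cellKey[keep], mean)
    }
    gfp <- agg("competitor-GFP")
    mch <- agg("competitor-mCherry")
    common <- intersect(names(gfp), names(mch))
    if (length(common) < 3L)
        epiStop("epiScape_data_error",
                "dye-swap check needs both orientations in >= 3 cells (found %d)",
                length(common))
    meta <- records[!duplicated(cellKey), ]
    meta <- meta[match(common, cellKey[!duplicated(cellKey)]), ]
    d <- data.frame(gfp = gfp[common], mch = mch[common],
                    environment = factor(environmentId(meta$antibiotic,
                                                       meta$temperature)),
                    genotype = factor(genotypeId(meta$abr_allele,
                                                 meta$ko_allele)))
    m0 <- lm(gfp ~ mch, data = d)
    fTests <- NULL
    if (nlevels(d$environment) > 1L && nlevels(d$genotype) > 1L) {
        m1 <- lm(gfp ~ mch + environment, data = d)
        m2 <- lm(gfp ~ mch + environment + genotype, data = d)
        a1 <- anova(m0, m1)
        a2 <- anova(m1, m2)
        fTests <- data.frame(
            added = c("environment", "genotype"),
            f = c(a1$F[2], a2$F[2]),
            df1 = c(a1$Df[2], a2$Df[2]),
            df2 = c(a1$Res.Df[2], a2$Res.Df[2]),
            p = c(a1$`Pr(>F)`[2], a2$`Pr(>F)`[2]))
    }
    est <- summary(m0)
    slope <- unname(coef(m0)["mch"])
    structure(class = "dyeSwapReport", list(
        slope = slope, intercept = unname(coef(m0)["(Intercept)"]),
        adjR2 = est$adj.r.squared,
        slopeCI = unname(stats::confint(m0)["mch", ]),
        nPairs = length(common), fTests = fTests, model = m0))
}

#' @export
print.dyeSwapReport <- function(x, ...) {
    cat("Dye-swap neutrality check (", x$nPairs, " paired cells)\n", sep = "")
    cat(sprintf("  GFP ~ mCherry: slope %.3f [%.3f, %.3f], intercept %.3f, adj R2 %.3f\n",
                x$slope, x$slopeCI[1], x$slopeCI[2], x$intercept, x$adjR2))
    if (!is.null(x$fTests)) {
        cat("  incremental F-tests:\n")
        for (i in seq_len(nrow(x$fTests)))
            cat(sprintf("    + %-11s F(%d,%d) = %.2f, p = %.3g\n",
                        x$fTests$added[i], x$fTests$df1[i], x$fTests$df2[i],
                        x$fTests$f[i], x$fTests$p[i]))
    }
    invisible(x)
}
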