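#' @describeIn FitnessLandscape-accessors matrix of mean competitive indices
#' @export
wMean <- function(x) SummarizedExperiment::assay(x, "w_mean")

#' @describeIn FitnessLandscape-accessors matrix of standard errors (NA where n = 1)
#' @export
wSE <- function(x) SummarizedExperiment::assay(x, "w_se")

#' @describeIn FitnessLandscape-accessors matrix of replicate counts
#' @export
nReps <- function(x) SummarizedExperiment::assay(x, "n")

#' Accessors for FitnessLandscape objects
#'
#' @param x a \linkS4class{FitnessLandscape}
#' @name FitnessLandscape-accessors
NULL

#' @describeIn FitnessLandscape-accessors resistance-locus allele per row
#' @export
abrAlleles <- function(x) SummarizedExperiment::rowData(x)$abrAllele

#' @describeIn FitnessLandscape-accessors knock-out-locus allele per row
#' @export
koAlleles <- function(x) SummarizedExperiment::rowData(x)$koAllele

#' @describeIn FitnessLandscape-accessors environment grid as a data.frame
#'   (antibiotic, temperature), one row per column of the object
#' @export
environments <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    data.frame(antibiotic = cd$antibiotic, temperature = cd$temperature,
               row.names = rownames(cd))
}

abrWildType <- function(x) S4Vectors::metadata(x)$abrWildType
koWildType <- function(x) S4Vectors::metadata(x)$koWildType

# Standard errors usable by the bootstrap: cells with n = 1 have no sample SD,
# so they borrow the median SE of the other cells in the same environment.
# The returned "imputed" matrix flags them.
usableSE <- function(x) {
    se <- wSE(x)
    imputed <- is.na(se)
    if (any(imputed)) {
        for (j in seq_len(ncol(se))) {
            if (!any(imputed[, j])) next
            med <- median(se[, j], na.rm = TRUE)
            if (is.na(med))
                epiStop("epiScape_data_error",
                        "environment %s has no replicated cell to borrow an SE from",
                        colnames(se)[j])
            se[imputed[, j], j] <- med
        }
    }
    if (any(se < 0)) epiStop("epiScape_data_error", "negative standard error")
    list(se = se, imputed = imputed)
}

setMethod("show", "FitnessLandscape", function(object) {
    cat(sprintf("FitnessLandscape: %d genotypes x %d environments\n",
                nrow(object), ncol(object)))
    cat(sprintf("  ABR alleles: %s\n",
                paste(unique(abrAlleles(object)), collapse = ", ")))
    cat(sprintf("  KO alleles:  %s\n",
                paste(unique(koAlleles(object)), collapse = ", ")))
    ev <- environments(object)
    cat(sprintf("  antibiotic (ug/ml): %s; temperature (C): %s\n",
                paste(sort(unique(ev$antibiotic)), collapse = ", "),
                paste(sort(unique(ev$temperature)), collapse = ", ")))
    n <- nReps(object)
    cat(sprintf("  replicates per cell: %d-%d; %d single-replicate cells\n",
                min(n), max(n), sum(n == 1L)))
    invisible(NULL)
})

setMethod("show", "LandscapeSlice", function(object) {
    cat(sprintf("LandscapeSlice %s x %s @ %g ug/ml, %g C\n",
                object@abrAllele, object@koAllele,
                object@antibiotic, object@temperature))
    m <- rbind(w = object@w, se = object@se, n = object@n)
    print(round(m, 4))
    invisible(NULL)
})

setMethod("show", "TruthParams", function(object) {
    cat(sprintf("TruthParams: %d x %d genotypes, %d x %d environments\n",
                length(object@abrAlleles), length(object@koAlleles),
                length(object@antibiotics), length(object@temperatures)))
    cat(sprintf("  reference %s; noise SD %g; replicates %s; seed %d\n",
                object@refAllele, object@noiseSD,
                paste(range(object@replicates), collapse = "-"), object@seed))
    nz <- if (nrow(object@interaction)) sum(object@interaction$i != 0) else 0L
    cat(sprintf("  %d non-zero interaction terms\n", nz))
    invisible(NULL)
})

#' Write fitness estimates to CSV
#'
#' One row per genotype-by-environment cell with columns \code{abr_allele},
#' \code{ko_allele}, \code{antibiotic}, \code{temperature}, \code{w_mean},
#' \code{w_se}, \code{n}.
#'
#' @param x a \linkS4class{FitnessLandscape}
#' @param path output file path
#' @return the written data.frame, invisibly.
#' @export
writeFitnessCSV <- function(x, path) {
    df <- fitnessTable(x)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(df)
}

#' @describeIn writeFitnessCSV the same table as a data.frame, without writing
#' @export
fitnessTable <- function(x) {
    ev <- environments(x)
    df <- expand.grid(row = seq_len(nrow(x)), col = seq_len(ncol(x)))
    data.frame(abr_allele = abrAlleles(x)[df$row],
               ko_allele = koAlleles(x)[df$row],
               antibiotic = ev$antibiotic[df$col],
               temperature = ev$temperature[df$col],
               w_mean = wMean(x)[cbind(df$row, df$col)],
               w_se = wSE(x)[cbind(df$row, df$col)],
               n = nReps(x)[cbind(df$row, df$col)])
}
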