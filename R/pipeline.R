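#' Read competition records from CSV
#'
#' Reads the long-format competition CSV (schema in
#' \link{competition-records}) and validates it.
#'
#' @param path CSV file path (UTF-8, header required, decimal point '.')
#' @return validated data.frame of competition records
#' @export
readCompetitionRecords <- function(path) {
    if (!file.exists(path))
        epiStop("epiScape_io_error", "cannot read '%s'", path)
    rec <- read.csv(path, stringsAsFactors = FALSE)
    checkRecords(rec)
    rec
}

#' Validate a competition-record CSV
#'
#' Checks header and column types, density positivity, duplicate replicate
#' keys, and genotype-by-environment grid completeness. Problems are split
#' into errors (schema violations, non-positive densities, duplicates) and
#' warnings (incomplete grid relative to the full allele cross).
#'
#' @param path CSV file path, or a data.frame of records
#' @return object of class \code{validationReport}: list with \code{errors},
#'   \code{warnings} (character vectors), \code{nRecords}, and logical
#'   \code{ok} (no errors).
#' @export
validateInput <- function(path) {
    errors <- character(); warnings <- character()
    rec <- NULL
    if (is.data.frame(path)) {
        rec <- path
    } else if (!file.exists(path)) {
        epiStop("epiScape_io_error", "cannot read '%s'", path)
    } else {
        rec <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                        error = function(e)
                            epiStop("epiScape_io_error", "cannot parse '%s': %s",
                                    path, conditionMessage(e)))
    }
    miss <- setdiff(recordColumns, names(rec))
    if (length(miss))
        errors <- c(errors, sprintf("missing columns: %s",
                                    paste(miss, collapse = ", ")))
    if (!length(errors)) {
        for (col in densityColumns) {
            v <- suppressWarnings(as.numeric(rec[[col]]))
            bad <- which(!is.finite(v) | v <= 0)
            if (length(bad))
                errors <- c(errors, sprintf(
                    "column '%s': non-positive or non-numeric density in rows %s",
                    col, paste(head(bad, 10), collapse = ", ")))
        }
        bad <- which(!rec$orientation %in% orientationLevels)
        if (length(bad))
            errors <- c(errors, sprintf("invalid orientation in rows %s",
                                        paste(head(bad, 10), collapse = ", ")))
        key <- paste(rec$abr_allele, rec$ko_allele, rec$antibiotic,
                     rec$temperature, rec$replicate, rec$orientation)
        dup <- which(duplicated(key))
        if (length(dup))
            errors <- c(errors, sprintf(
                "duplicated (genotype, environment, replicate, orientation) keys: %s",
                paste(head(unique(key[dup]), 5), collapse = "; ")))
        full <- expand.grid(abr = unique(rec$abr_allele),
                            ko = unique(rec$ko_allele),
                            env = unique(paste(rec$antibiotic,
                                               rec$temperature)),
                            KEEP.OUT.ATTRS = FALSE)
        present <- unique(paste(rec$abr_allele, rec$ko_allele,
                                rec$antibiotic, rec$temperature))
        missing <- setdiff(paste(full$abr, full$ko, full$env), present)
        if (length(missing))
            warnings <- c(warnings, sprintf(
                "incomplete genotype x environment grid: %d missing cells (%s%s)",
                length(missing), paste(head(missing, 5), collapse = "; "),
                if (length(missing) > 5) "; ..." else ""))
    }
    structure(class = "validationReport",
              list(errors = errors, warnings = warnings,
                   nRecords = if (is.null(rec)) 0L else nrow(rec),
                   ok = length(errors) == 0L))
}

#' @export
print.validationReport <- function(x, ...) {
    cat(sprintf("Validation of %d records: %s\n", x$nRecords,
                if (x$ok) "OK" else "FAILED"))
    for (e in x$errors) cat("  error:", e, "\n")
    for (w in x$warnings) cat("  warning:", w, "\n")
    invisible(x)
}

#' Default pipeline configuration
#'
#' Every setting has a default; \code{runPipeline} echoes the effective
#' configuration into the output directory.
#'
#' @param input path to the competition-record CSV (NULL to simulate)
#' @param outputDir directory for the CSV artifacts
#' @param scenarioName scenario simulated when no input is given
#' @param seed integer seed for simulation and bootstrap
#' @param bootstrapSamples number of parametric-bootstrap samples
#' @param alpha significance level for trend and model tests
#' @param qualityMetric environmental-quality variant (see
#'   [environmentalQuality()])
#' @param abCoding antibiotic coding in the model suite
#' @param poolOrientations pool dye orientations after the neutrality check
#' @return named list of settings.
#' @export
pipelineConfig <- function(input = NULL, outputDir = "episcape-out",
                           scenarioName = "paper_like", seed = 1L,
                           bootstrapSamples = 1000L, alpha = 0.01,
                           qualityMetric = "competitor",
                           abCoding = "factor", poolOrientations = TRUE) {
    list(input = input, outputDir = outputDir, scenarioName = scenarioName,
         seed = as.integer(seed),
         bootstrapSamples = as.integer(bootstrapSamples), alpha = alpha,
         qualityMetric = qualityMetric, abCoding = abCoding,
         poolOrientations = poolOrientations)
}

writeNum <- function(df, path) {
    write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes fitness estimation, dye-swap check, landscape slicing, the five
#' epistasis metrics with bootstrap CIs, environment-trend regressions,
#' environmental quality, cost-of-resistance contrasts, and the nested
#' interaction-model suite; writes every stage as a CSV artifact plus a run
#' log into \code{config$outputDir}. With no input file, a scenario is
#' simulated first and the truth tables are written alongside.
#'
#' @param config list from [pipelineConfig()]
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
runPipeline <- function(config = pipelineConfig()) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    logLines <- c(sprintf("epiScape %s",
                          as.character(utils::packageVersion("epiScape"))),
                  sprintf("seed %d", config$seed),
                  sprintf("config %s", paste(
                      vapply(config, function(v)
                          paste(format(v), collapse = ","), character(1)),
                      collapse = " | ")))
    truth <- NULL
    if (is.null(config$input)) {
        params <- scenario(config$scenarioName, seed = config$seed)
        sim <- simulateCompetitions(params)
        records <- sim$records
        truth <- sim$truth
        writeNum(records, file.path(config$outputDir, "records.csv"))
        writeNum(truth$fitness, file.path(config$outputDir, "truth.csv"))
        writeNum(truth$epsilon,
                 file.path(config$outputDir, "truth_epsilon.csv"))
        logLines <- c(logLines, sprintf("simulated scenario '%s'",
                                        config$scenarioName))
    } else {
        report <- validateInput(config$input)
        if (!report$ok)
            epiStop("epiScape_schema_error", "input validation failed:\n%s",
                    paste(report$errors, collapse = "\n"))
        records <- readCompetitionRecords(config$input)
    }

    dye <- tryCatch(dyeSwapCheck(records),
                    epiScape_data_error = function(e) NULL)
    fl <- summarizeFitness(records,
                           poolOrientations = config$poolOrientations)
    writeFitnessCSV(fl, file.path(config$outputDir, "fitness_estimates.csv"))

    boot <- bootParam(nSamples = config$bootstrapSamples,
                      seed = config$seed)
    summ <- epistasisSummary(fl, boot)
    writeNum(summ, file.path(config$outputDir, "epistasis_summary.csv"))
    slices <- sliceMetrics(fl, boot)
    writeNum(slices[c("abr_allele", "ko_allele", "antibiotic", "temperature",
                      "pairwise", "pairwise_lo", "pairwise_hi")],
             file.path(config$outputDir, "pairwise_epistasis.csv"))
    writeNum(slices[c("abr_allele", "ko_allele", "antibiotic", "temperature",
                      "rs_ratio", "rs_ratio_lo", "rs_ratio_hi")],
             file.path(config$outputDir, "rs_ratio.csv"))

    quality <- environmentalQuality(records, config$qualityMetric)
    writeNum(quality, file.path(config$outputDir, "quality.csv"))

    dimRet <- rbind(cbind(class = "ABR",
                          diminishingReturns(fl, "ABR", boot)),
                    cbind(class = "KO",
                          diminishingReturns(fl, "KO", boot)))
    writeNum(dimRet, file.path(config$outputDir, "diminishing_returns.csv"))

    trendOf <- function(col, predictor, qual = NULL) {
        tf <- trendVsEnvironment(
            data.frame(antibiotic = summ$antibiotic,
                       temperature = summ$temperature, value = summ[[col]]),
            predictor, quality = qual)
        data.frame(metric = col, predictor = predictor, slope = tf$slope,
                   f = tf$f, df1 = tf$df1, df2 = tf$df2, p = tf$p,
                   adj_r2 = tf$adjR2)
    }
    trends <- rbind(
        trendOf("gamma_all", "antibiotic"),
        trendOf("frac_reciprocal", "antibiotic"),
        trendOf("frac_simple", "antibiotic"),
        trendOf("rs_mean", "antibiotic"),
        trendOf("gamma_all", "quality", quality),
        trendOf("rs_mean", "quality", quality))
    writeNum(trends, file.path(config$outputDir, "trends.csv"))

    cost <- if (any(environments(fl)$antibiotic == 0))
        costOfResistance(fl, boot) else NULL
    if (!is.null(cost))
        writeNum(cost, file.path(config$outputDir, "cost_of_resistance.csv"))

    suite <- modelSuite(replicateIndices(records),
                        abCoding = config$abCoding)
    coefTabs <- do.call(rbind, lapply(names(suite$fits), function(nm)
        cbind(model = nm, suite$fits[[nm]]$coefficients)))
    writeNum(coefTabs, file.path(config$outputDir, "model_fits.csv"))
    cmp <- do.call(rbind, lapply(names(suite$comparisons), function(nm) {
        cc <- suite$comparisons[[nm]]
        data.frame(pair = nm, f = cc$f, df1 = cc$df1, df2 = cc$df2, p = cc$p)
    }))
    writeNum(cmp, file.path(config$outputDir, "model_comparisons.csv"))

    logLines <- c(logLines,
                  sprintf("%d records, %d genotypes, %d environments",
                          nrow(records), nrow(fl), ncol(fl)),
                  if (!is.null(dye))
                      sprintf("dye-swap slope %.3f adjR2 %.3f",
                              dye$slope, dye$adjR2),
                  sprintf("model adjR2: %s",
                          paste(sprintf("%.3f", suite$adjR2), collapse = " ")))
    writeLines(logLines, file.path(config$outputDir, "run.log"))

    invisible(list(records = records, truth = truth, fitness = fl,
                   dyeSwap = dye, epistasis = summ, slices = slices,
                   quality = quality, diminishingReturns = dimRet,
                   trends = trends, costOfResistance = cost,
                   models = suite, config = config))
}
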