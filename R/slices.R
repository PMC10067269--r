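#' Extract one two-locus landscape slice
#'
#' Pulls the four-genotype diamond \{(WT, none), (abr, none), (WT, ko),
#' (abr, ko)\} for one resistance allele, one knock-out allele and one
#' environment out of a fitness table.
#'
#' @param x a \linkS4class{FitnessLandscape}
#' @param abr resistance allele label (not the wild type)
#' @param ko knock-out allele label (not "none")
#' @param antibiotic,temperature environment coordinates
#' @return a \linkS4class{LandscapeSlice}
#' @export
landscapeSlice <- function(x, abr, ko, antibiotic, temperature) {
    eid <- which(environments(x)$antibiotic == antibiotic &
                 environments(x)$temperature == temperature)
    if (length(eid) != 1L)
        epiStop("epiScape_grid_error", "environment (%g, %g) not in the table",
                antibiotic, temperature)
    wtA <- abrWildType(x); wtK <- koWildType(x)
    corners <- rbind(c(wtA, wtK), c(abr, wtK), c(wtA, ko), c(abr, ko))
    rows <- match(genotypeId(corners[, 1], corners[, 2]),
                  genotypeId(abrAlleles(x), koAlleles(x)))
    if (anyNA(rows))
        epiStop("epiScape_grid_error", "missing genotype cell(s): %s",
                paste(genotypeId(corners[is.na(rows), 1],
                                 corners[is.na(rows), 2]), collapse = ", "))
    if (anyDuplicated(rows))
        epiStop("epiScape_grid_error",
                "slice genotypes are not pairwise distinct (abr = %s, ko = %s)",
                abr, ko)
    nm <- c("wt", "abr", "ko", "double")
    methods::new("LandscapeSlice",
        abrAllele = abr, koAllele = ko,
        antibiotic = antibiotic, temperature = temperature,
        w = setNames(wMean(x)[cbind(rows, eid)], nm),
        se = setNames(wSE(x)[cbind(rows, eid)], nm),
        n = setNames(nReps(x)[cbind(rows, eid)], nm))
}

#' All two-locus landscape slices of a fitness table
#'
#' One slice per (resistance allele != WT) x (knock-out allele != none) x
#' environment; for the default study design that is 3 x 5 x 12 = 180 slices,
#' 15 per environment, each containing the wild type.
#'
#' @param x a \linkS4class{FitnessLandscape} covering the complete grid
#' @return list of \linkS4class{LandscapeSlice} objects
#' @export
allSlices <- function(x) {
    abrs <- setdiff(unique(abrAlleles(x)), abrWildType(x))
    kos <- setdiff(unique(koAlleles(x)), koWildType(x))
    ev <- environments(x)
    missing <- character()
    out <- vector("list", length(abrs) * length(kos) * nrow(ev))
    k <- 0L
    for (j in seq_len(nrow(ev))) for (a in abrs) for (b in kos) {
        k <- k + 1L
        out[[k]] <- tryCatch(
            landscapeSlice(x, a, b, ev$antibiotic[j], ev$temperature[j]),
            epiScape_grid_error = function(e) {
                missing <<- c(missing, conditionMessage(e)); NULL
            })
    }
    if (length(missing))
        epiStop("epiScape_grid_error",
                "incomplete genotype x environment grid: %d slices unavailable\n%s",
                length(missing), paste(unique(missing), collapse = "\n"))
    out
}

# Row indices of each slice's four corners, vectorized form used by the
# bootstrap machinery: one matrix row per (abr, ko) pair, columns wt/abr/ko/double.
sliceIndexMatrix <- function(x) {
    abrs <- setdiff(unique(abrAlleles(x)), abrWildType(x))
    kos <- setdiff(unique(koAlleles(x)), koWildType(x))
    gids <- genotypeId(abrAlleles(x), koAlleles(x))
    pairs <- expand.grid(abr = abrs, ko = kos, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
    idx <- cbind(
        wt = match(genotypeId(abrWildType(x), koWildType(x)), gids),
        abr = match(genotypeId(pairs$abr, koWildType(x)), gids),
        ko = match(genotypeId(abrWildType(x), pairs$ko), gids),
        double = match(genotypeId(pairs$abr, pairs$ko), gids))
    if (anyNA(idx))
        epiStop("epiScape_grid_error", "incomplete genotype grid")
    list(pairs = pairs, idx = idx)
}
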