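#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData "assay<-"
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats anova coef complete.cases cor lm lm.fit median model.matrix
#'   pf pt quantile rnorm sd setNames as.formula
#' @importFrom utils read.csv write.csv head
NULL

#' FitnessLandscape: genotype-by-environment competitive fitness estimates
#'
#' An S4 container (extending
#' \linkS4class{SummarizedExperiment}) holding per-cell competitive-index
#' estimates for a two-locus genotype set assayed over an antibiotic
#' concentration by temperature environment grid. Rows are genotypes (an
#' antibiotic-resistance allele crossed with a gene knock-out allele), columns
#' are environments, and the assays are:
#' \describe{
#'   \item{\code{w_mean}}{mean competitive index (dimensionless log-ratio)}
#'   \item{\code{w_se}}{standard error of the mean; \code{NA} for cells with a
#'     single replicate}
#'   \item{\code{n}}{replicate count}
#' }
#' \code{rowData} carries \code{abrAllele} and \code{koAllele}; \code{colData}
#' carries \code{antibiotic} (ug/ml) and \code{temperature} (degrees C).
#' \code{metadata} records the wild-type labels of the two loci.
#'
#' @seealso [summarizeFitness()], [allSlices()], [epistasisSummary()]
#' @aliases FitnessLandscape
#' @exportClass FitnessLandscape
setClass("FitnessLandscape", contains = "SummarizedExperiment")

setValidity("FitnessLandscape", function(object) {
    msg <- character()
    need <- c("w_mean", "w_se", "n")
    if (!all(need %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, sprintf("assays must include %s",
                              paste(need, collapse = ", ")))
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("abrAllele", "koAllele") %in% colnames(rd)))
        msg <- c(msg, "rowData must have abrAllele and koAllele")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("antibiotic", "temperature") %in% colnames(cd)))
        msg <- c(msg, "colData must have antibiotic and temperature")
    else {
        if (any(cd$antibiotic < 0)) msg <- c(msg, "antibiotic must be >= 0")
        if (any(cd$temperature <= 0)) msg <- c(msg, "temperature must be > 0")
    }
    md <- S4Vectors::metadata(object)
    if (is.null(md$abrWildType) || is.null(md$koWildType))
        msg <- c(msg, "metadata must record abrWildType and koWildType")
    if ("n" %in% SummarizedExperiment::assayNames(object)) {
        n <- SummarizedExperiment::assay(object, "n")
        if (any(n < 1)) msg <- c(msg, "every cell needs n >= 1")
        se <- SummarizedExperiment::assay(object, "w_se")
        if (any(se[!is.na(se)] < 0)) msg <- c(msg, "w_se must be >= 0")
        if (any(!is.na(se[n < 2])))
            msg <- c(msg, "w_se must be NA (undefined) where n = 1")
    }
    if (length(msg)) msg else TRUE
})

#' LandscapeSlice: one two-locus fitness landscape
#'
#' The four-genotype diamond \{wild type, resistance single mutant, knock-out
#' single mutant, double mutant\} for one resistance allele, one knock-out
#' allele and one environment. Fitness values, their standard errors and
#' replicate counts are stored as length-4 vectors named
#' \code{c("wt", "abr", "ko", "double")}.
#'
#' @slot abrAllele resistance allele label of the slice
#' @slot koAllele knock-out allele label of the slice
#' @slot antibiotic antibiotic concentration (ug/ml)
#' @slot temperature temperature (degrees C)
#' @slot w named numeric(4), mean competitive indices
#' @slot se named numeric(4), standard errors (NA where n = 1)
#' @slot n named integer(4), replicate counts
#' @aliases LandscapeSlice
#' @exportClass LandscapeSlice
setClass("LandscapeSlice",
    representation(abrAllele = "character", koAllele = "character",
                   antibiotic = "numeric", temperature = "numeric",
                   w = "numeric", se = "numeric", n = "integer"))

setValidity("LandscapeSlice", function(object) {
    msg <- character()
    corners <- c("wt", "abr", "ko", "double")
    for (sl in c("w", "se", "n")) {
        v <- slot(object, sl)
        if (length(v) != 4L || !identical(names(v), corners))
            msg <- c(msg, sprintf("slot '%s' must be length 4 named %s",
                                  sl, paste(corners, collapse = "/")))
    }
    if (any(!is.finite(object@w)))
        msg <- c(msg, "all four fitness values must be finite")
    if (length(msg)) msg else TRUE
})

#' BootParam: parametric bootstrap configuration
#'
#' Settings for the parametric bootstrap used throughout the package: each
#' bootstrap sample redraws every genotype-by-environment cell independently
#' from Normal(w_mean, w_se). Streams are reproducible: the same seed and
#' inputs give identical samples.
#'
#' @slot nSamples number of bootstrap samples (default 1000)
#' @slot seed integer RNG seed
#' @slot ciLevel confidence level for percentile intervals (default 0.95)
#' @aliases BootParam-class
#' @export BootParam
#' @exportClass BootParam
BootParam <- setClass("BootParam",
    representation(nSamples = "integer", seed = "integer", ciLevel = "numeric"),
    prototype(nSamples = 1000L, seed = 1L, ciLevel = 0.95))

setValidity("BootParam", function(object) {
    msg <- character()
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
    if (object@ciLevel <= 0 || object@ciLevel >= 1)
        msg <- c(msg, "ciLevel must be in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' @rdname BootParam-class
#' @param nSamples number of bootstrap samples
#' @param seed integer RNG seed
#' @param ciLevel confidence level in (0, 1)
#' @return \code{bootParam} returns a \code{BootParam} object.
#' @export
bootParam <- function(nSamples = 1000L, seed = 1L, ciLevel = 0.95) {
    BootParam(nSamples = as.integer(nSamples), seed = as.integer(seed),
              ciLevel = as.numeric(ciLevel))
}

#' TruthParams: generative parameters for synthetic competition data
#'
#' Full specification of a synthetic study: allele sets, environment grid,
#' environment-dependent additive effects per allele, pairwise interaction
#' terms, reference-strain growth, measurement noise and design sizes. The
#' true competitive index of a genotype is the sum of its allele effects plus
#' its interaction term, measured relative to the reference genotype (whose
#' own true index is therefore exactly 0 in every environment).
#'
#' @slot abrAlleles resistance-locus allele labels; first element is wild type
#' @slot koAlleles knock-out-locus allele labels; first element means "none"
#' @slot refAllele resistance allele of the reference competitor strain
#' @slot antibiotics antibiotic concentrations of the grid (ug/ml)
#' @slot temperatures temperatures of the grid (degrees C)
#' @slot additive data.frame(locus, allele, antibiotic, temperature, a):
#'   additive log-fitness effect of each allele in each environment
#' @slot interaction data.frame(abr, ko, antibiotic, temperature, i): pairwise
#'   interaction terms; absent combinations are 0
#' @slot refLogGrowth data.frame(antibiotic, temperature, g): log growth
#'   factor of the reference strain over one competition cycle
#' @slot noiseSD lognormal measurement noise SD on each density channel
#' @slot inoculum initial density per channel (events per volume)
#' @slot replicates admissible replicate counts per cell (e.g. 3:4)
#' @slot dyeSwap emit both fluorophore orientations (alternating replicates)
#' @slot orientationBias systematic index shift for swapped-dye records
#'   (0 = neutral marker)
#' @slot seed integer RNG seed for simulation
#' @aliases TruthParams
#' @exportClass TruthParams
setClass("TruthParams",
    representation(abrAlleles = "character", koAlleles = "character",
                   refAllele = "character",
                   antibiotics = "numeric", temperatures = "numeric",
                   additive = "data.frame", interaction = "data.frame",
                   refLogGrowth = "data.frame",
                   noiseSD = "numeric", inoculum = "numeric",
                   replicates = "integer", dyeSwap = "logical",
                   orientationBias = "numeric", seed = "integer"))

setValidity("TruthParams", function(object) {
    msg <- character()
    if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
    if (object@inoculum <= 0) msg <- c(msg, "inoculum must be > 0")
    if (!object@refAllele %in% object@abrAlleles)
        msg <- c(msg, "refAllele must be one of abrAlleles")
    if (any(object@replicates < 1L)) msg <- c(msg, "replicates must be >= 1")
    grid <- expand.grid(antibiotic = object@antibiotics,
                        temperature = object@temperatures)
    for (locus in c("ABR", "KO")) {
        alleles <- if (locus == "ABR") object@abrAlleles else object@koAlleles
        add <- object@additive[object@additive$locus == locus, ]
        want <- nrow(grid) * length(alleles)
        have <- nrow(unique(add[c("allele", "antibiotic", "temperature")]))
        if (have < want)
            msg <- c(msg, sprintf(
                "additive effects incomplete for locus %s (%d of %d cells)",
                locus, have, want))
    }
    if (length(msg)) msg else TRUE
})
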