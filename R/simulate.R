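presetAbrAlleles <- c("WT", "S512F", "H526Y", "I572S")
presetKoAlleles <- c("none", "marR", "nuoC", "waaP", "yidK", "ybfG")
presetAntibiotics <- c(0, 4, 8, 10)
presetTemperatures <- c(37, 40, 42)

#' Construct generative parameters for a named scenario
#'
#' Returns a fully-populated \linkS4class{TruthParams} for the default study
#' design (4 resistance alleles x 6 knock-out states, 4 rifampicin
#' concentrations x 3 temperatures, 3-4 replicates, reference strain H526Y).
#' Scenarios differ in the true additive and interaction structure:
#' \describe{
#'   \item{additive}{environment-independent allele effects, no interactions;
#'     every landscape is exactly additive.}
#'   \item{gxe_only}{susceptible resistance alleles are strongly suppressed by
#'     antibiotic (strong gene-by-environment structure) but there are no
#'     gene-by-gene interactions.}
#'   \item{masking}{as gxe_only, plus resistance alleles rescue the
#'     antibiotic-hypersusceptible waaP knock-out (positive interaction
#'     growing with concentration).}
#'   \item{reciprocal_sign_at_zero_ab}{as gxe_only, plus strong negative
#'     interactions between the weak resistance allele I572S and three mildly
#'     beneficial knock-outs, present only without antibiotic: those slices
#'     show reciprocal sign epistasis at concentration 0 and none elsewhere.}
#'   \item{diminishing_returns}{interaction terms proportional to the
#'     knock-out background effect so that resistance-mutation effects decline
#'     linearly in background fitness with slope -0.4.}
#'   \item{paper_like}{gene-by-environment structure plus interactions that
#'     decay linearly with antibiotic concentration (vanishing above 8 ug/ml):
#'     reciprocal-sign pairs at concentration 0, waaP rescue under antibiotic.}
#' }
#'
#' @param name scenario name (see Details)
#' @param seed integer RNG seed carried into simulation
#' @param noiseSD lognormal measurement noise SD per density channel
#'   (default 0.05)
#' @param replicates admissible replicate counts per cell (default 3:4)
#' @param dyeSwap alternate fluorophore orientations across replicates
#' @param orientationBias systematic index shift for swapped-dye records
#' @return a \linkS4class{TruthParams}
#' @export
scenario <- function(name = c("additive", "gxe_only", "masking",
                              "reciprocal_sign_at_zero_ab",
                              "diminishing_returns", "paper_like"),
                     seed = 1L, noiseSD = 0.05, replicates = 3:4,
                     dyeSwap = TRUE, orientationBias = 0) {
    if (!is.character(name) || !name[1] %in% eval(formals(scenario)$name))
        epiStop("epiScape_schema_error",
                "unknown scenario '%s'; valid names: %s", name[1],
                paste(eval(formals(scenario)$name), collapse = ", "))
    name <- match.arg(name)
    grid <- expand.grid(antibiotic = presetAntibiotics,
                        temperature = presetTemperatures,
                        KEEP.OUT.ATTRS = FALSE)

    # additive allele effects (log scale, relative growth per cycle)
    aAbr <- function(allele, ab, temp) {
        base <- switch(allele, WT = 0, S512F = 0.5, H526Y = 0.4, I572S = 0.3)
        if (name == "additive" || name == "diminishing_returns") return(base)
        # antibiotic suppression of susceptible / weakly resistant alleles
        base + switch(allele,
            WT = -0.35 * ab + 0.02 * (temp - 37),
            I572S = -0.12 * ab,
            S512F = -0.01 * ab,
            H526Y = 0)
    }
    aKo <- function(allele, ab, temp) {
        base <- switch(allele, none = 0, marR = 0.2, nuoC = -0.3,
                       waaP = -0.5, yidK = -0.1, ybfG = 0.15)
        if (name == "additive" || name == "diminishing_returns")
            return(if (allele == "waaP") -0.9 else base)
        extra <- if (allele == "waaP") -0.05 * ab else 0
        base + extra + (allele != "none") * 0.01 * (temp - 37)
    }
    additive <- do.call(rbind, lapply(seq_len(nrow(grid)), function(j) {
        ab <- grid$antibiotic[j]; temp <- grid$temperature[j]
        rbind(
            data.frame(locus = "ABR", allele = presetAbrAlleles,
                       antibiotic = ab, temperature = temp,
                       a = vapply(presetAbrAlleles, aAbr, numeric(1), ab, temp)),
            data.frame(locus = "KO", allele = presetKoAlleles,
                       antibiotic = ab, temperature = temp,
                       a = vapply(presetKoAlleles, aKo, numeric(1), ab, temp)))
    }))
    rownames(additive) <- NULL

    # interaction structure per scenario
    inter <- additive[0, c("antibiotic", "temperature")]
    inter <- data.frame(abr = character(), ko = character(),
                        antibiotic = numeric(), temperature = numeric(),
                        i = numeric())
    addInter <- function(tab, abr, ko, ab, temp, i)
        rbind(tab, data.frame(abr = abr, ko = ko, antibiotic = ab,
                              temperature = temp, i = i))
    resist <- setdiff(presetAbrAlleles, "WT")
    # knock-outs with positive base effects: pairing them with the weak
    # resistance allele and a strong negative interaction flips both loci's
    # effect signs (true reciprocal sign epistasis)
    recipKos <- c("marR", "ybfG")
    for (j in seq_len(nrow(grid))) {
        ab <- grid$antibiotic[j]; temp <- grid$temperature[j]
        if (name == "masking" && ab > 0)
            inter <- addInter(inter, rep(resist, each = 1), "waaP", ab, temp,
                              pmin(0.05 * ab + 0.5, 1))
        if (name == "reciprocal_sign_at_zero_ab" && ab == 0)
            inter <- addInter(inter, "I572S", recipKos, ab, temp, -0.8)
        if (name == "diminishing_returns")
            for (m in resist)
                inter <- addInter(inter, m, presetKoAlleles, ab, temp,
                    -0.4 * vapply(presetKoAlleles, aKo, numeric(1), ab, temp))
        if (name == "paper_like") {
            decay <- max(0, 1 - ab / 8)
            if (decay > 0)
                inter <- addInter(inter, "I572S", recipKos, ab, temp,
                                  -0.8 * decay)
            if (ab > 0)
                inter <- addInter(inter, resist, "waaP", ab, temp,
                                  pmin(0.05 * ab, 0.5))
        }
    }

    refLogGrowth <- data.frame(grid,
        g = 1.8 - 0.03 * grid$antibiotic + 0.03 * (grid$temperature - 37))

    methods::new("TruthParams",
        abrAlleles = presetAbrAlleles, koAlleles = presetKoAlleles,
        refAllele = "H526Y",
        antibiotics = presetAntibiotics, temperatures = presetTemperatures,
        additive = additive, interaction = inter,
        refLogGrowth = refLogGrowth,
        noiseSD = noiseSD, inoculum = 500,
        replicates = as.integer(replicates), dyeSwap = dyeSwap,
        orientationBias = orientationBias, seed = as.integer(seed))
}

lookupAdditive <- function(params, locus, allele, ab, temp) {
    tab <- params@additive
    m <- match(paste(locus, allele, ab, temp),
               paste(tab$locus, tab$allele, tab$antibiotic, tab$temperature))
    if (anyNA(m))
        epiStop("epiScape_grid_error",
                "missing additive effect for %s allele '%s' at (%s, %s)",
                locus, allele[is.na(m)][1], ab, temp)
    tab$a[m]
}

lookupInteraction <- function(params, abr, ko, ab, temp) {
    tab <- params@interaction
    if (nrow(tab) == 0L) return(rep(0, length(abr)))
    m <- match(paste(abr, ko, ab, temp),
               paste(tab$abr, tab$ko, tab$antibiotic, tab$temperature))
    ifelse(is.na(m), 0, tab$i[m])
}

#' True competitive indices implied by generative parameters
#'
#' The true index of genotype g in environment e is the sum of its allele
#' effects and interaction term, minus the same sum for the reference
#' genotype; the reference's own index is exactly 0 everywhere.
#'
#' @param params a \linkS4class{TruthParams}
#' @return list with \code{fitness} (data.frame abr_allele, ko_allele,
#'   antibiotic, temperature, w_true) and \code{epsilon} (true pairwise
#'   epistasis per slice: abr_allele, ko_allele, antibiotic, temperature,
#'   epsilon_true).
#' @export
trueFitness <- function(params) {
    methods::validObject(params)
    geno <- expand.grid(abr_allele = params@abrAlleles,
                        ko_allele = params@koAlleles,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    grid <- expand.grid(antibiotic = params@antibiotics,
                        temperature = params@temperatures,
                        KEEP.OUT.ATTRS = FALSE)
    fitness <- do.call(rbind, lapply(seq_len(nrow(grid)), function(j) {
        ab <- grid$antibiotic[j]; temp <- grid$temperature[j]
        ref <- lookupAdditive(params, "ABR", params@refAllele, ab, temp) +
            lookupAdditive(params, "KO", params@koAlleles[1], ab, temp) +
            lookupInteraction(params, params@refAllele, params@koAlleles[1],
                              ab, temp)
        w <- lookupAdditive(params, "ABR", geno$abr_allele, ab, temp) +
            lookupAdditive(params, "KO", geno$ko_allele, ab, temp) +
            lookupInteraction(params, geno$abr_allele, geno$ko_allele,
                              ab, temp) - ref
        data.frame(geno, antibiotic = ab, temperature = temp, w_true = w)
    }))
    wtA <- params@abrAlleles[1]; wtK <- params@koAlleles[1]
    pairs <- expand.grid(abr_allele = setdiff(params@abrAlleles, wtA),
                         ko_allele = setdiff(params@koAlleles, wtK),
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    epsilon <- do.call(rbind, lapply(seq_len(nrow(grid)), function(j) {
        ab <- grid$antibiotic[j]; temp <- grid$temperature[j]
        eps <- lookupInteraction(params, pairs$abr_allele, pairs$ko_allele,
                                 ab, temp) -
            lookupInteraction(params, pairs$abr_allele, wtK, ab, temp) -
            lookupInteraction(params, wtA, pairs$ko_allele, ab, temp) +
            lookupInteraction(params, wtA, wtK, ab, temp)
        data.frame(pairs, antibiotic = ab, temperature = temp,
                   epsilon_true = eps)
    }))
    list(fitness = fitness, epsilon = epsilon)
}

#' Simulate competition-assay records from generative parameters
#'
#' Emits one record per genotype x environment x replicate. Initial densities
#' are the inoculum with multiplicative lognormal measurement noise per
#' channel; the final reference density grows by the environment's reference
#' growth factor, the final competitor density additionally by exp(true
#' index); each final channel carries its own lognormal noise. With
#' \code{dyeSwap} the fluorophore orientation alternates across replicates
#' (adding \code{orientationBias} to swapped records, 0 by default). With zero
#' noise the competitive index recovers the true index exactly.
#'
#' @param params a \linkS4class{TruthParams}
#' @param truth optional precomputed [trueFitness()] result
#' @return list with \code{records} (competition records, see
#'   \link{competition-records}) and \code{truth} (the [trueFitness()] tables).
#' @export
simulateCompetitions <- function(params, truth = trueFitness(params)) {
    fit <- truth$fitness
    g <- params@refLogGrowth
    gm <- match(paste(fit$antibiotic, fit$temperature),
                paste(g$antibiotic, g$temperature))
    records <- withSeed(params@seed, {
        reps <- params@replicates
        nrep <- if (length(reps) == 1L) rep(reps, nrow(fit))
                else sample(reps, nrow(fit), replace = TRUE)
        rows <- rep(seq_len(nrow(fit)), nrep)
        repIdx <- sequence(nrep)
        nRec <- length(rows)
        orient <- if (params@dyeSwap)
            orientationLevels[1L + repIdx %% 2L]
        else rep(orientationLevels[1], nRec)
        sdN <- params@noiseSD
        dci <- params@inoculum * exp(rnorm(nRec, 0, sdN))
        dri <- params@inoculum * exp(rnorm(nRec, 0, sdN))
        growth <- exp(g$g[gm][rows])
        bias <- ifelse(orient == orientationLevels[2],
                       params@orientationBias, 0)
        dcf <- dci * growth * exp(fit$w_true[rows] + bias) *
            exp(rnorm(nRec, 0, sdN))
        drf <- dri * growth * exp(rnorm(nRec, 0, sdN))
        data.frame(abr_allele = fit$abr_allele[rows],
                   ko_allele = fit$ko_allele[rows],
                   antibiotic = fit$antibiotic[rows],
                   temperature = fit$temperature[rows],
                   replicate = repIdx, orientation = orient,
                   d_comp_initial = dci, d_ref_initial = dri,
                   d_comp_final = dcf, d_ref_final = drf)
    })
    list(records = records, truth = truth, params = params)
}
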