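# Fixture builders shared across the suite. Everything is generated in code;
# no files are read.

# Competition records whose competitive index is exactly `w` (no noise):
# equal inocula, reference growth factor `growth`, competitor growth
# growth * exp(w).
recordsFromW <- function(df, growth = 4, inoculum = 500,
                         orientation = "competitor-GFP") {
    stopifnot(all(c("abr", "ko", "antibiotic", "temperature", "replicate",
                    "w") %in% names(df)))
    data.frame(abr_allele = df$abr, ko_allele = df$ko,
               antibiotic = df$antibiotic, temperature = df$temperature,
               replicate = df$replicate,
               orientation = if (is.null(df$orientation)) orientation
                             else df$orientation,
               d_comp_initial = inoculum, d_ref_initial = inoculum,
               d_comp_final = inoculum * growth * exp(df$w),
               d_ref_final = inoculum * growth)
}

# Build a FitnessLandscape directly from per-cell summaries.
flFromW <- function(df, abrWildType = "WT", koWildType = "none") {
    if (is.null(df$se)) df$se <- 0
    if (is.null(df$n)) df$n <- 3L
    gids <- unique(data.frame(abr = df$abr, ko = df$ko))
    eids <- unique(data.frame(antibiotic = df$antibiotic,
                              temperature = df$temperature))
    gl <- paste(gids$abr, gids$ko, sep = "|")
    el <- paste0(eids$antibiotic, "ug|", eids$temperature, "C")
    idx <- cbind(match(paste(df$abr, df$ko, sep = "|"), gl),
                 match(paste0(df$antibiotic, "ug|", df$temperature, "C"), el))
    mk <- function(v, default) {
        m <- matrix(default, nrow(gids), nrow(eids),
                    dimnames = list(gl, el))
        m[idx] <- v
        m
    }
    se <- mk(df$se, NA_real_)
    n <- mk(as.integer(df$n), NA_integer_)
    se[n < 2L] <- NA_real_
    methods::new("FitnessLandscape",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(w_mean = mk(df$w, NA_real_), w_se = se, n = n),
            rowData = S4Vectors::DataFrame(abrAllele = gids$abr,
                                           koAllele = gids$ko,
                                           row.names = gl),
            colData = S4Vectors::DataFrame(antibiotic = eids$antibiotic,
                                           temperature = eids$temperature,
                                           row.names = el),
            metadata = list(abrWildType = abrWildType,
                            koWildType = koWildType,
                            reference = NA_character_,
                            pooledOrientations = TRUE)))
}

sliceFromW <- function(wt, abr, ko, dbl, se = 0, n = 3L) {
    nm <- c("wt", "abr", "ko", "double")
    sev <- rep_len(se, 4)
    nv <- rep_len(as.integer(n), 4)
    sev[nv < 2L] <- NA_real_
    methods::new("LandscapeSlice", abrAllele = "A", koAllele = "B",
                 antibiotic = 0, temperature = 37,
                 w = setNames(c(wt, abr, ko, dbl), nm),
                 se = setNames(sev, nm), n = setNames(nv, nm))
}

# full-factorial record set for the default design with additive truth
additiveGridRecords <- function(nrep = 4L,
                                abrs = c("WT", "S512F", "H526Y", "I572S"),
                                kos = c("none", "marR", "nuoC", "waaP",
                                        "yidK", "ybfG"),
                                abx = c(0, 4, 8, 10), temps = c(37, 40, 42)) {
    aAbr <- setNames(seq_along(abrs) / 10, abrs)
    aKo <- setNames(-seq_along(kos) / 20, kos)
    df <- expand.grid(abr = abrs, ko = kos, antibiotic = abx,
                      temperature = temps, replicate = seq_len(nrep),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    df$w <- aAbr[df$abr] + aKo[df$ko]
    recordsFromW(df)
}
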