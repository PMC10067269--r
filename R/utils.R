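# Condition helpers: every user-facing failure is a classed condition so the
# pipeline layer can map it to an exit code.

epiStop <- function(class, fmt, ..., data = NULL) {
    cond <- structure(
        class = c(class, "epiScape_error", "error", "condition"),
        list(message = sprintf(fmt, ...), call = sys.call(-1), data = data))
    stop(cond)
}

# Evaluate `expr` with a private RNG stream: the caller's .Random.seed is
# untouched and the same seed always yields the same draws.
withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    expr
}

genotypeId <- function(abr, ko) paste(abr, ko, sep = "|")
environmentId <- function(antibiotic, temperature)
    paste0(format(antibiotic, trim = TRUE), "ug|",
           format(temperature, trim = TRUE), "C")

#' @keywords internal
"_PACKAGE"
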