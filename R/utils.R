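# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. `seed = NULL` leaves the RNG stream untouched.
withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) {
            assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    })
    set.seed(seed)
    force(code)
}

# Derive `n` independent sub-seeds from a master seed (kept < 2^31).
deriveSeeds <- function(seed, n) {
    withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

# Full-precision numeric formatting for lossless CSV round-trips.
fmtNum <- function(x) {
    out <- vapply(x, function(v) {
        if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }, character(1))
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
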