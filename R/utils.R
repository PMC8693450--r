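# Internal helpers: seeded evaluation, substream derivation, hashing.

.dysbCache <- new.env(parent = emptyenv())

# Evaluate expr under a fixed seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_old) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# One global seed, named substreams: changing one stage's draws cannot shift
# another's. Result is a deterministic integer-valued double < 2^31 - 1.
substreamSeed <- function(seed, stream) {
    codes <- utf8ToInt(stream)
    h <- 0
    for (k in codes) h <- (h * 131 + k) %% 2147483647
    ((as.double(seed) %% 2147483647) * 48271 + h) %% 2147483647
}

# md5 of an in-memory character payload (via a temp file; tools::md5sum is
# file-based).
md5Of <- function(txt) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(txt, tf)
    unname(tools::md5sum(tf))
}

stopIfNotNumericVector <- function(x, name) {
    if (!is.numeric(x) || length(x) == 0L)
        stop(name, " must be a non-empty numeric vector")
    if (anyNA(x) || any(!is.finite(x)))
        stop(name, " contains NA or non-finite values")
    invisible(TRUE)
}
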