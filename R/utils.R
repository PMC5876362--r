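# Seed plumbing: every stochastic operation evaluates under a local RNG
# state so that (a) results are a pure function of the seed argument and
# (b) the caller's RNG stream is left untouched.

withLocalSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# Deterministically combine a master seed with labels (fold index, category
# name, ...) into a derived 31-bit seed.
deriveSeed <- function(seed, ...) {
    parts <- unlist(lapply(list(...), function(p) {
        if (is.character(p)) vapply(p, function(s) {
            cp <- utf8ToInt(s)
            sum(cp * seq_along(cp)) %% 2147483647
        }, numeric(1)) else as.numeric(p)
    }), use.names = FALSE)
    s <- as.numeric(seed) %% 2147483647
    for (p in c(parts, 97)) s <- (s * 69069 + p + 1) %% 2147483647
    as.integer(s)
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# radial-basis kernel matrix between row sets
rbfKernel <- function(x, z, gamma) {
    x <- as.matrix(x); z <- as.matrix(z)
    d2 <- outer(rowSums(x^2), rowSums(z^2), "+") - 2 * tcrossprod(x, z)
    d2[d2 < 0] <- 0
    exp(-gamma * d2)
}
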