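# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed so generator calls compose deterministically.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("seed must be a single number")
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Symmetric-by-construction Dirichlet draw with concentration vector alpha.
rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) <= 0) g <- rep(1, length(alpha))
    g / sum(g)
}

# Hamming distance between equal-length strings a (scalar) and b (vector).
hammingTo <- function(a, b) {
    ar <- charToRaw(a)
    vapply(b, function(x) sum(charToRaw(x) != ar), integer(1L),
           USE.NAMES = FALSE)
}

# Character matrix (width x n) of equal-length strings, built once for
# repeated mismatch queries.
charMatrix <- function(seqs, width) {
    matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
           nrow = width)
}

# Mismatch count of one query string against every column of a charMatrix.
mismatchToAll <- function(query, mat) {
    q <- strsplit(query, "", fixed = TRUE)[[1L]]
    colSums(mat != q)
}

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
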