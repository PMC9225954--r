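# Seed plumbing: every stochastic stage takes an explicit seed; helpers
# below keep the global RNG state untouched and derive per-stage /
# per-subject seeds deterministically from a root seed.

#' Evaluate an expression under a local RNG seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so package functions never perturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' Derive a stage seed from a root seed
#'
#' Deterministic 31-bit seed derived from a root seed and a stage name,
#' so that independent pipeline stages use decorrelated but reproducible
#' random streams.
#'
#' @param rootSeed integer root seed.
#' @param stage character stage name.
#' @return Integer seed in [1, 2^31 - 2].
#' @export
deriveSeed <- function(rootSeed, stage) {
    m <- 2147483647  # 2^31 - 1, prime
    h <- 0
    for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
    s <- (as.numeric(rootSeed) %% m + h) %% m
    as.integer(if (s < 1) s + 1 else s)
}

#' Derive independent subject seeds
#'
#' @param rootSeed integer root seed.
#' @param n number of simulated subjects.
#' @return Integer vector of \code{n} distinct seeds.
#' @export
subjectSeeds <- function(rootSeed, n) {
    withSeed(deriveSeed(rootSeed, "subjects"),
             sample.int(2147483646L, n))
}

# Gaussian temporal bump; width is full width at half maximum in ms.
.bump <- function(timeMs, latencyMs, widthMs) {
    exp(-4 * log(2) * (timeMs - latencyMs)^2 / widthMs^2)
}

# Random unit-norm pattern vectors (rows)
.unitRows <- function(n, p) {
    m <- matrix(stats::rnorm(n * p), n, p)
    m / sqrt(rowSums(m^2))
}

.assertChoice <- function(x, choices, what) {
    if (!x %in% choices)
        stop("'", what, "' must be one of: ", paste(choices, collapse = ", "))
    x
}
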