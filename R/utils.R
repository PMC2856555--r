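# internal helpers

# run expr with a local RNG state; restores the caller's .Random.seed
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# deterministic argmin with ties resolved to the first (smallest) candidate;
# candidates assumed sorted in preference order
.argmin <- function(values) which(values == min(values))[1L]

`%||%` <- function(a, b) if (is.null(a)) b else a
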