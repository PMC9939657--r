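# Counter-based seed substreams: derive a 31-bit seed from a root seed and
# any number of integer counters, so each draw has its own RNG stream and
# output is independent of rejection/iteration history elsewhere.
.subSeed <- function(...) {
    ks <- c(...)
    x <- 2026
    for (k in ks) {
        # modular LCG-style mixing kept in double precision (< 2^53 throughout)
        x <- (x * 69069 + (k %% 2147483647) + 1) %% 2147483647
        x <- (x * 48271) %% 2147483647
    }
    as.integer(x)
}

# Evaluate `expr` with a temporary RNG state seeded by `seed`, restoring
# the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

.stopWithClass <- function(class, fmt, ...) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
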