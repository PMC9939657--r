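test_that("the physiological constraint check evaluates the four extreme rates", {
    base <- theta(demoParams())
    mk <- function(...) {
        th <- base
        repl <- list(...)
        th[names(repl)] <- unlist(repl)
        channelParams(theta = th)
    }
    # term value 1 lies inside (0.0167, 1e6): inequality passes
    expect_true(checkConstraints(mk(p1 = 1, p2 = 1e-4)))
    # term value 0.01 < 0.0167: fails
    expect_false(checkConstraints(mk(p1 = 0.01, p2 = 1e-4)))
    # 10 * e^24 >> 1e6: fails
    expect_false(checkConstraints(mk(p1 = 10, p2 = 400)))
    terms <- constraintTerms(mk(p1 = 10, p2 = 400))
    expect_equal(terms[["k1_at_Vmax"]], 10 * exp(24), tolerance = 1e-12)
})

test_that("sampled parameters satisfy the prior box and the constraints", {
    spec <- priorSpec()
    draws <- sampleParams(spec, n = 500, seed = 7)
    m <- t(vapply(draws, theta, numeric(9)))
    expect_true(all(m[, 1] >= 100 & m[, 1] <= 5e5))
    expect_true(all(m[, c(2, 4, 6, 8)] >= 1e-4 & m[, c(2, 4, 6, 8)] <= 1e6))
    expect_true(all(m[, c(3, 5, 7, 9)] >= 1e-4 & m[, c(3, 5, 7, 9)] <= 400))
    expect_true(all(vapply(draws, checkConstraints, logical(1), spec = spec)))
})

test_that("sampling is deterministic and per-draw seeded", {
    a <- sampleParams(n = 10, seed = 42)
    b <- sampleParams(n = 10, seed = 42)
    expect_identical(lapply(a, theta), lapply(b, theta))
    # draw i does not depend on how many draws were requested
    c5 <- sampleParams(n = 5, seed = 42)
    expect_identical(theta(c5[[3]]), theta(a[[3]]))
    d <- sampleParams(n = 10, seed = 43)
    expect_false(identical(theta(a[[1]]), theta(d[[1]])))
})

test_that("marginals are uniform when the rate constraints never bind", {
    # bounds chosen so every candidate satisfies the constraint window:
    # prefactors in [1, 100], sensitivities in [1e-4, 50] give extreme
    # rates inside (1, 4.1e4) subset of (0.0167, 1e6)
    spec <- priorSpec(prefactorBounds = c(1, 100),
                      sensitivityBounds = c(1e-4, 50))
    m <- t(vapply(sampleParams(spec, n = 2000, seed = 9), theta, numeric(9)))
    for (j in c(3, 5, 7, 9))   # sensitivities: uniform on the raw scale
        expect_gt(stats::ks.test(m[, j], "punif", 1e-4, 50)$p.value, 0.01)
    for (j in c(2, 4, 6, 8))   # prefactors: uniform on the log10 scale
        expect_gt(stats::ks.test(log10(m[, j]), "punif", 0, 2)$p.value, 0.01)
})

test_that("accepted prefactors are spread on the log scale but clustered raw", {
    m <- t(vapply(sampleParams(n = 3000, seed = 11), theta, numeric(9)))
    entropy <- function(x, breaks) {
        h <- hist(x, breaks = breaks, plot = FALSE)$counts
        p <- h[h > 0] / sum(h)
        -sum(p * log(p))
    }
    for (j in c(2, 4, 6, 8)) {
        eRaw <- entropy(m[, j], seq(1e-4, 1e6, length.out = 51))
        eLog <- entropy(log10(m[, j]), seq(-4, 6, length.out = 51))
        expect_gt(eLog, eRaw + 1)   # substantially more uniform after log10
    }
})

test_that("normalization maps the box to [0,1] and inverts exactly", {
    norm <- normalizationSpec()
    spec <- priorSpec()
    atLo <- channelParams(theta = c(spec@gBounds[1],
                                    rep(c(spec@prefactorBounds[1],
                                          spec@sensitivityBounds[1]), 4)))
    atHi <- channelParams(theta = c(spec@gBounds[2],
                                    rep(c(spec@prefactorBounds[2],
                                          spec@sensitivityBounds[2]), 4)))
    expect_equal(unname(toNormalized(atLo, norm)), rep(0, 9), tolerance = 1e-12)
    expect_equal(unname(toNormalized(atHi, norm)), rep(1, 9), tolerance = 1e-12)
    # p1 = 10 with log10 bounds (-4, 6) normalizes to 0.5
    th <- theta(demoParams()); th["p1"] <- 10
    expect_equal(toNormalized(channelParams(theta = th), norm)[["p1"]], 0.5,
                 tolerance = 1e-12)
    # round trip over sampled parameters
    worst <- 0
    for (p in sampleParams(n = 200, seed = 3)) {
        back <- theta(fromNormalized(toNormalized(p, norm), norm))
        worst <- max(worst, max(abs(back - theta(p)) / theta(p)))
    }
    expect_lt(worst, 1e-10)
    expect_error(fromNormalized(c(rep(0.5, 8), 1.5)), "outside")
})

test_that("the rejection budget error is raised for an unsatisfiable spec", {
    # rate window moved entirely above any attainable extreme rate
    bad <- priorSpec(prefactorBounds = c(1e-4, 1e-3),
                     sensitivityBounds = c(1e-4, 1e-3),
                     rateBounds = c(1e5, 1e6))
    expect_error(sampleParams(bad, n = 1, seed = 1, maxAttempts = 200),
                 class = "hergSamplerError")
})
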