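#' Physiological constraint terms and check
#'
#' The uniform prior box is intersected with four physiological rate
#' constraints: each transition rate, evaluated at the extreme voltage at
#' which it is largest (Vmax = 0.06 V for the depolarization-activated
#' rates k1 and k3, Vmin = -0.12 V for the hyperpolarization-activated
#' rates k2 and k4), must lie strictly inside the physiological window
#' (0.0167, 1e6) 1/s. `constraintTerms` returns the four rate values
#' p1 e^(p2 Vmax), p3 e^(-p4 Vmin), p5 e^(p6 Vmax), p7 e^(-p8 Vmin);
#' `checkConstraints` returns TRUE iff all four lie strictly inside the
#' window.
#'
#' @param params A [ChannelParams-class] object.
#' @param spec A [PriorSpec-class] object.
#' @return `constraintTerms`: named numeric(4) of extreme-voltage rates
#'   (1/s). `checkConstraints`: logical scalar.
#' @examples
#' checkConstraints(demoParams())
#' @export
constraintTerms <- function(params, spec = priorSpec()) {
    stopifnot(is(params, "ChannelParams"), is(spec, "PriorSpec"))
    th <- params@theta
    c(k1_at_Vmax = th[["p1"]] * exp(th[["p2"]] * spec@vMax),
      k2_at_Vmin = th[["p3"]] * exp(-th[["p4"]] * spec@vMin),
      k3_at_Vmax = th[["p5"]] * exp(th[["p6"]] * spec@vMax),
      k4_at_Vmin = th[["p7"]] * exp(-th[["p8"]] * spec@vMin))
}

#' @rdname constraintTerms
#' @export
checkConstraints <- function(params, spec = priorSpec()) {
    terms <- constraintTerms(params, spec)
    all(terms > spec@rateBounds[1] & terms < spec@rateBounds[2])
}

# One (prefactor, sensitivity) pair conditioned on its rate constraint,
# drawn by rejection with counter-based substream seeds. `vcoef` is the
# (positive) voltage multiplying the sensitivity in the constraint term.
.samplePair <- function(spec, vcoef, seed, draw, pairIdx, maxAttempts) {
    pb <- spec@prefactorBounds
    sb <- spec@sensitivityBounds
    rb <- spec@rateBounds
    lpb <- log10(pb)
    for (attempt in seq_len(maxAttempts)) {
        u <- .withSeed(.subSeed(seed, draw, pairIdx, attempt), stats::runif(2))
        pre <- 10^(lpb[1] + u[1] * (lpb[2] - lpb[1]))
        sen <- sb[1] + u[2] * (sb[2] - sb[1])
        term <- pre * exp(sen * vcoef)
        if (term > rb[1] && term < rb[2])
            return(c(pre, sen))
    }
    .stopWithClass("hergSamplerError",
                   "rejection budget (%d) exceeded for pair %d of draw %d",
                   maxAttempts, pairIdx, draw)
}

#' Sample channel parameters from the constrained uniform prior
#'
#' Draws parameter sets from the componentwise prior over the
#' [PriorSpec-class] box, accepted only if the four physiological rate
#' constraints hold ([checkConstraints()]). The conductance and the
#' voltage sensitivities are uniform on their raw scale; the rate
#' prefactors p1, p3, p5, p7, which span ten decades, are uniform on
#' the log10 scale — on the raw scale their accepted distribution is
#' tightly clustered at small values, and the log scale spreads it
#' across the decades the downstream normalization and regression work
#' in. The constraints factorize over the independent pairs (p1,p2),
#' (p3,p4), (p5,p6), (p7,p8), so each pair is rejection-sampled against
#' its own constraint — exactly equivalent to joint rejection, at a
#' small fraction of the cost.
#'
#' Seeding is counter-based per draw, pair and attempt, so draw `i` of a
#' given seed is identical regardless of `n` or of other draws'
#' rejection histories.
#'
#' @param spec A [PriorSpec-class] object.
#' @param n Number of accepted parameter sets (>= 1).
#' @param seed Integer root seed.
#' @param maxAttempts Rejection budget per pair per draw; exceeding it
#'   raises a sampler error (condition class `hergSamplerError`).
#' @return A list of `n` [ChannelParams-class] objects.
#' @examples
#' th <- sampleParams(n = 3, seed = 1)
#' all(vapply(th, checkConstraints, logical(1)))
#' @export
sampleParams <- function(spec = priorSpec(), n = 1, seed = 1,
                         maxAttempts = 1e6) {
    stopifnot(is(spec, "PriorSpec"), n >= 1)
    validObject(spec)
    # the constraint's extreme-voltage coefficients for the four pairs
    vcoefs <- c(spec@vMax, -spec@vMin, spec@vMax, -spec@vMin)
    lapply(seq_len(n), function(i) {
        ug <- .withSeed(.subSeed(seed, i, 0L, 0L), stats::runif(1))
        g <- spec@gBounds[1] + ug * (spec@gBounds[2] - spec@gBounds[1])
        pairs <- lapply(1:4, function(k)
            .samplePair(spec, vcoefs[k], seed, i, k, maxAttempts))
        channelParams(theta = c(g, unlist(pairs)))
    })
}

#' Map parameters to and from the normalized learning space
#'
#' `toNormalized` applies log10 to the log-flagged components (by default
#' `g_Kr` and the rate prefactors) and then min-max normalizes every
#' component to [0, 1] using bounds fixed by the prior.
#' `fromNormalized` inverts the transform exactly; components outside
#' `[-eps, 1+eps]` raise a range error, and values within the tolerance
#' band are clamped to the box edge before inversion.
#'
#' @param params A [ChannelParams-class] object (within the prior box).
#' @param x Numeric vector of length 9 in [0, 1].
#' @param norm A [NormalizationSpec-class] object.
#' @param eps Tolerance band outside [0, 1] accepted on inversion.
#' @return `toNormalized`: named numeric(9) in [0, 1];
#'   `fromNormalized`: a [ChannelParams-class] object.
#' @examples
#' norm <- normalizationSpec()
#' x <- toNormalized(demoParams(), norm)
#' max(abs(theta(fromNormalized(x, norm)) - theta(demoParams())))
#' @export
toNormalized <- function(params, norm = normalizationSpec()) {
    stopifnot(is(params, "ChannelParams"), is(norm, "NormalizationSpec"))
    x <- params@theta
    x[norm@logFlags] <- log10(x[norm@logFlags])
    (x - norm@lo) / (norm@hi - norm@lo)
}

#' @rdname toNormalized
#' @export
fromNormalized <- function(x, norm = normalizationSpec(), eps = 1e-6) {
    stopifnot(is(norm, "NormalizationSpec"), length(x) == 9L)
    if (any(x < -eps | x > 1 + eps))
        stop(sprintf("normalized component outside [-%g, 1+%g]: [%g, %g]",
                     eps, eps, min(x), max(x)))
    x <- pmin(pmax(as.numeric(x), 0), 1)
    th <- norm@lo + x * (norm@hi - norm@lo)
    th[norm@logFlags] <- 10^th[norm@logFlags]
    channelParams(theta = th)
}
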