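# Precomputed segment/time geometry for repeated clean-current evaluation
# on a fixed (protocol, time grid) pair, used by the optimizer and MCMC
# hot loops.
.trajCache <- function(protocol, times) {
    durs <- protocol@durations
    starts <- cumsum(c(0, durs))
    nseg <- length(durs)
    segIdx <- vector("list", nseg)
    dts <- vector("list", nseg)
    for (s in seq_len(nseg)) {
        sel <- which(times >= starts[s] & times < starts[s + 1])
        if (s == nseg) sel <- union(sel, which(times == starts[s + 1]))
        segIdx[[s]] <- sel
        dts[[s]] <- times[sel] - starts[s]
    }
    list(volts = protocol@voltages, durs = durs, segIdx = segIdx, dts = dts,
         n = length(times))
}

# Clean current for a raw theta vector (g, p1..p8) on a cached grid;
# exact per-segment solution, no S4 dispatch. Returns NULL on overflow.
.currentFast <- function(th, cache, E_K) {
    v <- cache$volts
    e1 <- th[3] * v; e2 <- -th[5] * v; e3 <- th[7] * v; e4 <- -th[9] * v
    if (max(abs(c(e1, e2, e3, e4))) > .EXP_CLAMP) return(NULL)
    k1 <- th[2] * exp(e1); k2 <- th[4] * exp(e2)
    k3 <- th[6] * exp(e3); k4 <- th[8] * exp(e4)
    sa <- k1 + k2; sr <- k3 + k4
    ainf <- k1 / sa; rinf <- k4 / sr
    I <- numeric(cache$n)
    a0 <- ainf[1]; r0 <- rinf[1]
    for (s in seq_along(v)) {
        idx <- cache$segIdx[[s]]
        if (length(idx)) {
            ea <- exp(-cache$dts[[s]] * sa[s])
            er <- exp(-cache$dts[[s]] * sr[s])
            a <- ainf[s] + (a0 - ainf[s]) * ea
            r <- rinf[s] + (r0 - rinf[s]) * er
            I[idx] <- th[1] * a * r * (v[s] - E_K)
        }
        eaEnd <- exp(-cache$durs[s] * sa[s])
        erEnd <- exp(-cache$durs[s] * sr[s])
        a0 <- ainf[s] + (a0 - ainf[s]) * eaEnd
        r0 <- rinf[s] + (r0 - rinf[s]) * erEnd
    }
    if (anyNA(I)) return(NULL)
    I
}

#' Residual RMSE of a parameter set against an observed trace
#'
#' Root-mean-square difference, in pA, between the observed (decimated)
#' trace and the clean model current simulated for `params` on the same
#' protocol, sampled at `factor` times the observed rate and decimated
#' by `factor` (keep-first), i.e. evaluated exactly on the observed
#' sample grid. Simulation infeasibility (rate overflow, non-finite
#' state) yields `Inf`, which the fitter treats as a worst-case
#' objective.
#'
#' @param params A [ChannelParams-class] object.
#' @param trace Observed [CurrentTrace-class] (already decimated).
#' @param protocol A [VoltageProtocol-class] object.
#' @param factor Decimation factor linking the observed rate to the
#'   simulation rate (default 50).
#' @param constants A [PhysicalConstants-class] object.
#' @return RMSE in pA (`Inf` if infeasible).
#' @export
objectiveRMSE <- function(params, trace, protocol, factor = 50,
                          constants = physicalConstants()) {
    stopifnot(is(trace, "CurrentTrace"), is(protocol, "VoltageProtocol"))
    obs <- currents(trace)
    times <- (seq_along(obs) - 1) / sampleRate(trace)
    cache <- .trajCache(protocol, times)
    sim <- .currentFast(unname(theta(params)), cache, nernstPotential(constants))
    if (is.null(sim)) return(Inf)
    sqrt(mean((sim - obs)^2))
}

#' Classify the outcome of a fit
#'
#' A fit whose optimizer or simulator broke down is `"failed"`. A clean
#' termination is `"converged"` when the residual RMSE is at most
#' `threshold` times the noise SD — on a correctly fitted noisy trace
#' the best attainable RMSE concentrates near sigma — and otherwise a
#' `"local_minimum"` (a wrong basin far above the noise floor).
#'
#' @param rmse Residual RMSE, pA.
#' @param sigma Noise SD, pA (> 0).
#' @param solverOk FALSE if the optimizer/simulator broke down.
#' @param threshold Multiple of sigma separating convergence from a
#'   local minimum (default 1.2).
#' @return `"converged"`, `"local_minimum"` or `"failed"`.
#' @examples
#' classifyFit(10.84, 10.84)    # converged
#' classifyFit(108.4, 10.84)    # local_minimum
#' @export
classifyFit <- function(rmse, sigma, solverOk = TRUE, threshold = 1.2) {
    stopifnot(sigma > 0)
    if (!solverOk) return("failed")
    if (is.finite(rmse) && rmse <= threshold * sigma) "converged"
    else "local_minimum"
}

# Project a normalized point onto the physiological constraint region by
# rescaling each pair's prefactor so its extreme-voltage rate sits just
# inside the bounds (the minimal along-prefactor move; stays in the box
# because the rate window is contained in the prefactor bounds).
.projectFeasible <- function(x, norm, spec, margin = 0.05) {
    th <- norm@lo + pmin(pmax(x, 0), 1) * (norm@hi - norm@lo)
    th[norm@logFlags] <- 10^th[norm@logFlags]
    vext <- c(spec@vMax, -spec@vMin, spec@vMax, -spec@vMin)
    lrb <- log10(spec@rateBounds)
    for (k in 1:4) {
        pre <- th[2 * k]; sen <- th[2 * k + 1]
        lterm <- log10(pre) + sen * vext[k] / log(10)
        if (lterm <= lrb[1])
            th[2 * k] <- 10^(log10(pre) + (lrb[1] + margin - lterm))
        else if (lterm >= lrb[2])
            th[2 * k] <- 10^(log10(pre) - (lterm - lrb[2] + margin))
    }
    xp <- th
    xp[norm@logFlags] <- log10(xp[norm@logFlags])
    pmin(pmax((xp - norm@lo) / (norm@hi - norm@lo), 0), 1)
}

# Standard (mu/mu_w, lambda)-CMA-ES minimizer on R^n with rank-mu and
# rank-one covariance updates and cumulative step-size adaptation
# (Hansen's reference parameterization). Returns the best point seen.
.cmaes <- function(fn, x0, sigma0 = 0.1, maxIter = 1000,
                   stagnTol = 1e-6, stagnIter = 30, seed = 1,
                   lambda = NULL) {
    n <- length(x0)
    if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
    mu <- floor(lambda / 2)
    wts <- log(mu + 0.5) - log(seq_len(mu))
    wts <- wts / sum(wts)
    mueff <- 1 / sum(wts^2)
    cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
    cs <- (mueff + 2) / (n + mueff + 5)
    c1 <- 2 / ((n + 1.3)^2 + mueff)
    cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
    damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
    chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

    xmean <- x0
    sigma <- sigma0
    pc <- ps <- numeric(n)
    C <- diag(n)
    eig <- eigen(C, symmetric = TRUE)
    invsqrtC <- diag(n)
    B <- diag(n); D <- rep(1, n)
    best <- list(x = x0, f = Inf)
    history <- numeric(0)
    evals <- 0L
    iter <- 0L

    .withSeed(seed, {
        repeat {
            iter <- iter + 1L
            Z <- matrix(stats::rnorm(n * lambda), n, lambda)
            Y <- B %*% (D * Z)
            X <- xmean + sigma * Y
            fvals <- apply(X, 2, fn)
            evals <- evals + lambda
            ord <- order(fvals)
            if (fvals[ord[1]] < best$f)
                best <- list(x = X[, ord[1]], f = fvals[ord[1]])
            history <- c(history, best$f)

            sel <- ord[seq_len(mu)]
            yw <- drop(Y[, sel, drop = FALSE] %*% wts)
            xmean <- xmean + sigma * yw
            ps <- (1 - cs) * ps +
                sqrt(cs * (2 - cs) * mueff) * drop(invsqrtC %*% yw)
            hsig <- sqrt(sum(ps^2)) /
                sqrt(1 - (1 - cs)^(2 * iter)) / chiN < 1.4 + 2 / (n + 1)
            pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
            artmp <- Y[, sel, drop = FALSE]
            C <- (1 - c1 - cmu) * C +
                c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
                cmu * artmp %*% (wts * t(artmp))
            sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

            C <- (C + t(C)) / 2
            eig <- eigen(C, symmetric = TRUE)
            D <- sqrt(pmax(eig$values, 1e-20))
            B <- eig$vectors
            invsqrtC <- B %*% (t(B) / D)

            if (iter >= maxIter) break
            if (length(history) > stagnIter &&
                history[length(history) - stagnIter] - best$f < stagnTol) break
            if (sigma * max(D) < 1e-12) break
            if (!all(is.finite(C))) break
        }
    })
    list(x = best$x, f = best$f, iterations = iter, evaluations = evals,
         history = history, ok = is.finite(best$f))
}

#' Fit the channel model to a trace with CMA-ES
#'
#' Minimizes [objectiveRMSE()] over the normalized parameter space
#' [0,1]^9 by CMA-ES, starting from `init`. Candidates are clamped to
#' the box for evaluation with a quadratic out-of-box penalty, and
#' candidates violating the physiological rate constraints receive a
#' large constraint-distance penalty instead of a simulation, so the
#' search is steered back into the feasible region. An initializer
#' outside the box or the constraints is projected/penalized the same
#' way (with a message) and the run proceeds.
#'
#' @param trace Observed [CurrentTrace-class] (decimated).
#' @param protocol A [VoltageProtocol-class] object.
#' @param init A [ChannelParams-class] start point.
#' @param spec A [PriorSpec-class] object.
#' @param noise A [NoiseModel-class]; its sigma sets the convergence
#'   threshold of [classifyFit()].
#' @param factor Decimation factor (see [objectiveRMSE()]).
#' @param sigma0 Initial CMA-ES step size in normalized space.
#' @param maxIter Iteration (generation) cap.
#' @param stagnTol,stagnIter Stop when the best objective improves by
#'   less than `stagnTol` (pA; default 1e-3, about 0.01% of the noise
#'   floor) over `stagnIter` iterations (default 60 — patient enough
#'   that slow covariance learning is not mistaken for a stall).
#' @param seed Integer seed.
#' @param initializer Label recorded in the result.
#' @param lambda CMA-ES population size. The default (16) doubles the
#'   textbook 4 + floor(3 ln 9) for this 9-dimensional problem, which
#'   markedly improves covariance learning on the strongly anisotropic
#'   normalized landscape.
#' @return A [FitResult-class] object.
#' @export
fitCMAES <- function(trace, protocol, init, spec = priorSpec(),
                     noise = noiseModel(), factor = 50, sigma0 = 0.1,
                     maxIter = 1000, stagnTol = 1e-3, stagnIter = 60,
                     seed = 1, initializer = "custom", lambda = 16) {
    stopifnot(is(init, "ChannelParams"))
    norm <- normalizationSpec(spec)
    th0 <- theta(init)
    lo <- norm@lo; hi <- norm@hi
    x0raw <- th0
    x0raw[norm@logFlags] <- log10(x0raw[norm@logFlags])
    x0 <- (x0raw - lo) / (hi - lo)
    if (any(x0 < 0 | x0 > 1)) {
        message("initializer outside the prior box; projected onto it")
        x0 <- pmin(pmax(x0, 0), 1)
    }
    if (!checkConstraints(fromNormalized(x0, norm), spec)) {
        message("initializer violates the rate constraints; projected to the feasible region")
        x0 <- .projectFeasible(x0, norm, spec)
    }
    rb <- log10(spec@rateBounds)
    obs <- currents(trace)
    cache <- .trajCache(protocol, (seq_along(obs) - 1) / sampleRate(trace))
    E_K <- nernstPotential()
    logF <- norm@logFlags
    vext <- c(spec@vMax, -spec@vMin, spec@vMax, -spec@vMin)
    fn <- function(x) {
        xc <- pmin(pmax(x, 0), 1)
        boxPen <- 1e4 * sum((x - xc)^2)
        th <- unname(lo + xc * (hi - lo))
        th[logF] <- 10^th[logF]
        lterms <- log10(th[c(2, 4, 6, 8)]) + th[c(3, 5, 7, 9)] * vext / log(10)
        viol <- sum(pmax(0, rb[1] - lterms) + pmax(0, lterms - rb[2]))
        if (viol > 0)
            return(1e7 * (1 + viol) + boxPen)
        sim <- .currentFast(th, cache, E_K)
        if (is.null(sim)) return(1e7 + boxPen)
        sqrt(mean((sim - obs)^2)) + boxPen
    }
    res <- .cmaes(fn, x0, sigma0 = sigma0, maxIter = maxIter,
                  stagnTol = stagnTol, stagnIter = stagnIter, seed = seed,
                  lambda = lambda)
    solverOk <- res$ok && res$f < 1e7
    xhat <- pmin(pmax(res$x, 0), 1)
    thetaHat <- fromNormalized(xhat, norm)
    rmse <- if (solverOk) objectiveRMSE(thetaHat, trace, protocol, factor)
            else Inf
    new("FitResult", thetaHat = thetaHat, rmse = rmse,
        iterations = res$iterations, evaluations = res$evaluations,
        status = classifyFit(rmse, noise@sigma, solverOk),
        initializer = initializer, seed = seed)
}

#' Explore the posterior with adaptive Metropolis MCMC
#'
#' Random-walk Metropolis in the normalized parameter space with the
#' Haario-style adaptive proposal: after a warm-up, the proposal
#' covariance tracks the chain history (scaled by 2.38^2/d with a small
#' regularizer) and the global scale is tuned toward an acceptance rate
#' of about 0.25 with a diminishing adaptation rate. The posterior is
#' the iid Gaussian likelihood with known noise SD times the box prior
#' with the physiological constraint indicator.
#'
#' @param trace Observed [CurrentTrace-class] (decimated).
#' @param protocol A [VoltageProtocol-class] object.
#' @param init Feasible [ChannelParams-class] start point.
#' @param nSamples Total chain length including burn-in.
#' @param seed Integer seed.
#' @param spec A [PriorSpec-class] object.
#' @param noise A [NoiseModel-class]; its sigma enters the likelihood.
#' @param factor Decimation factor (see [objectiveRMSE()]).
#' @param nBurn Burn-in length discarded from the returned chain
#'   (default `nSamples %/% 4`).
#' @param warmup Iterations before covariance adaptation starts.
#' @return A [PosteriorChain-class] object.
#' @export
adaptiveMetropolis <- function(trace, protocol, init, nSamples = 20000,
                               seed = 1, spec = priorSpec(),
                               noise = noiseModel(), factor = 50,
                               nBurn = nSamples %/% 4, warmup = 500) {
    stopifnot(is(init, "ChannelParams"), nSamples > nBurn, noise@sigma > 0)
    norm <- normalizationSpec(spec)
    obs <- currents(trace)
    times <- (seq_along(obs) - 1) / sampleRate(trace)
    s2 <- noise@sigma^2
    cache <- .trajCache(protocol, times)
    E_K <- nernstPotential()
    lo <- norm@lo; hi <- norm@hi; logF <- norm@logFlags
    rb <- spec@rateBounds
    vext <- c(spec@vMax, -spec@vMin, spec@vMax, -spec@vMin)
    logLik <- function(x) {
        if (any(x < 0 | x > 1)) return(-Inf)
        th <- unname(lo + x * (hi - lo))
        th[logF] <- 10^th[logF]
        terms <- th[c(2, 4, 6, 8)] * exp(th[c(3, 5, 7, 9)] * vext)
        if (any(terms <= rb[1] | terms >= rb[2])) return(-Inf)
        sim <- .currentFast(th, cache, E_K)
        if (is.null(sim)) return(-Inf)
        -sum((sim - obs)^2) / (2 * s2)
    }
    d <- 9L
    x <- toNormalized(init, norm)
    ll <- logLik(x)
    if (!is.finite(ll))
        stop("init must be feasible (inside the box and constraints)")
    chain <- matrix(NA_real_, nSamples, d)
    logScale <- log(0.1 / sqrt(d))
    covC <- diag(d)
    cholC <- diag(d)
    mean_ <- x
    M2 <- matrix(0, d, d)
    nAcc <- 0L
    consecRej <- 0L
    .withSeed(seed, {
        for (t in seq_len(nSamples)) {
            step <- exp(logScale) * drop(cholC %*% stats::rnorm(d))
            prop <- x + step
            llp <- logLik(prop)
            acc <- is.finite(llp) && log(stats::runif(1)) < llp - ll
            if (acc) {
                x <- prop; ll <- llp; nAcc <- nAcc + 1L; consecRej <- 0L
            } else {
                consecRej <- consecRej + 1L
                if (consecRej >= 1000L)
                    .stopWithClass("hergSamplerError",
                                   "MCMC stalled: 1000 consecutive rejections")
            }
            chain[t, ] <- x
            # running mean/covariance of the chain
            delta <- x - mean_
            mean_ <- mean_ + delta / t
            M2 <- M2 + delta %o% (x - mean_)
            # diminishing scale adaptation toward 0.25 acceptance
            logScale <- logScale + (as.numeric(acc) - 0.25) / t^0.6
            if (t > warmup && t %% 50L == 0L) {
                covC <- (2.38^2 / d) * (M2 / (t - 1)) + 1e-10 * diag(d)
                ch <- tryCatch(chol(covC), error = function(e) NULL)
                if (!is.null(ch)) cholC <- t(ch)
            }
        }
    })
    kept <- chain[(nBurn + 1L):nSamples, , drop = FALSE]
    raw <- t(apply(kept, 1, function(z) theta(fromNormalized(z, norm))))
    colnames(raw) <- colnames(kept) <- .PARAM_NAMES
    new("PosteriorChain", samples = raw, normalized = kept,
        acceptance = nAcc / nSamples, nBurn = nBurn)
}

#' Benchmark the three fitting initializers
#'
#' For each synthetic cell, runs [fitCMAES()] three ways — warm-started
#' from the regressor's prediction on the cell's trace, from the prior
#' midpoint vector, and from a random prior draw — and aggregates
#' outcome counts and mean iterations/wall time per initializer. Mean
#' iterations and time are computed over converged fits (the convention
#' used when comparing fitting rates of cells that succeeded); all-fit
#' means are also reported.
#'
#' @param cells List of cells as produced by [sampleBenchmarkCells()]
#'   (each `list(trace =, theta = or NULL)`).
#' @param model A [TrainedRegressor-class] object.
#' @param priorInit The "prior" initializer; default is the midpoint of
#'   the normalized box.
#' @param spec,protocol,noise,factor Shared fitting setup.
#' @param seed Integer root seed (per-cell substreams).
#' @param ... Further arguments passed to [fitCMAES()] (e.g. `maxIter`).
#' @return A list with `report` (one data.frame row per initializer:
#'   meanIterations, meanTimeS, nFailures, nLocalMinima, nConverged,
#'   nCells, plus all-fit means) and `fits` (list of per-cell
#'   [FitResult-class] triplets).
#' @export
benchmarkInits <- function(cells, model, priorInit = NULL,
                           spec = priorSpec(),
                           protocol = staircaseProtocol(),
                           noise = noiseModel(), factor = 50, seed = 1,
                           ...) {
    stopifnot(length(cells) >= 1, is(model, "TrainedRegressor"))
    norm <- normalizationSpec(spec)
    if (is.null(priorInit)) priorInit <- fromNormalized(rep(0.5, 9), norm)
    inits <- c("predicted", "prior", "random")
    fits <- vector("list", length(cells))
    for (ci in seq_along(cells)) {
        cell <- cells[[ci]]
        predInit <- predictParams(model, cell$trace, type = "theta")
        randInit <- sampleParams(spec, 1, seed = .subSeed(seed, 601L, ci))[[1]]
        starts <- list(predicted = predInit, prior = priorInit,
                       random = randInit)
        fits[[ci]] <- lapply(inits, function(lab) {
            t0 <- proc.time()[["elapsed"]]
            # common random numbers: the same optimizer seed for all
            # three arms of a cell, so the comparison is paired
            fr <- suppressMessages(
                fitCMAES(cell$trace, protocol, starts[[lab]], spec,
                         noise, factor,
                         seed = .subSeed(seed, 602L, ci),
                         initializer = lab, ...))
            attr(fr, "timeS") <- proc.time()[["elapsed"]] - t0
            fr
        })
        names(fits[[ci]]) <- inits
    }
    rows <- lapply(inits, function(lab) {
        frs <- lapply(fits, `[[`, lab)
        st <- vapply(frs, fitStatus, character(1))
        it <- vapply(frs, function(f) f@iterations, numeric(1))
        tm <- vapply(frs, function(f) attr(f, "timeS"), numeric(1))
        conv <- st == "converged"
        data.frame(
            initializer = lab,
            meanIterations = if (any(conv)) mean(it[conv]) else NA_real_,
            meanTimeS = if (any(conv)) mean(tm[conv]) else NA_real_,
            nFailures = sum(st == "failed"),
            nLocalMinima = sum(st == "local_minimum"),
            nConverged = sum(conv),
            nCells = length(frs),
            meanIterationsAll = mean(it),
            meanTimeSAll = mean(tm))
    })
    list(report = do.call(rbind, rows), fits = fits)
}
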