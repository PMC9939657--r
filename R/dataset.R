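#' Add Gaussian recording noise to a trace
#'
#' Adds independent zero-mean Gaussian noise per sample, emulating
#' patch-clamp recording noise: I_obs ~ I_sim + alpha, alpha ~ N(0,
#' sigma^2). Deterministic given `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param trace A [CurrentTrace-class] object.
#' @param noise A [NoiseModel-class] object.
#' @param seed Integer seed.
#' @return A [CurrentTrace-class] with the same sampling rate.
#' @export
addNoise <- function(trace, noise = noiseModel(), seed = 1) {
    stopifnot(is(trace, "CurrentTrace"), is(noise, "NoiseModel"))
    if (noise@sigma == 0) return(trace)
    eps <- .withSeed(seed, stats::rnorm(length(trace), 0, noise@sigma))
    currentTrace(currents(trace) + eps, sampleRate(trace))
}

#' Decimate a trace by an integer factor
#'
#' Keep-first decimation: samples 1, 1+factor, 1+2*factor, ... are kept
#' and the sampling rate is divided by `factor`. With the study defaults
#' (15.4 s at 5 kHz, factor 50) a 77,000-sample trace becomes 1,540
#' samples at 100 Hz.
#'
#' @param trace A [CurrentTrace-class] object.
#' @param factor Integer >= 1.
#' @return A [CurrentTrace-class] object.
#' @export
downsampleTrace <- function(trace, factor) {
    stopifnot(is(trace, "CurrentTrace"))
    if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
        factor != round(factor))
        stop("factor must be a single integer >= 1")
    if (factor == 1) return(trace)
    keep <- seq(1L, length(trace), by = as.integer(factor))
    currentTrace(currents(trace)[keep], sampleRate(trace) / factor)
}

#' Generate a labelled synthetic training dataset
#'
#' Produces `n` (trace, parameters) training pairs by the pipeline:
#' draw theta from the constrained prior, simulate the clean current on
#' the protocol at `sampleRate`, add Gaussian noise on the full-rate
#' trace, decimate by `factor`, and store the noisy trace alongside the
#' normalized parameter vector. Parameter draws whose simulation is
#' infeasible are resampled (preserving the prior's support) and the
#' events counted in the manifest. Fully reproducible from `seed` via
#' counter-based per-example substreams.
#'
#' @param n Number of examples (>= 1).
#' @param spec A [PriorSpec-class] object.
#' @param protocol A [VoltageProtocol-class] object.
#' @param noise A [NoiseModel-class] object.
#' @param factor Integer decimation factor (default 50).
#' @param sampleRate Full simulation sampling rate, Hz (default 5000).
#' @param seed Integer root seed.
#' @param norm A [NormalizationSpec-class]; defaults to one derived
#'   from `spec`.
#' @param maxResample Resample budget per example.
#' @return A [HergDataset-class] object.
#' @examples
#' ds <- generateDataset(n = 3, seed = 1, sampleRate = 500, factor = 5)
#' @export
generateDataset <- function(n, spec = priorSpec(),
                            protocol = staircaseProtocol(),
                            noise = noiseModel(), factor = 50,
                            sampleRate = 5000, seed = 1,
                            norm = normalizationSpec(spec),
                            maxResample = 100) {
    stopifnot(n >= 1)
    L <- length(downsampleTrace(
        currentTrace(numeric(round(totalDuration(protocol) * sampleRate)), sampleRate),
        factor))
    traces <- matrix(NA_real_, n, L)
    targets <- matrix(NA_real_, n, 9)
    thetaRaw <- matrix(NA_real_, n, 9)
    colnames(targets) <- colnames(thetaRaw) <- .PARAM_NAMES
    nResampled <- 0L
    for (i in seq_len(n)) {
        tr <- NULL
        for (attempt in seq_len(maxResample)) {
            th <- sampleParams(spec, 1, seed = .subSeed(seed, 9001L, i, attempt))[[1]]
            tr <- tryCatch(
                simulateCurrent(th, protocol, sampleRate = sampleRate),
                hergSimError = function(e) NULL)
            if (!is.null(tr)) break
            nResampled <- nResampled + 1L
        }
        if (is.null(tr))
            .stopWithClass("hergSamplerError",
                           "resample budget exceeded for example %d", i)
        noisy <- addNoise(tr, noise, seed = .subSeed(seed, 9002L, i))
        down <- downsampleTrace(noisy, factor)
        traces[i, ] <- currents(down)
        targets[i, ] <- toNormalized(th, norm)
        thetaRaw[i, ] <- theta(th)
    }
    manifest <- list(
        n = n, seed = seed, sigma = noise@sigma, factor = factor,
        sampleRate = sampleRate, traceLength = L,
        protocolName = protocol@name,
        protocolHash = .protocolHash(protocol),
        prior = list(gBounds = spec@gBounds,
                     prefactorBounds = spec@prefactorBounds,
                     sensitivityBounds = spec@sensitivityBounds,
                     rateBounds = spec@rateBounds,
                     vMin = spec@vMin, vMax = spec@vMax),
        logFlags = unname(norm@logFlags),
        nResampled = nResampled)
    new("HergDataset", traces = traces, targets = targets,
        thetaRaw = thetaRaw, sampleRate = sampleRate / factor,
        manifest = manifest)
}

.protocolHash <- function(protocol) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp))
    writeProtocolCSV(protocol, tmp)
    unname(tools::md5sum(tmp))
}

#' Write or read a dataset container
#'
#' The container is an RDS bundle of the three arrays (traces, targets,
#' theta) plus a JSON sidecar `<path>.manifest.json` holding the
#' provenance metadata (seed, prior, protocol hash, noise sigma,
#' decimation factor).
#'
#' @param dataset A [HergDataset-class] object.
#' @param path Output path (conventionally `.rds`).
#' @return `writeDataset` returns `path` invisibly; `readDataset`
#'   returns a [HergDataset-class].
#' @export
writeDataset <- function(dataset, path) {
    stopifnot(is(dataset, "HergDataset"))
    saveRDS(list(format = "hergfit-dataset", version = 1L,
                 traces = dataset@traces, targets = dataset@targets,
                 theta = dataset@thetaRaw, sampleRate = dataset@sampleRate,
                 manifest = dataset@manifest),
            path, version = 2)
    jsonlite::write_json(dataset@manifest,
                         paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname writeDataset
#' @export
readDataset <- function(path) {
    obj <- tryCatch(readRDS(path), error = function(e)
        stop("not a readable dataset container: ", conditionMessage(e)))
    if (!is.list(obj) || !identical(obj$format, "hergfit-dataset"))
        stop("file is not a hergfit dataset container")
    new("HergDataset", traces = obj$traces, targets = obj$targets,
        thetaRaw = obj$theta, sampleRate = obj$sampleRate,
        manifest = obj$manifest)
}

#' Synthetic benchmark cells emulating an experimental cell population
#'
#' Draws "cells" for fitting benchmarks as log-uniform perturbations
#' (each parameter multiplied by a factor in [1/spread, spread]) of the
#' literature-typical kinetics of [demoParams()], with the conductance
#' drawn uniformly over a decade around the typical value. Candidates
#' are clipped to the prior box and must satisfy the physiological
#' constraints and a peak-current quality filter (clean peak |I| >=
#' `minPeak` pA), mirroring the quality control an experimental cell
#' population has passed. This emulates a population of biological
#' replicates of the same channel, not raw prior draws.
#'
#' @param n Number of cells.
#' @param spec A [PriorSpec-class] object.
#' @param protocol A [VoltageProtocol-class] object.
#' @param noise A [NoiseModel-class]; each cell's observed trace is the
#'   clean decimated trace plus this noise.
#' @param factor Decimation factor for the observed traces.
#' @param sampleRate Full simulation rate, Hz.
#' @param seed Integer root seed.
#' @param spread Multiplicative kinetic spread (default 2: factors in
#'   [0.5, 2]).
#' @param minPeak Peak-current QC threshold, pA (default 250, about 25
#'   noise SDs).
#' @return List of `n` cells, each `list(trace = CurrentTrace (noisy,
#'   decimated), theta = ChannelParams, clean = CurrentTrace (decimated),
#'   peak = full-rate clean peak |I| in pA)`.
#' @export
sampleBenchmarkCells <- function(n, spec = priorSpec(),
                                 protocol = staircaseProtocol(),
                                 noise = noiseModel(), factor = 50,
                                 sampleRate = 5000, seed = 1,
                                 spread = 2, minPeak = 250) {
    stopifnot(n >= 1, spread > 1)
    base <- theta(demoParams())
    cells <- vector("list", n)
    for (i in seq_len(n)) {
        cell <- NULL
        for (attempt in 1:1000) {
            u <- .withSeed(.subSeed(seed, 7001L, i, attempt), stats::runif(9))
            mult <- spread^(2 * u - 1)
            mult[1] <- 10^(u[1] - 0.5)   # conductance: one decade
            th <- base * mult
            lo <- c(spec@gBounds[1], rep(c(spec@prefactorBounds[1],
                                           spec@sensitivityBounds[1]), 4))
            hi <- c(spec@gBounds[2], rep(c(spec@prefactorBounds[2],
                                           spec@sensitivityBounds[2]), 4))
            th <- pmin(pmax(th, lo), hi)
            params <- channelParams(theta = th)
            if (!checkConstraints(params, spec)) next
            clean <- tryCatch(
                simulateCurrent(params, protocol, sampleRate = sampleRate),
                hergSimError = function(e) NULL)
            if (is.null(clean)) next
            if (max(abs(currents(clean))) < minPeak) next
            noisy <- downsampleTrace(
                addNoise(clean, noise, seed = .subSeed(seed, 7002L, i)),
                factor)
            cell <- list(trace = noisy, theta = params,
                         clean = downsampleTrace(clean, factor),
                         peak = max(abs(currents(clean))))
            break
        }
        if (is.null(cell))
            .stopWithClass("hergSamplerError",
                           "could not generate benchmark cell %d", i)
        cells[[i]] <- cell
    }
    cells
}
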