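#' @import methods
NULL

.PARAM_NAMES <- c("g_Kr", "p1", "p2", "p3", "p4", "p5", "p6", "p7", "p8")

#' Nine-parameter hERG channel parameter vector
#'
#' Holds the parameter vector theta = (g_Kr, p1, ..., p8) of the
#' Hodgkin-Huxley hERG model. `g_Kr` is the maximal conductance in pA/V;
#' `p1, p3, p5, p7` are rate prefactors in 1/s; `p2, p4, p6, p8` are
#' voltage sensitivities in 1/V. All components must be strictly positive.
#'
#' @slot theta Named numeric vector of length 9.
#' @export
setClass("ChannelParams", representation(theta = "numeric"))

setValidity("ChannelParams", function(object) {
    th <- object@theta
    if (length(th) != 9L)
        return("theta must have length 9")
    if (!identical(names(th), .PARAM_NAMES))
        return(sprintf("theta must be named %s", paste(.PARAM_NAMES, collapse = ", ")))
    if (!all(is.finite(th)))
        return("all parameters must be finite")
    if (any(th <= 0))
        return("all parameters must be strictly positive")
    TRUE
})

#' @param g_Kr,p1,p2,p3,p4,p5,p6,p7,p8 Positive scalars; see class description
#'   for units.
#' @param theta Alternatively, a numeric vector of length 9 in the order
#'   `g_Kr, p1, ..., p8` (names optional).
#' @return A `ChannelParams` object.
#' @examples
#' channelParams(theta = c(33000, rep(c(1, 50), 4)))
#' @rdname ChannelParams-class
#' @export
channelParams <- function(g_Kr, p1, p2, p3, p4, p5, p6, p7, p8, theta = NULL) {
    if (is.null(theta))
        theta <- c(g_Kr, p1, p2, p3, p4, p5, p6, p7, p8)
    theta <- as.numeric(theta)
    if (length(theta) != 9L)
        stop("theta must have length 9")
    names(theta) <- .PARAM_NAMES
    new("ChannelParams", theta = theta)
}

#' @param object,x A `ChannelParams` object.
#' @rdname ChannelParams-class
#' @export
setGeneric("theta", function(object) standardGeneric("theta"))

#' @rdname ChannelParams-class
#' @export
setMethod("theta", "ChannelParams", function(object) object@theta)

#' @rdname ChannelParams-class
#' @param ... unused.
#' @export
setMethod("as.numeric", "ChannelParams", function(x, ...) x@theta)

setMethod("show", "ChannelParams", function(object) {
    cat("ChannelParams (g_Kr in pA/V; p1,p3,p5,p7 in 1/s; p2,p4,p6,p8 in 1/V)\n")
    print(signif(object@theta, 6))
})

#' Physical constants for the Nernst potential
#'
#' Ideal gas constant R, absolute temperature T, Faraday constant F, ion
#' valency z and the extracellular / intracellular potassium concentrations.
#' Defaults are the room-temperature values used for the hERG recordings
#' this model targets.
#'
#' @slot R J/(K mol). @slot T K. @slot F C/mol. @slot z dimensionless.
#' @slot K_out,K_in mM.
#' @export
setClass("PhysicalConstants", representation(
    R = "numeric", T = "numeric", F = "numeric", z = "numeric",
    K_out = "numeric", K_in = "numeric"))

setValidity("PhysicalConstants", function(object) {
    vals <- c(object@R, object@T, object@F, object@K_out, object@K_in)
    if (!all(is.finite(vals)) || any(vals <= 0))
        return("R, T, F, K_out, K_in must be positive and finite")
    if (object@z == 0)
        return("z must be nonzero")
    TRUE
})

#' @param R,T,F,z,K_out,K_in See class slots; defaults are the standard values.
#' @param file Optional path to a `key=value` override file; keys are the
#'   slot names, unknown keys are an error.
#' @return A `PhysicalConstants` object.
#' @rdname PhysicalConstants-class
#' @export
physicalConstants <- function(R = 8.314472, T = 298.15, F = 96485.3415,
                              z = 1, K_out = 4, K_in = 110, file = NULL) {
    vals <- list(R = R, T = T, F = F, z = z, K_out = K_out, K_in = K_in)
    if (!is.null(file)) {
        lines <- readLines(file, warn = FALSE)
        lines <- trimws(lines)
        lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
        for (ln in lines) {
            kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
            if (length(kv) != 2L)
                stop("malformed constants line: ", ln)
            key <- trimws(kv[1])
            if (!key %in% names(vals))
                stop("unknown constant: ", key)
            vals[[key]] <- as.numeric(trimws(kv[2]))
        }
    }
    new("PhysicalConstants", R = vals$R, T = vals$T, F = vals$F,
        z = vals$z, K_out = vals$K_out, K_in = vals$K_in)
}

setMethod("show", "PhysicalConstants", function(object) {
    cat(sprintf("PhysicalConstants: R=%g T=%g F=%g z=%+g [K+]o=%g mM [K+]i=%g mM\n",
                object@R, object@T, object@F, object@z, object@K_out, object@K_in))
})

#' Gating state of the two-gate hERG model
#'
#' Activation gate occupancy `a` and inactivation gate occupancy `r`,
#' both dimensionless in [0, 1].
#'
#' @slot a,r Numeric scalars in [0, 1].
#' @export
setClass("GateState", representation(a = "numeric", r = "numeric"))

setValidity("GateState", function(object) {
    if (!is.finite(object@a) || !is.finite(object@r))
        return("gate occupancies must be finite")
    if (object@a < 0 || object@a > 1 || object@r < 0 || object@r > 1)
        return("gate occupancies must lie in [0, 1]")
    TRUE
})

#' @param a,r Gate occupancies in [0, 1].
#' @return A `GateState` object.
#' @rdname GateState-class
#' @export
gateState <- function(a, r) new("GateState", a = a, r = r)

setMethod("show", "GateState", function(object)
    cat(sprintf("GateState: a=%.6g r=%.6g\n", object@a, object@r)))

#' Piecewise-constant voltage-clamp protocol
#'
#' An ordered list of (duration, voltage) segments, voltages in volts and
#' durations in seconds. The voltage at a segment boundary belongs to the
#' later segment (half-open convention).
#'
#' @slot durations Segment durations, s, all > 0.
#' @slot voltages Segment command voltages, V.
#' @slot name Protocol label.
#' @slot voltageWindow Sanity window for voltages, V.
#' @export
setClass("VoltageProtocol", representation(
    durations = "numeric", voltages = "numeric", name = "character",
    voltageWindow = "numeric"))

setValidity("VoltageProtocol", function(object) {
    if (length(object@durations) < 1L)
        return("protocol needs at least one segment")
    if (length(object@durations) != length(object@voltages))
        return("durations and voltages must have equal length")
    if (!all(is.finite(object@durations)) || any(object@durations <= 0))
        return("all durations must be positive and finite")
    if (!all(is.finite(object@voltages)))
        return("all voltages must be finite")
    w <- object@voltageWindow
    if (length(w) != 2L || w[1] >= w[2])
        return("voltageWindow must be (lo, hi) with lo < hi")
    if (any(object@voltages < w[1] | object@voltages > w[2]))
        return(sprintf("voltages outside sanity window [%g, %g] V", w[1], w[2]))
    TRUE
})

#' @param durations,voltages Equal-length numeric vectors (s, V).
#' @param name Protocol label.
#' @param voltageWindow Allowed voltage range, default c(-0.15, 0.10) V.
#' @return A `VoltageProtocol` object.
#' @rdname VoltageProtocol-class
#' @export
voltageProtocol <- function(durations, voltages, name = "protocol",
                            voltageWindow = c(-0.15, 0.10)) {
    new("VoltageProtocol", durations = as.numeric(durations),
        voltages = as.numeric(voltages), name = name,
        voltageWindow = voltageWindow)
}

#' @param object A `VoltageProtocol`.
#' @rdname VoltageProtocol-class
#' @export
setGeneric("totalDuration", function(object) standardGeneric("totalDuration"))

#' @rdname VoltageProtocol-class
#' @export
setMethod("totalDuration", "VoltageProtocol",
          function(object) sum(object@durations))

#' @rdname VoltageProtocol-class
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))

#' @rdname VoltageProtocol-class
#' @export
setMethod("nSegments", "VoltageProtocol",
          function(object) length(object@durations))

#' @rdname VoltageProtocol-class
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))

#' @rdname VoltageProtocol-class
#' @export
setMethod("segments", "VoltageProtocol", function(object)
    data.frame(duration_s = object@durations, voltage_V = object@voltages))

setMethod("show", "VoltageProtocol", function(object) {
    cat(sprintf("VoltageProtocol '%s': %d segments, %.4g s total, V in [%.3g, %.3g]\n",
                object@name, nSegments(object), totalDuration(object),
                min(object@voltages), max(object@voltages)))
})

#' Uniformly sampled current trace
#'
#' A membrane current time series in pA sampled uniformly at `sampleRate`
#' Hz starting at t = 0.
#'
#' @slot current Current samples, pA.
#' @slot sampleRate Sampling rate, Hz.
#' @export
setClass("CurrentTrace", representation(current = "numeric",
                                        sampleRate = "numeric"))

setValidity("CurrentTrace", function(object) {
    if (length(object@current) < 1L)
        return("trace must contain at least one sample")
    if (!all(is.finite(object@current)))
        return("all current samples must be finite")
    if (!is.finite(object@sampleRate) || object@sampleRate <= 0)
        return("sampleRate must be positive")
    TRUE
})

#' @param current Numeric vector, pA.
#' @param sampleRate Hz.
#' @return A `CurrentTrace` object.
#' @rdname CurrentTrace-class
#' @export
currentTrace <- function(current, sampleRate) {
    new("CurrentTrace", current = as.numeric(current),
        sampleRate = as.numeric(sampleRate))
}

#' @param object A `CurrentTrace`.
#' @rdname CurrentTrace-class
#' @export
setGeneric("currents", function(object) standardGeneric("currents"))

#' @rdname CurrentTrace-class
#' @export
setMethod("currents", "CurrentTrace", function(object) object@current)

#' @rdname CurrentTrace-class
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname CurrentTrace-class
#' @export
setMethod("sampleRate", "CurrentTrace", function(object) object@sampleRate)

#' @rdname CurrentTrace-class
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname CurrentTrace-class
#' @export
setMethod("sampleTimes", "CurrentTrace", function(object)
    (seq_along(object@current) - 1) / object@sampleRate)

#' @rdname CurrentTrace-class
#' @param x A `CurrentTrace`.
#' @export
setMethod("length", "CurrentTrace", function(x) length(x@current))

setMethod("show", "CurrentTrace", function(object) {
    cat(sprintf("CurrentTrace: %d samples @ %g Hz (%.4g s), range [%.4g, %.4g] pA\n",
                length(object@current), object@sampleRate,
                length(object@current) / object@sampleRate,
                min(object@current), max(object@current)))
})

#' Uniform prior with physiological rate constraints
#'
#' Box bounds of the uniform prior over the nine channel parameters plus
#' the rate bounds and voltage window of the physiological constraints:
#' each of the four transition rates evaluated at the extreme protocol
#' voltages must lie strictly inside `rateBounds`.
#'
#' @slot gBounds Conductance bounds, pA/V.
#' @slot prefactorBounds Bounds for p1, p3, p5, p7, 1/s.
#' @slot sensitivityBounds Bounds for p2, p4, p6, p8, 1/V.
#' @slot rateBounds Physiological rate window, 1/s.
#' @slot vMin,vMax Extreme protocol voltages, V.
#' @export
setClass("PriorSpec", representation(
    gBounds = "numeric", prefactorBounds = "numeric",
    sensitivityBounds = "numeric", rateBounds = "numeric",
    vMin = "numeric", vMax = "numeric"))

setValidity("PriorSpec", function(object) {
    for (nm in c("gBounds", "prefactorBounds", "sensitivityBounds", "rateBounds")) {
        b <- slot(object, nm)
        if (length(b) != 2L || !all(is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
            return(sprintf("%s must be positive (lo, hi) with lo < hi", nm))
    }
    if (object@vMin >= object@vMax)
        return("vMin must be below vMax")
    TRUE
})

#' @param gBounds,prefactorBounds,sensitivityBounds,rateBounds,vMin,vMax
#'   See class slots; defaults are the standard study values.
#' @return A `PriorSpec` object.
#' @rdname PriorSpec-class
#' @export
priorSpec <- function(gBounds = c(100, 5e5),
                      prefactorBounds = c(1e-4, 1e6),
                      sensitivityBounds = c(1e-4, 400),
                      rateBounds = c(1.67e-2, 1e6),
                      vMin = -0.12, vMax = 0.06) {
    new("PriorSpec", gBounds = gBounds, prefactorBounds = prefactorBounds,
        sensitivityBounds = sensitivityBounds, rateBounds = rateBounds,
        vMin = vMin, vMax = vMax)
}

setMethod("show", "PriorSpec", function(object) {
    cat(sprintf(paste0(
        "PriorSpec: g in [%g, %g] pA/V; prefactors in [%g, %g] 1/s;\n",
        "  sensitivities in [%g, %g] 1/V; rates in (%g, %g) 1/s at V in [%g, %g]\n"),
        object@gBounds[1], object@gBounds[2],
        object@prefactorBounds[1], object@prefactorBounds[2],
        object@sensitivityBounds[1], object@sensitivityBounds[2],
        object@rateBounds[1], object@rateBounds[2], object@vMin, object@vMax))
})

#' Parameter normalization for the learning space
#'
#' Deterministic transform from raw parameters to the [0,1]^9 learning
#' space: decade-spanning components (`g_Kr` and the rate prefactors) are
#' log10-scaled, then every component is min-max normalized with bounds
#' derived from a `PriorSpec` (never from a data batch).
#'
#' @slot logFlags Logical(9): apply log10 to this component.
#' @slot lo,hi Numeric(9): normalization bounds in transformed space.
#' @export
setClass("NormalizationSpec", representation(
    logFlags = "logical", lo = "numeric", hi = "numeric"))

setValidity("NormalizationSpec", function(object) {
    if (length(object@logFlags) != 9L || length(object@lo) != 9L ||
        length(object@hi) != 9L)
        return("logFlags, lo, hi must have length 9")
    if (any(object@lo >= object@hi))
        return("lo must be strictly below hi componentwise")
    TRUE
})

#' @param spec A `PriorSpec` the bounds are derived from.
#' @param logConductance Log10-scale `g_Kr` as well as the prefactors?
#'   Default TRUE (it spans 3.7 decades).
#' @return A `NormalizationSpec`.
#' @rdname NormalizationSpec-class
#' @export
normalizationSpec <- function(spec = priorSpec(), logConductance = TRUE) {
    stopifnot(is(spec, "PriorSpec"))
    logFlags <- c(logConductance, rep(c(TRUE, FALSE), 4))
    lo <- c(spec@gBounds[1], rep(c(spec@prefactorBounds[1],
                                   spec@sensitivityBounds[1]), 4))
    hi <- c(spec@gBounds[2], rep(c(spec@prefactorBounds[2],
                                   spec@sensitivityBounds[2]), 4))
    lo[logFlags] <- log10(lo[logFlags])
    hi[logFlags] <- log10(hi[logFlags])
    names(lo) <- names(hi) <- names(logFlags) <- .PARAM_NAMES
    new("NormalizationSpec", logFlags = logFlags, lo = lo, hi = hi)
}

setMethod("show", "NormalizationSpec", function(object) {
    cat("NormalizationSpec (min-max on [0,1], log10 where flagged):\n")
    print(data.frame(log10 = object@logFlags, lo = object@lo, hi = object@hi))
})

#' Additive Gaussian recording-noise model
#'
#' Zero-mean iid Gaussian noise added to simulated currents to emulate
#' patch-clamp recording noise. The default standard deviation is the
#' value measured at steady-state current in the experimental recordings
#' this pipeline emulates.
#'
#' @slot sigma Noise standard deviation, pA (>= 0).
#' @export
setClass("NoiseModel", representation(sigma = "numeric"))

setValidity("NoiseModel", function(object) {
    if (!is.finite(object@sigma) || object@sigma < 0)
        return("sigma must be finite and >= 0")
    TRUE
})

#' @param sigma Noise SD in pA, default 10.84.
#' @return A `NoiseModel` object.
#' @rdname NoiseModel-class
#' @export
noiseModel <- function(sigma = 10.84) new("NoiseModel", sigma = sigma)

#' @param object A `NoiseModel`.
#' @rdname NoiseModel-class
#' @export
setGeneric("noiseSigma", function(object) standardGeneric("noiseSigma"))

#' @rdname NoiseModel-class
#' @export
setMethod("noiseSigma", "NoiseModel", function(object) object@sigma)

setMethod("show", "NoiseModel", function(object)
    cat(sprintf("NoiseModel: additive iid N(0, sigma^2), sigma = %g pA\n",
                object@sigma)))

#' Time-frequency spectrogram of a current trace
#'
#' Non-negative magnitude spectrogram (after log1p compression) with
#' frequency bins in rows and time frames in columns.
#'
#' @slot grid Non-negative numeric matrix (freq bins x time frames).
#' @slot stftParams Named list: nFFT, hop, win (samples).
#' @export
setClass("Spectrogram", representation(grid = "matrix", stftParams = "list"))

setValidity("Spectrogram", function(object) {
    if (!is.numeric(object@grid))
        return("grid must be numeric")
    if (!all(is.finite(object@grid)) || any(object@grid < 0))
        return("grid entries must be finite and >= 0")
    TRUE
})

#' @param grid Non-negative matrix.
#' @param stftParams Named list of STFT parameters (may be empty for
#'   resized grids).
#' @return A `Spectrogram` object.
#' @rdname Spectrogram-class
#' @export
spectrogram <- function(grid, stftParams = list()) {
    new("Spectrogram", grid = grid, stftParams = stftParams)
}

#' @param object A `Spectrogram`.
#' @rdname Spectrogram-class
#' @export
setGeneric("specGrid", function(object) standardGeneric("specGrid"))

#' @rdname Spectrogram-class
#' @export
setMethod("specGrid", "Spectrogram", function(object) object@grid)

#' @rdname Spectrogram-class
#' @param x A `Spectrogram`.
#' @export
setMethod("dim", "Spectrogram", function(x) dim(x@grid))

setMethod("show", "Spectrogram", function(object) {
    cat(sprintf("Spectrogram: %d freq bins x %d frames, max %.4g\n",
                nrow(object@grid), ncol(object@grid), max(object@grid)))
})

#' Result of a single CMA-ES model fit
#'
#' @slot thetaHat Fitted `ChannelParams`.
#' @slot rmse Residual root-mean-square error, pA.
#' @slot iterations CMA-ES generations used.
#' @slot evaluations Objective evaluations used.
#' @slot status One of "converged", "local_minimum", "failed".
#' @slot initializer Label of the initializer that produced the start point.
#' @slot seed Integer seed used by the optimizer.
#' @export
setClass("FitResult", representation(
    thetaHat = "ChannelParams", rmse = "numeric", iterations = "numeric",
    evaluations = "numeric", status = "character", initializer = "character",
    seed = "numeric"))

setValidity("FitResult", function(object) {
    if (!object@status %in% c("converged", "local_minimum", "failed"))
        return("status must be converged, local_minimum or failed")
    if (object@status != "failed" && object@iterations < 1)
        return("non-failed fits must report at least one iteration")
    TRUE
})

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult [%s]: status=%s rmse=%.4g pA iters=%d evals=%d\n",
                object@initializer, object@status, object@rmse,
                as.integer(object@iterations), as.integer(object@evaluations)))
})

#' @param object A `FitResult`.
#' @rdname FitResult-class
#' @export
setGeneric("fitStatus", function(object) standardGeneric("fitStatus"))

#' @rdname FitResult-class
#' @export
setMethod("fitStatus", "FitResult", function(object) object@status)

#' @rdname FitResult-class
#' @export
setGeneric("fittedParams", function(object) standardGeneric("fittedParams"))

#' @rdname FitResult-class
#' @export
setMethod("fittedParams", "FitResult", function(object) object@thetaHat)

#' Labelled synthetic dataset of (trace, parameters) pairs
#'
#' Rows are training examples: `traces` holds the downsampled noisy
#' current traces (pA), `targets` the normalized parameter vectors in
#' [0,1]^9 and `thetaRaw` the raw parameters. `manifest` records full
#' provenance (seed, prior, protocol hash, noise sigma, downsample factor).
#'
#' @slot traces n x L numeric matrix, pA.
#' @slot targets n x 9 numeric matrix in [0,1].
#' @slot thetaRaw n x 9 numeric matrix, raw parameter scale.
#' @slot sampleRate Sampling rate of the stored traces, Hz.
#' @slot manifest Named list of provenance metadata.
#' @export
setClass("HergDataset", representation(
    traces = "matrix", targets = "matrix", thetaRaw = "matrix",
    sampleRate = "numeric", manifest = "list"))

setValidity("HergDataset", function(object) {
    n <- nrow(object@traces)
    if (nrow(object@targets) != n || nrow(object@thetaRaw) != n)
        return("traces, targets, thetaRaw must have equal row counts")
    if (ncol(object@targets) != 9L || ncol(object@thetaRaw) != 9L)
        return("targets and thetaRaw must have 9 columns")
    if (!all(is.finite(object@traces)))
        return("all trace samples must be finite")
    if (any(object@targets < 0 | object@targets > 1))
        return("targets must lie in [0,1]")
    TRUE
})

setMethod("show", "HergDataset", function(object) {
    cat(sprintf("HergDataset: %d examples, trace length %d @ %g Hz\n",
                nrow(object@traces), ncol(object@traces), object@sampleRate))
})

#' @param object A `HergDataset`.
#' @rdname HergDataset-class
#' @export
setGeneric("nExamples", function(object) standardGeneric("nExamples"))

#' @rdname HergDataset-class
#' @export
setMethod("nExamples", "HergDataset", function(object) nrow(object@traces))

#' Trained spectrogram-to-parameters regressor
#'
#' A small convolutional network mapping current spectrograms to the
#' normalized nine-parameter vector, together with its configuration,
#' the normalization transform it was trained against, and its per-epoch
#' training log.
#'
#' @slot weights Named list of weight arrays.
#' @slot config Named list (architecture, schedule, optimizer settings).
#' @slot norm The `NormalizationSpec` used for the targets.
#' @slot trainingLog Data frame of per-epoch train/validation losses.
#' @export
setClass("TrainedRegressor", representation(
    weights = "list", config = "list", norm = "NormalizationSpec",
    trainingLog = "data.frame"))

setMethod("show", "TrainedRegressor", function(object) {
    nW <- sum(vapply(object@weights, length, integer(1)))
    last <- tail(object@trainingLog, 1)
    cat(sprintf("TrainedRegressor: %d weights, %d logged epochs", nW,
                nrow(object@trainingLog)))
    if (nrow(last))
        cat(sprintf(", final val MSE %.4g", last$valMSE))
    cat("\n")
})

#' @param object A `TrainedRegressor`.
#' @rdname TrainedRegressor-class
#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))

#' @rdname TrainedRegressor-class
#' @export
setMethod("trainingLog", "TrainedRegressor", function(object) object@trainingLog)

#' Posterior chain from adaptive Metropolis sampling
#'
#' @slot samples n x 9 matrix of raw-scale parameters (post burn-in).
#' @slot normalized n x 9 matrix of the same states in normalized space.
#' @slot acceptance Overall acceptance rate.
#' @slot nBurn Number of burn-in iterations discarded.
#' @export
setClass("PosteriorChain", representation(
    samples = "matrix", normalized = "matrix", acceptance = "numeric",
    nBurn = "numeric"))

setMethod("show", "PosteriorChain", function(object) {
    cat(sprintf("PosteriorChain: %d retained samples, acceptance %.3f (burn-in %d)\n",
                nrow(object@samples), object@acceptance, as.integer(object@nBurn)))
})
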