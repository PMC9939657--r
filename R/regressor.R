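#' Regressor configuration
#'
#' Architecture, featurization and training-schedule settings for the
#' spectrogram-to-parameters regressor. The default backbone is a small
#' convolutional network (three 3x3 conv blocks with max pooling, an
#' adaptive average pool to a fixed 6x6 grid — making the conv stack
#' independent of input resolution — and a two-layer dense head).
#' Training follows a two-stage schedule: a lower resolution on a subset
#' of the data first, then the full set at higher resolution reusing the
#' weights (the transfer step); the adaptive pooling is what lets the
#' weights transfer across resolutions.
#'
#' @param backbone `"small_cnn"` (the only backbone shipped; a
#'   large pretrained backbone is out of scope without GPU-scale
#'   training).
#' @param channels Conv widths per block.
#' @param poolDim Side of the adaptive average-pool grid.
#' @param hidden Width of the dense hidden layer.
#' @param batchSize,learningRate Adam minibatch settings.
#' @param seed Integer seed for initialization and shuffling.
#' @param schedule List of stages, each
#'   `list(resolution =, fraction =, epochs =)` with an optional
#'   per-stage `lr` overriding `learningRate` (the transfer stage
#'   defaults to a halved rate).
#' @param nFFT,hop,win,inputScale STFT featurization settings (see
#'   [stftSpectrogram()]).
#' @return Named list of class settings for [trainRegressor()].
#' @export
regressorConfig <- function(backbone = "small_cnn",
                            channels = c(12, 24, 48), poolDim = 6,
                            hidden = 96, batchSize = 32,
                            learningRate = 1e-3, seed = 1,
                            schedule = list(
                                list(resolution = 33, fraction = 0.6, epochs = 16),
                                list(resolution = 49, fraction = 1.0, epochs = 10,
                                     lr = 5e-4)),
                            nFFT = 256, hop = 12, win = 48,
                            inputScale = 1e4) {
    stopifnot(identical(backbone, "small_cnn"), length(schedule) >= 1,
              all(vapply(schedule, function(s) s$resolution, 1) > 0))
    list(backbone = backbone, channels = channels, poolDim = poolDim,
         hidden = hidden, batchSize = batchSize,
         learningRate = learningRate, seed = seed, schedule = schedule,
         nFFT = nFFT, hop = hop, win = win, inputScale = inputScale)
}

#' Mean squared error over a batch of parameter vectors
#'
#' J = (1/N) * sum_i || pred_i - target_i ||^2, the training loss of the
#' regressor: squared Euclidean distance in the normalized parameter
#' space, averaged over the batch.
#'
#' @param pred,target Numeric matrices of equal shape (vectors are
#'   treated as single-row batches). Rows are examples.
#' @return Scalar loss.
#' @examples
#' mseLoss(c(0, 0, 1), c(0, 0, 0))   # 1
#' @export
mseLoss <- function(pred, target) {
    if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1)
    if (is.null(dim(target))) target <- matrix(target, nrow = 1)
    if (!identical(dim(pred), dim(target)))
        stop("pred and target must have identical shapes")
    sum((pred - target)^2) / nrow(pred)
}

# Featurize rows of a trace matrix into an (res, res, n) array.
.traceMatrixFeatures <- function(traces, sampleRate, resolution, config) {
    n <- nrow(traces)
    X <- array(0, c(resolution, resolution, n))
    for (i in seq_len(n)) {
        sp <- traceFeatures(currentTrace(traces[i, ], sampleRate),
                            resolution = resolution, nFFT = config$nFFT,
                            hop = config$hop, win = config$win,
                            scale = config$inputScale)
        X[, , i] <- sp@grid
    }
    X
}

#' Train the spectrogram-to-parameters regressor
#'
#' Runs the staged training schedule of `config` on a labelled dataset:
#' each stage featurizes the (seeded, subsampled) training traces at its
#' resolution and continues Adam/MSE optimization from the previous
#' stage's weights. Per-epoch train and validation MSE are logged.
#' Deterministic given `config$seed`.
#'
#' @param config A [regressorConfig()] list.
#' @param trainData,valData [HergDataset-class] objects; `valData` is
#'   only ever used for evaluation.
#' @return A [TrainedRegressor-class] object.
#' @export
trainRegressor <- function(config, trainData, valData) {
    stopifnot(is(trainData, "HergDataset"), is(valData, "HergDataset"),
              nExamples(trainData) >= 1, nExamples(valData) >= 1)
    nConv <- length(config$channels)
    w <- .nnInit(config$channels, config$poolDim, config$hidden, 9L,
                 seed = config$seed)
    adam <- .adamInit(w)
    logRows <- list()
    nTrain <- nExamples(trainData)
    yAll <- t(trainData@targets)                     # 9 x n
    for (si in seq_along(config$schedule)) {
        stage <- config$schedule[[si]]
        nUse <- max(1L, min(nTrain, round(stage$fraction * nTrain)))
        idxUse <- if (nUse < nTrain)
            .withSeed(.subSeed(config$seed, 401L, si),
                      sample.int(nTrain, nUse))
        else seq_len(nTrain)
        X <- .traceMatrixFeatures(trainData@traces[idxUse, , drop = FALSE],
                                  trainData@sampleRate, stage$resolution,
                                  config)
        y <- yAll[, idxUse, drop = FALSE]
        Xval <- .traceMatrixFeatures(valData@traces, valData@sampleRate,
                                     stage$resolution, config)
        yval <- t(valData@targets)
        stageLR <- if (!is.null(stage$lr)) stage$lr else config$learningRate
        for (epoch in seq_len(stage$epochs)) {
            ord <- .withSeed(.subSeed(config$seed, 402L, si, epoch),
                             sample.int(nUse))
            batchStarts <- seq(1L, nUse, by = config$batchSize)
            lossSum <- 0
            nSeen <- 0L
            for (bs in batchStarts) {
                sel <- ord[bs:min(bs + config$batchSize - 1L, nUse)]
                fw <- .nnForward(w, X[, , sel, drop = FALSE], nConv,
                                 config$poolDim, keepCache = TRUE)
                resid <- fw$pred - y[, sel, drop = FALSE]
                loss <- sum(resid^2) / length(sel)
                if (!is.finite(loss)) {
                    cond <- structure(
                        class = c("hergTrainError", "error", "condition"),
                        list(message = sprintf(
                            "training diverged at stage %d epoch %d", si, epoch),
                            call = sys.call(), checkpoint = w))
                    stop(cond)
                }
                lossSum <- lossSum + loss * length(sel)
                nSeen <- nSeen + length(sel)
                g <- .nnBackward(w, fw, 2 * resid / length(sel), nConv,
                                 config$poolDim)
                upd <- .adamStep(w, g, adam, stageLR)
                w <- upd$w
                adam <- upd$state
            }
            valPred <- .nnForward(w, Xval, nConv, config$poolDim)$pred
            logRows[[length(logRows) + 1L]] <- data.frame(
                stage = si, resolution = stage$resolution, epoch = epoch,
                trainMSE = lossSum / nSeen,
                valMSE = sum((valPred - yval)^2) / ncol(yval))
        }
    }
    norm <- normalizationSpec(priorSpec())
    if (!is.null(trainData@manifest$prior)) {
        pr <- trainData@manifest$prior
        norm <- normalizationSpec(priorSpec(
            gBounds = pr$gBounds, prefactorBounds = pr$prefactorBounds,
            sensitivityBounds = pr$sensitivityBounds,
            rateBounds = pr$rateBounds, vMin = pr$vMin, vMax = pr$vMax))
    }
    finalRes <- config$schedule[[length(config$schedule)]]$resolution
    config$inputResolution <- finalRes
    new("TrainedRegressor", weights = w, config = config, norm = norm,
        trainingLog = do.call(rbind, logRows))
}

#' Predict normalized parameters from a trace or spectrogram
#'
#' Runs the trained network forward. A [CurrentTrace-class] input is
#' featurized with the model's own featurization settings at its input
#' resolution; a [Spectrogram-class] input must already have that
#' resolution (a mismatch is an error). Output is clipped to [0, 1]^9.
#'
#' @param model A [TrainedRegressor-class] object.
#' @param input A [CurrentTrace-class], a [Spectrogram-class], or a list
#'   of either.
#' @param type `"normalized"` for the raw [0,1]^9 vector(s),
#'   `"theta"` to de-normalize into [ChannelParams-class] object(s).
#' @return For a single input: a named numeric(9) (or `ChannelParams`).
#'   For a list: a matrix with one row per input (or a list of
#'   `ChannelParams`).
#' @export
predictParams <- function(model, input, type = c("normalized", "theta")) {
    stopifnot(is(model, "TrainedRegressor"))
    type <- match.arg(type)
    single <- !is.list(input)
    inputs <- if (single) list(input) else input
    res <- model@config$inputResolution
    X <- array(0, c(res, res, length(inputs)))
    for (i in seq_along(inputs)) {
        obj <- inputs[[i]]
        if (is(obj, "CurrentTrace")) {
            sp <- traceFeatures(obj, resolution = res,
                                nFFT = model@config$nFFT,
                                hop = model@config$hop,
                                win = model@config$win,
                                scale = model@config$inputScale)
        } else if (is(obj, "Spectrogram")) {
            if (!all(dim(obj) == c(res, res)))
                stop(sprintf("spectrogram is %dx%d but the model expects %dx%d",
                             dim(obj)[1], dim(obj)[2], res, res))
            sp <- obj
        } else stop("input must be CurrentTrace or Spectrogram objects")
        X[, , i] <- sp@grid
    }
    pred <- .nnForward(model@weights, X, length(model@config$channels),
                       model@config$poolDim)$pred
    pred <- pmin(pmax(pred, 0), 1)
    rownames(pred) <- .PARAM_NAMES
    if (type == "theta") {
        out <- lapply(seq_len(ncol(pred)), function(i)
            fromNormalized(pred[, i], model@norm))
        return(if (single) out[[1]] else out)
    }
    if (single) pred[, 1] else t(pred)
}

#' Save or load a trained regressor
#'
#' The model file is a single RDS blob embedding the weights, the full
#' configuration, the normalization transform and the training log. A
#' loaded model predicts identically to the saved one.
#'
#' @param model A [TrainedRegressor-class] object.
#' @param path File path.
#' @return `saveRegressor` returns `path` invisibly; `loadRegressor`
#'   returns a [TrainedRegressor-class]. A file that is not a regressor
#'   blob of the current format version is a format error.
#' @export
saveRegressor <- function(model, path) {
    stopifnot(is(model, "TrainedRegressor"))
    saveRDS(list(format = "hergfit-regressor", version = 1L,
                 weights = model@weights, config = model@config,
                 norm = list(logFlags = model@norm@logFlags,
                             lo = model@norm@lo, hi = model@norm@hi),
                 trainingLog = model@trainingLog),
            path, version = 2)
    invisible(path)
}

#' @rdname saveRegressor
#' @export
loadRegressor <- function(path) {
    obj <- tryCatch(readRDS(path), error = function(e)
        stop("not a readable regressor file: ", conditionMessage(e)))
    if (!is.list(obj) || !identical(obj$format, "hergfit-regressor"))
        stop("file is not a hergfit regressor blob")
    if (!identical(obj$version, 1L))
        stop("unsupported regressor format version: ", obj$version)
    norm <- new("NormalizationSpec", logFlags = obj$norm$logFlags,
                lo = obj$norm$lo, hi = obj$norm$hi)
    new("TrainedRegressor", weights = obj$weights, config = obj$config,
        norm = norm, trainingLog = obj$trainingLog)
}
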