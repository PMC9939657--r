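#' Run the full generate-train-benchmark pipeline
#'
#' Orchestrates the end-to-end flow from one configuration: (1) build or
#' read the voltage protocol; (2) generate the labelled synthetic
#' dataset (cached: an existing dataset file whose manifest matches the
#' configuration is reused, so deleting a later artifact only reruns
#' later stages); (3) train the regressor on a train/validation split;
#' (4) benchmark the predicted / prior / random initializers on fresh
#' synthetic cells. Every artifact is written under `outDir` with a
#' manifest, and all randomness derives from the root seed.
#'
#' @param config A named list or path to a YAML/JSON config file. Keys
#'   (all optional, shown with defaults): `seed` (1), `outDir`
#'   ("hergfit-run"), `nTrain` (500), `valFraction` (0.2), `nCells`
#'   (10), `factor` (50), `sampleRate` (5000), `sigma` (10.84),
#'   `protocolCSV` (NULL: default staircase), `maxIter` (300), plus a
#'   `regressor` sublist passed to [regressorConfig()].
#' @param quiet Suppress per-stage messages.
#' @return A list with the benchmark `report` data frame and the paths
#'   of the written artifacts.
#' @export
runPipeline <- function(config = list(), quiet = FALSE) {
    if (is.character(config)) {
        config <- if (grepl("\\.json$", config))
            jsonlite::read_json(config, simplifyVector = TRUE)
        else yaml::read_yaml(config)
    }
    defaults <- list(seed = 1, outDir = "hergfit-run", nTrain = 500,
                     valFraction = 0.2, nCells = 10, factor = 50,
                     sampleRate = 5000, sigma = 10.84,
                     protocolCSV = NULL, maxIter = 300,
                     regressor = list())
    cfg <- utils::modifyList(defaults, config)
    say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)

    protocol <- if (is.null(cfg$protocolCSV)) staircaseProtocol()
                else readProtocolCSV(cfg$protocolCSV)
    protocolPath <- file.path(cfg$outDir, "protocol.csv")
    writeProtocolCSV(protocol, protocolPath)
    spec <- priorSpec()
    noise <- noiseModel(cfg$sigma)

    datasetPath <- file.path(cfg$outDir, "dataset.rds")
    ds <- NULL
    if (file.exists(datasetPath)) {
        ds <- tryCatch(readDataset(datasetPath), error = function(e) NULL)
        if (!is.null(ds)) {
            m <- ds@manifest
            numEq <- function(a, b) isTRUE(all.equal(as.numeric(a),
                                                     as.numeric(b)))
            if (!(numEq(m$n, cfg$nTrain) && numEq(m$seed, cfg$seed) &&
                  numEq(m$sigma, cfg$sigma) && numEq(m$factor, cfg$factor) &&
                  identical(m$protocolHash, .protocolHash(protocol))))
                ds <- NULL
        }
        if (!is.null(ds)) say("stage dataset: reusing %s", datasetPath)
    }
    if (is.null(ds)) {
        say("stage dataset: generating %d examples", cfg$nTrain)
        ds <- tryCatch(
            generateDataset(cfg$nTrain, spec, protocol, noise,
                            factor = cfg$factor,
                            sampleRate = cfg$sampleRate, seed = cfg$seed),
            error = function(e) stop("stage dataset failed (", datasetPath,
                                     "): ", conditionMessage(e)))
        writeDataset(ds, datasetPath)
    }

    nVal <- max(1L, round(cfg$valFraction * nExamples(ds)))
    valIdx <- .withSeed(.subSeed(cfg$seed, 501L),
                        sample.int(nExamples(ds), nVal))
    split <- splitDataset(ds, valIdx)

    modelPath <- file.path(cfg$outDir, "model.rds")
    model <- NULL
    if (file.exists(modelPath))
        model <- tryCatch(loadRegressor(modelPath), error = function(e) NULL)
    if (is.null(model)) {
        say("stage train: %d train / %d val examples",
            nExamples(split$train), nExamples(split$val))
        rcfg <- do.call(regressorConfig,
                        utils::modifyList(list(seed = cfg$seed),
                                          cfg$regressor))
        model <- tryCatch(
            trainRegressor(rcfg, split$train, split$val),
            error = function(e) stop("stage train failed (", modelPath,
                                     "): ", conditionMessage(e)))
        saveRegressor(model, modelPath)
    } else say("stage train: reusing %s", modelPath)

    say("stage benchmark: %d cells, 3 initializers", cfg$nCells)
    cells <- sampleBenchmarkCells(cfg$nCells, spec, protocol, noise,
                                  factor = cfg$factor,
                                  sampleRate = cfg$sampleRate,
                                  seed = .subSeed(cfg$seed, 502L))
    bench <- tryCatch(
        benchmarkInits(cells, model, spec = spec, protocol = protocol,
                       noise = noise, factor = cfg$factor,
                       seed = .subSeed(cfg$seed, 503L),
                       maxIter = cfg$maxIter),
        error = function(e) stop("stage benchmark failed: ",
                                 conditionMessage(e)))
    reportPath <- file.path(cfg$outDir, "report.csv")
    utils::write.csv(bench$report, reportPath, row.names = FALSE)
    jsonlite::write_json(
        list(seed = cfg$seed, nTrain = cfg$nTrain, nCells = cfg$nCells,
             sigma = cfg$sigma, factor = cfg$factor,
             datasetChecksum = unname(tools::md5sum(datasetPath)),
             protocolHash = .protocolHash(protocol)),
        file.path(cfg$outDir, "run-manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("done: report at %s", reportPath)
    list(report = bench$report, fits = bench$fits,
         paths = list(protocol = protocolPath, dataset = datasetPath,
                      model = modelPath, report = reportPath))
}

#' Split a dataset into train and validation parts
#'
#' @param dataset A [HergDataset-class] object.
#' @param valIdx Integer indices of the validation examples, or the
#'   string `"odd"` / `"even"` to split by example parity (the
#'   convention used to split ordered experimental cells into
#'   validation and test sets).
#' @return `list(train =, val =)` of [HergDataset-class] objects.
#' @export
splitDataset <- function(dataset, valIdx) {
    stopifnot(is(dataset, "HergDataset"))
    n <- nExamples(dataset)
    if (is.character(valIdx)) {
        valIdx <- match.arg(valIdx, c("odd", "even"))
        valIdx <- if (valIdx == "odd") seq(1L, n, by = 2L)
                  else seq(2L, n, by = 2L)
    }
    valIdx <- sort(unique(as.integer(valIdx)))
    stopifnot(all(valIdx >= 1), all(valIdx <= n), length(valIdx) < n)
    take <- function(idx) {
        m <- dataset@manifest
        m$n <- length(idx)
        new("HergDataset", traces = dataset@traces[idx, , drop = FALSE],
            targets = dataset@targets[idx, , drop = FALSE],
            thetaRaw = dataset@thetaRaw[idx, , drop = FALSE],
            sampleRate = dataset@sampleRate, manifest = m)
    }
    list(train = take(setdiff(seq_len(n), valIdx)), val = take(valIdx))
}
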