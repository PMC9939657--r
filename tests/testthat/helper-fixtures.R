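# Shared slow fixtures, built once per test session on first use.
.fixtures <- new.env(parent = emptyenv())

.memo <- function(name, builder) {
    if (!exists(name, envir = .fixtures)) {
        assign(name, builder(), envir = .fixtures)
    }
    get(name, envir = .fixtures)
}

# 2,000 labelled synthetic examples at the study defaults (15.4 s, 5 kHz,
# sigma 10.84, decimation 50).
fixtureDataset <- function() {
    .memo("dataset", function() generateDataset(n = 2000, seed = 100))
}

# 1,600 / 400 train/validation split of the fixture dataset.
fixtureSplit <- function() {
    .memo("split", function() splitDataset(fixtureDataset(), seq(1, 2000, by = 5)))
}

# The default small-CNN regressor trained on the fixture split.
fixtureModel <- function() {
    .memo("model", function() {
        sp <- fixtureSplit()
        trainRegressor(regressorConfig(seed = 100), sp$train, sp$val)
    })
}

# A fast literature-typical noisy cell for small inference tests.
fixtureCell <- function() {
    .memo("cell", function() sampleBenchmarkCells(1, seed = 55)[[1]])
}

expectRelEqual <- function(actual, expected, tol) {
    expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
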