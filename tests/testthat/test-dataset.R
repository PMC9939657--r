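test_that("additive noise has the configured spread and zero mean", {
    zero <- currentTrace(numeric(1e5), 5000)
    noisy <- addNoise(zero, noiseModel(), seed = 12)
    s <- sd(currents(noisy))
    expect_lt(abs(s - 10.84) / 10.84, 0.01)
    expect_lt(abs(mean(currents(noisy))), 3 * 10.84 / sqrt(1e5))
    # sigma = 0 leaves the trace untouched; same seed reproduces
    expect_identical(currents(addNoise(zero, noiseModel(0), seed = 1)),
                     currents(zero))
    expect_identical(currents(addNoise(zero, noiseModel(), seed = 12)),
                     currents(noisy))
})

test_that("decimation keeps every factor-th sample from the first", {
    tr <- currentTrace(seq_len(77000), 5000)
    d <- downsampleTrace(tr, 50)
    expect_identical(length(d), 1540L)
    expect_equal(sampleRate(d), 100)
    expect_identical(currents(d)[1:3], c(1, 51, 101))
    expect_identical(currents(downsampleTrace(tr, 1)), currents(tr))
    # composition law when lengths divide evenly
    tr2 <- currentTrace(seq_len(1200), 1200)
    expect_identical(currents(downsampleTrace(downsampleTrace(tr2, 4), 3)),
                     currents(downsampleTrace(tr2, 12)))
    expect_error(downsampleTrace(tr, 0), "factor")
})

test_that("dataset generation is reproducible and correctly labelled", {
    ds1 <- generateDataset(n = 4, seed = 21)
    ds2 <- generateDataset(n = 4, seed = 21)
    expect_identical(ds1@traces, ds2@traces)
    expect_identical(ds1@targets, ds2@targets)
    expect_identical(ncol(ds1@traces), 1540L)
    expect_true(all(ds1@targets >= 0 & ds1@targets <= 1))
    expect_equal(ds1@sampleRate, 100)
    # label consistency: stored trace minus the clean re-simulation is
    # exactly the stored noise realization
    norm <- normalizationSpec()
    for (i in 1:4) {
        th <- channelParams(theta = ds1@thetaRaw[i, ])
        expect_equal(unname(toNormalized(th, norm)), unname(ds1@targets[i, ]),
                     tolerance = 1e-12)
        clean <- downsampleTrace(simulateCurrent(th, staircaseProtocol()), 50)
        resid <- ds1@traces[i, ] - currents(clean)
        expect_lt(abs(sd(resid) - 10.84) / 10.84, 0.05)
    }
})

test_that("dataset containers round trip with their manifest", {
    ds <- generateDataset(n = 3, seed = 8, sampleRate = 500, factor = 5)
    f <- withr::local_tempfile(fileext = ".rds")
    writeDataset(ds, f)
    expect_true(file.exists(paste0(f, ".manifest.json")))
    back <- readDataset(f)
    expect_identical(back@traces, ds@traces)
    expect_identical(back@targets, ds@targets)
    expect_identical(back@manifest$seed, 8)
    expect_identical(back@manifest$sigma, 10.84)
    man <- jsonlite::read_json(paste0(f, ".manifest.json"),
                               simplifyVector = TRUE)
    expect_equal(man$factor, 5)
    notDs <- withr::local_tempfile(fileext = ".rds")
    saveRDS(list(a = 1), notDs)
    expect_error(readDataset(notDs), "not a hergfit dataset")
})

test_that("benchmark cells pass QC and stay physiological", {
    cells <- sampleBenchmarkCells(5, seed = 33)
    for (cell in cells) {
        expect_true(checkConstraints(cell$theta))
        expect_gte(cell$peak, 250)
        expect_identical(length(cell$trace), 1540L)
        # the observed trace is the clean one plus recording noise
        expect_lt(abs(sd(currents(cell$trace) - currents(cell$clean)) - 10.84),
                  1.5)
    }
})
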