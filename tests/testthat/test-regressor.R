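test_that("the batch loss is the mean squared Euclidean error", {
    expect_identical(mseLoss(rep(0, 9), rep(0, 9)), 0)
    p <- rep(0, 9); p[4] <- 1
    expect_identical(mseLoss(p, rep(0, 9)), 1)
    set.seed(2)
    a <- matrix(runif(45), 5); b <- matrix(runif(45), 5)
    per <- vapply(1:5, function(i) mseLoss(a[i, ], b[i, ]), 1)
    expect_equal(mseLoss(a, b), mean(per), tolerance = 1e-12)
    expect_error(mseLoss(a, b[1:3, ]), "shapes")
})

test_that("training beats the constant-mean predictor on held-out data", {
    sp <- fixtureSplit()
    model <- fixtureModel()
    lg <- trainingLog(model)
    expect_true(all(is.finite(lg$trainMSE)))
    finalVal <- tail(lg$valMSE, 1)
    mu <- colMeans(sp$train@targets)
    baseline <- sum((t(sp$val@targets) - mu)^2) / nExamples(sp$val)
    expect_lt(finalVal, baseline)
    # the transfer stage continued to improve on stage one
    expect_lt(finalVal, lg$valMSE[max(which(lg$stage == 1))])
})

test_that("predictions are deterministic, bounded and de-normalizable", {
    model <- fixtureModel()
    cell <- fixtureCell()
    p1 <- predictParams(model, cell$trace)
    p2 <- predictParams(model, cell$trace)
    expect_identical(p1, p2)
    expect_identical(length(p1), 9L)
    expect_true(all(p1 >= 0 & p1 <= 1))
    th <- predictParams(model, cell$trace, type = "theta")
    expect_s4_class(th, "ChannelParams")
    expect_true(all(theta(th) > 0))
    # a spectrogram at the wrong resolution is an argument error
    wrong <- spectrogram(matrix(0.1, 10, 10))
    expect_error(predictParams(model, wrong), "expects")
})

test_that("per-parameter rank correlation is positive on noiseless cells", {
    model <- fixtureModel()
    ds <- generateDataset(n = 200, seed = 900, noise = noiseModel(0))
    pred <- predictParams(model, lapply(seq_len(200), function(i)
        currentTrace(ds@traces[i, ], ds@sampleRate)))
    rc <- vapply(1:9, function(j)
        cor(pred[, j], ds@targets[, j], method = "spearman"), 1)
    expect_gte(sum(rc > 0), 7)
})

test_that("de-normalized predictions beat random prior draws as trace fits", {
    model <- fixtureModel()
    sp <- fixtureSplit()
    pr <- staircaseProtocol()
    wins <- 0
    for (i in 1:50) {
        tr <- currentTrace(sp$val@traces[i, ], sp$val@sampleRate)
        rmsePred <- objectiveRMSE(predictParams(model, tr, type = "theta"),
                                  tr, pr)
        rmseRand <- objectiveRMSE(sampleParams(n = 1, seed = 5000 + i)[[1]],
                                  tr, pr)
        wins <- wins + (rmsePred < rmseRand)
    }
    expect_gte(wins, 40)
})

test_that("a small training set can be memorized", {
    ds <- fixtureDataset()
    small <- splitDataset(ds, 65:nExamples(ds))$train
    cfg <- regressorConfig(seed = 3, batchSize = 16,
                           schedule = list(list(resolution = 33, fraction = 1,
                                                epochs = 300, lr = 3e-3)))
    m <- trainRegressor(cfg, small, small)
    expect_lt(min(trainingLog(m)$trainMSE), 1e-3)
})

test_that("models round trip through their file format", {
    model <- fixtureModel()
    cell <- fixtureCell()
    f <- withr::local_tempfile(fileext = ".rds")
    saveRegressor(model, f)
    back <- loadRegressor(f)
    expect_lt(max(abs(predictParams(back, cell$trace) -
                      predictParams(model, cell$trace))), 1e-6)
    expect_identical(back@config, model@config)
    # a truncated file is a format error
    bytes <- readBin(f, "raw", file.info(f)$size)
    trunc <- withr::local_tempfile(fileext = ".rds")
    writeBin(bytes[1:50], trunc)
    expect_error(loadRegressor(trunc), "not a readable")
    other <- withr::local_tempfile(fileext = ".rds")
    saveRDS(list(format = "something-else"), other)
    expect_error(loadRegressor(other), "not a hergfit regressor")
})
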