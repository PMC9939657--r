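test_that("the objective is zero at the generating parameters of a clean trace", {
    p <- demoParams()
    pr <- staircaseProtocol()
    clean <- downsampleTrace(simulateCurrent(p, pr), 50)
    expect_lt(objectiveRMSE(p, clean, pr), 1e-3)
    # with noise, the residual at the truth is the injected noise
    noisy <- downsampleTrace(addNoise(simulateCurrent(p, pr), noiseModel(),
                                      seed = 4), 50)
    expect_lt(abs(objectiveRMSE(p, noisy, pr) - 10.84) / 10.84, 0.05)
    # a (near-)zero-conductance model leaves the full target as residual
    thZero <- theta(p); thZero[1] <- 1e-12
    expect_equal(objectiveRMSE(channelParams(theta = thZero), noisy, pr),
                 sqrt(mean(currents(noisy)^2)), tolerance = 1e-6)
})

test_that("the objective equals simulate-then-decimate on the observed grid", {
    p <- demoParams()
    pr <- staircaseProtocol()
    noisy <- downsampleTrace(addNoise(simulateCurrent(p, pr), noiseModel(),
                                      seed = 4), 50)
    manual <- sqrt(mean((currents(downsampleTrace(simulateCurrent(p, pr), 50)) -
                         currents(noisy))^2))
    expect_equal(objectiveRMSE(p, noisy, pr, factor = 50), manual,
                 tolerance = 1e-10)
})

test_that("fit outcomes are classified against the noise floor", {
    expect_identical(classifyFit(10.84, 10.84), "converged")
    expect_identical(classifyFit(1.2 * 10.84, 10.84), "converged")
    expect_identical(classifyFit(108.4, 10.84), "local_minimum")
    expect_identical(classifyFit(5, 10.84, solverOk = FALSE), "failed")
    expect_error(classifyFit(1, 0), "sigma")
})

test_that("CMA-ES incumbents never get worse across iterations", {
    set.seed(10)
    fn <- function(x) sum((x - 0.3)^2) + 0.1 * sum(abs(x))
    res <- hergfit:::.cmaes(fn, rep(0.8, 4), sigma0 = 0.2, maxIter = 60,
                            seed = 2)
    expect_true(all(diff(res$history) <= 0))
    expect_equal(res$evaluations, res$iterations * (4 + floor(3 * log(4))))
})

test_that("a fit started at the optimum stays converged with few iterations", {
    cell <- fixtureCell()
    fit <- fitCMAES(cell$trace, staircaseProtocol(), cell$theta, seed = 5,
                    maxIter = 400)
    expect_identical(fitStatus(fit), "converged")
    expect_lt(fit@rmse, 1.2 * 10.84)
    expect_lt(fit@iterations, 350)
})

test_that("infeasible initializers are projected and the fit proceeds", {
    cell <- fixtureCell()
    th <- theta(cell$theta)
    th["p1"] <- 900; th["p2"] <- 390   # extreme rate far above 1e6
    bad <- channelParams(theta = th)
    expect_false(checkConstraints(bad))
    expect_message(
        fit <- fitCMAES(cell$trace, staircaseProtocol(), bad, seed = 6,
                        maxIter = 150),
        "projected")
    expect_true(fitStatus(fit) %in% c("converged", "local_minimum"))
    expect_true(checkConstraints(fittedParams(fit)))
})

test_that("kinetic parameters are recovered from perturbed starts", {
    # lightly decimated traces (500 Hz) so fast inactivation is resolved
    cells <- sampleBenchmarkCells(3, seed = 400, factor = 10)
    pr <- staircaseProtocol()
    for (ci in 1:3) {
        tru <- theta(cells[[ci]]$theta)
        flips <- hergfit:::.withSeed(hergfit:::.subSeed(400, 88L, ci),
                                     sample(c(-1, 1), 9, TRUE))
        init <- channelParams(theta = tru * 1.5^flips)
        fit <- fitCMAES(cells[[ci]]$trace, pr, init, factor = 10,
                        seed = hergfit:::.subSeed(400, 89L, ci))
        rel <- abs(theta(fittedParams(fit)) - tru) / tru
        expect_lt(max(rel[2:9]), 0.10)
    }
})

test_that("adaptive Metropolis explores the posterior around the truth", {
    cell <- fixtureCell()
    chain <- adaptiveMetropolis(cell$trace, staircaseProtocol(), cell$theta,
                                nSamples = 20000, seed = 7, nBurn = 5000)
    expect_gt(chain@acceptance, 0.05)
    expect_lt(chain@acceptance, 0.6)
    expect_true(all(chain@normalized >= 0 & chain@normalized <= 1))
    tru <- toNormalized(cell$theta)
    z <- abs(colMeans(chain@normalized) - tru) /
        apply(chain@normalized, 2, sd)
    expect_true(all(z < 3))
    badTheta <- theta(cell$theta)
    badTheta["p1"] <- 900; badTheta["p2"] <- 390
    expect_error(
        adaptiveMetropolis(cell$trace, staircaseProtocol(),
                           channelParams(theta = badTheta),
                           nSamples = 100, seed = 1),
        "feasible")
})

test_that("the initializer benchmark aggregates complete outcome counts", {
    model <- fixtureModel()
    cells <- sampleBenchmarkCells(3, seed = 77)
    bench <- benchmarkInits(cells, model, seed = 78, maxIter = 120)
    rep <- bench$report
    expect_identical(rep$initializer, c("predicted", "prior", "random"))
    expect_true(all(rep$nFailures + rep$nLocalMinima + rep$nConverged ==
                    rep$nCells))
    expect_true(all(rep$nCells == 3))
    expect_identical(length(bench$fits), 3L)
    expect_error(benchmarkInits(list(), model), "length")
})
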