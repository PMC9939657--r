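test_that("Nernst potential matches direct evaluation and its symmetries", {
    # independent scalar evaluation of (RT/zF) ln(Kout/Kin) with the
    # printed constants
    expected <- (8.314472 * 298.15) / (1 * 96485.3415) * log(4 / 110)
    expect_equal(nernstPotential(), expected, tolerance = 1e-12)
    expect_equal(nernstPotential(), -0.08515, tolerance = 2e-5)
    expect_lt(nernstPotential(), 0)
    expect_identical(nernstPotential(physicalConstants(K_out = 7, K_in = 7)), 0)
    expect_equal(nernstPotential(physicalConstants(K_out = 110, K_in = 4)),
                 -nernstPotential(), tolerance = 1e-15)
    expect_error(physicalConstants(K_out = -1), "positive")
})

test_that("constants can be overridden from a key=value file", {
    f <- withr::local_tempfile(lines = c("# override", "T = 310", "K_out=5.4"))
    cst <- physicalConstants(file = f)
    expect_equal(cst@T, 310)
    expect_equal(cst@K_out, 5.4)
    expect_equal(cst@K_in, 110)
    bad <- withr::local_tempfile(lines = "Q = 3")
    expect_error(physicalConstants(file = bad), "unknown constant")
})

test_that("transition rates follow the four exponential rate laws", {
    p <- demoParams()
    th <- theta(p)
    k0 <- transitionRates(p, 0)
    expect_equal(unname(k0), unname(th[c("p1", "p3", "p5", "p7")]))
    # p1 = 1, p2 = 100 at V = 0.06 gives k1 = e^6
    p2 <- channelParams(theta = c(1000, 1, 100, th[4:9]))
    expect_equal(transitionRates(p2, 0.06)[["k1"]], exp(6), tolerance = 1e-12)
    expect_equal(transitionRates(p2, 0.06)[["k1"]], 403.4288, tolerance = 1e-7)
    # monotonicity on a voltage grid
    ks <- transitionRates(p, seq(-0.12, 0.06, length.out = 25))
    expect_true(all(diff(ks["k1", ]) > 0))
    expect_true(all(diff(ks["k2", ]) < 0))
    expect_true(all(ks > 0))
    # exponent overflow is a simulation-infeasibility error
    pBig <- channelParams(theta = c(1000, 1, 1e5, th[4:9]))
    expect_error(transitionRates(pBig, 0.06), class = "hergSimError")
})

test_that("gate equilibria and time constants follow from the rates", {
    eq <- gateEquilibria(c(k1 = 2, k2 = 2, k3 = 5, k4 = 5))
    expect_equal(eq[["a_inf"]], 0.5)
    expect_equal(eq[["r_inf"]], 0.5)
    eq2 <- gateEquilibria(c(k1 = 3, k2 = 1, k3 = 1, k4 = 1))
    expect_equal(eq2[["a_inf"]], 0.75)
    expect_equal(eq2[["tau_a"]], 0.25)
    expect_true(all(eq2[c("a_inf", "r_inf")] > 0 &
                    eq2[c("a_inf", "r_inf")] < 1))
})

test_that("state occupancies sum to one and stay in [0,1]", {
    for (a in c(0, 0.3, 1)) for (r in c(0, 0.7, 1)) {
        pr <- stateProbabilities(gateState(a, r))
        expect_equal(sum(pr), 1, tolerance = 1e-15)
        expect_true(all(pr >= 0 & pr <= 1))
    }
    expect_error(gateState(1.2, 0.5), "0, 1")
})

test_that("instantaneous current is ohmic in the open state", {
    p <- demoParams()
    E <- nernstPotential()
    expect_identical(instantaneousCurrent(p, gateState(0.4, 0.8), E, E), 0)
    expect_identical(instantaneousCurrent(p, gateState(0, 0.8), 0.02, E), 0)
    g1000 <- channelParams(theta = c(1000, theta(p)[2:9]))
    expect_equal(instantaneousCurrent(g1000, gateState(0.5, 0.5), 0.02,
                                      -0.08515),
                 1000 * 0.25 * 0.10515, tolerance = 1e-12)
})

test_that("held-voltage simulations relax to the analytic steady state", {
    p <- demoParams()
    E <- nernstPotential()
    for (V in c(-0.12, -0.04, 0.06)) {
        eq <- gateEquilibria(transitionRates(p, V))
        hold <- voltageProtocol(12 * max(eq[["tau_a"]], eq[["tau_r"]]), V)
        closed <- theta(p)[["g_Kr"]] * eq[["a_inf"]] * eq[["r_inf"]] * (V - E)
        for (method in c("analytic", "ode")) {
            tr <- simulateCurrent(p, hold, sampleRate = 60 / totalDuration(hold),
                                  method = method)
            expect_equal(tail(currents(tr), 1), closed,
                         tolerance = 1e-3, ignore_attr = TRUE)
        }
    }
})

test_that("the analytic and adaptive-ODE simulators agree on the staircase", {
    p <- demoParams()
    pr <- staircaseProtocol()
    a <- currents(simulateCurrent(p, pr, sampleRate = 200))
    o <- currents(simulateCurrent(p, pr, sampleRate = 200, method = "ode"))
    expect_lt(sqrt(mean((a - o)^2)) / sqrt(mean(a^2)), 1e-4)
    # grid refinement: tightening tolerances moves the ODE trace by < 1e-4
    # relative RMS
    o2 <- currents(simulateCurrent(p, pr, sampleRate = 200, method = "ode",
                                   absTol = 1e-10, relTol = 1e-12))
    expect_lt(sqrt(mean((o - o2)^2)) / sqrt(mean(o^2)), 1e-4)
})

test_that("simulated traces scale linearly in conductance and keep gates in [0,1]", {
    p <- demoParams()
    pr <- staircaseProtocol()
    tr1 <- currents(simulateCurrent(p, pr, sampleRate = 100))
    th2 <- theta(p); th2[1] <- 2 * th2[1]
    tr2 <- currents(simulateCurrent(channelParams(theta = th2), pr,
                                    sampleRate = 100))
    expect_equal(tr2, 2 * tr1, tolerance = 1e-12)
    traj <- hergfit:::.gateTrajectory(p, pr, seq(0, 15.39, by = 0.01))
    expect_true(all(traj$a >= 0 & traj$a <= 1))
    expect_true(all(traj$r >= 0 & traj$r <= 1))
})

test_that("prior-sampled parameters simulate without failure on the staircase", {
    pr <- staircaseProtocol()
    for (p in sampleParams(n = 100, seed = 17)) {
        tr <- simulateCurrent(p, pr, sampleRate = 100)
        expect_true(all(is.finite(currents(tr))))
    }
})

test_that("trace CSV round trip preserves samples and rate", {
    tr <- simulateCurrent(demoParams(), staircaseProtocol(), sampleRate = 50)
    f <- withr::local_tempfile(fileext = ".csv")
    writeTraceCSV(tr, f)
    back <- readTraceCSV(f)
    expect_equal(currents(back), currents(tr), tolerance = 1e-12)
    expect_equal(sampleRate(back), 50, tolerance = 1e-9)
})
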