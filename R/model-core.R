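#' Potassium Nernst (reversal) potential
#'
#' Computes E_K = (R T)/(z F) * ln([K+]_o / [K+]_i), the voltage at which
#' net potassium flux through the open channel is zero. With the default
#' constants (room temperature, 4 mM external / 110 mM internal K+) this
#' is about -85.2 mV.
#'
#' @param constants A [PhysicalConstants-class] object.
#' @return Reversal potential in volts (negative for the defaults).
#' @examples
#' nernstPotential()           # about -0.08515 V
#' @export
nernstPotential <- function(constants = physicalConstants()) {
    stopifnot(is(constants, "PhysicalConstants"))
    validObject(constants)
    (constants@R * constants@T) / (constants@z * constants@F) *
        log(constants@K_out / constants@K_in)
}

# Largest exponent magnitude allowed in the rate laws before the
# evaluation is flagged as simulation-infeasible.
.EXP_CLAMP <- 700

#' Voltage-dependent transition rates of the hERG gates
#'
#' Evaluates the four exponential rate laws
#' k1 = p1 exp(p2 V), k2 = p3 exp(-p4 V), k3 = p5 exp(p6 V),
#' k4 = p7 exp(-p8 V). k1/k2 drive activation/deactivation of the `a`
#' gate; k3/k4 drive inactivation/recovery of the `r` gate.
#'
#' An exponent of magnitude above 700 would overflow double precision;
#' such evaluations raise a simulation-infeasibility error (condition
#' class `hergSimError`) that the fitter treats as a failed candidate.
#'
#' @param params A [ChannelParams-class] object.
#' @param V Membrane voltage, volts (finite scalar or vector).
#' @return If `V` is scalar, a named numeric vector (k1..k4) in 1/s;
#'   if `V` is a vector, a 4-row matrix with one column per voltage.
#' @examples
#' transitionRates(demoParams(), 0)     # (p1, p3, p5, p7) at V = 0
#' @export
transitionRates <- function(params, V) {
    stopifnot(is(params, "ChannelParams"), all(is.finite(V)))
    th <- params@theta
    ex <- rbind(th["p2"] * V, -th["p4"] * V, th["p6"] * V, -th["p8"] * V)
    if (any(abs(ex) > .EXP_CLAMP))
        .stopWithClass("hergSimError",
                       "rate-law exponent exceeds %g: simulation infeasible",
                       .EXP_CLAMP)
    k <- c(th["p1"], th["p3"], th["p5"], th["p7"]) * exp(ex)
    rownames(k) <- c("k1", "k2", "k3", "k4")
    if (length(V) == 1L) k[, 1] else k
}

#' Steady states and time constants of the gating variables
#'
#' For rates (k1..k4) at a fixed voltage, returns the gate equilibria
#' a_inf = k1/(k1+k2), r_inf = k4/(k3+k4) and the relaxation time
#' constants tau_a = 1/(k1+k2), tau_r = 1/(k3+k4).
#'
#' @param rates Named numeric vector (k1..k4) as returned by
#'   [transitionRates()], or a 4-row matrix of rate columns.
#' @return Named numeric vector (or 4-row matrix) with components
#'   `a_inf`, `r_inf`, `tau_a`, `tau_r`.
#' @export
gateEquilibria <- function(rates) {
    m <- if (is.matrix(rates)) rates else matrix(rates, nrow = 4)
    stopifnot(nrow(m) == 4, all(is.finite(m)), all(m > 0))
    sa <- m[1, ] + m[2, ]
    sr <- m[3, ] + m[4, ]
    out <- rbind(a_inf = m[1, ] / sa, r_inf = m[4, ] / sr,
                 tau_a = 1 / sa, tau_r = 1 / sr)
    if (ncol(out) == 1L) out[, 1] else out
}

#' Occupancies of the four channel states
#'
#' In the two-gate Hodgkin-Huxley structure the channel is open (O) with
#' probability a*r; the remaining occupancy splits into closed (C),
#' inactivated (I) and closed-inactivated (CI) states. The four
#' occupancies sum to 1 identically.
#'
#' @param state A [GateState-class] object.
#' @return Named numeric vector with components `CI`, `I`, `O`, `C`:
#'   (1-r)(1-a), a(1-r), a r, r(1-a).
#' @export
stateProbabilities <- function(state) {
    stopifnot(is(state, "GateState"))
    validObject(state)
    a <- state@a; r <- state@r
    c(CI = (1 - r) * (1 - a), I = a * (1 - r), O = a * r, C = r * (1 - a))
}

#' Instantaneous hERG current
#'
#' Ohmic open-channel current I_Kr = g_Kr * a * r * (V - E_K).
#'
#' @param params A [ChannelParams-class] object.
#' @param state A [GateState-class] object.
#' @param V Membrane voltage, volts.
#' @param E_K Reversal potential, volts (default from standard constants).
#' @return Current in pA.
#' @export
instantaneousCurrent <- function(params, state, V,
                                 E_K = nernstPotential()) {
    stopifnot(is(params, "ChannelParams"), is(state, "GateState"))
    validObject(state)
    params@theta[["g_Kr"]] * state@a * state@r * (V - E_K)
}

# Gate trajectories at arbitrary times under a piecewise-constant protocol.
# Within a constant-voltage segment both gate ODEs are linear with constant
# coefficients, so the trajectory is the exact exponential relaxation
# x(t) = x_inf + (x0 - x_inf) exp(-(t - t0)/tau). Gates start at
# equilibrium for the first segment's voltage.
# Returns list(a, r, V) aligned with `times` (assumed sorted, within
# [0, totalDuration)).
.gateTrajectory <- function(params, protocol, times) {
    durs <- protocol@durations
    volts <- protocol@voltages
    starts <- cumsum(c(0, durs))
    nseg <- length(durs)
    a <- numeric(length(times))
    r <- numeric(length(times))
    Vout <- numeric(length(times))
    eq0 <- gateEquilibria(transitionRates(params, volts[1]))
    a0 <- eq0[["a_inf"]]; r0 <- eq0[["r_inf"]]
    for (s in seq_len(nseg)) {
        eq <- gateEquilibria(transitionRates(params, volts[s]))
        # half-open [start, end): boundary samples belong to this segment
        sel <- times >= starts[s] & times < starts[s + 1]
        if (s == nseg) sel <- sel | times == starts[s + 1]
        if (any(sel)) {
            dt <- times[sel] - starts[s]
            a[sel] <- eq[["a_inf"]] + (a0 - eq[["a_inf"]]) * exp(-dt / eq[["tau_a"]])
            r[sel] <- eq[["r_inf"]] + (r0 - eq[["r_inf"]]) * exp(-dt / eq[["tau_r"]])
            Vout[sel] <- volts[s]
        }
        ds <- durs[s]
        a0 <- eq[["a_inf"]] + (a0 - eq[["a_inf"]]) * exp(-ds / eq[["tau_a"]])
        r0 <- eq[["r_inf"]] + (r0 - eq[["r_inf"]]) * exp(-ds / eq[["tau_r"]])
    }
    list(a = a, r = r, V = Vout)
}

# deSolve-based gate trajectories, integrating da/dt = (a_inf - a)/tau_a,
# dr/dt = (r_inf - r)/tau_r segment by segment with lsoda.
.gateTrajectoryODE <- function(params, protocol, times, absTol, relTol) {
    durs <- protocol@durations
    volts <- protocol@voltages
    starts <- cumsum(c(0, durs))
    nseg <- length(durs)
    a <- numeric(length(times)); r <- numeric(length(times))
    Vout <- numeric(length(times))
    eq0 <- gateEquilibria(transitionRates(params, volts[1]))
    y <- c(a = eq0[["a_inf"]], r = eq0[["r_inf"]])
    rhs <- function(t, y, p) {
        list(c((p[1] - y[1]) / p[2], (p[3] - y[2]) / p[4]))
    }
    for (s in seq_len(nseg)) {
        eq <- gateEquilibria(transitionRates(params, volts[s]))
        sel <- times >= starts[s] & times < starts[s + 1]
        if (s == nseg) sel <- sel | times == starts[s + 1]
        tloc <- times[sel] - starts[s]
        tgrid <- sort(unique(c(0, tloc, durs[s])))
        out <- deSolve::lsoda(
            y = y, times = tgrid, func = rhs,
            parms = c(eq[["a_inf"]], eq[["tau_a"]], eq[["r_inf"]], eq[["tau_r"]]),
            atol = absTol, rtol = relTol)
        if (attr(out, "istate")[1] < 0 || any(!is.finite(out[, -1])))
            .stopWithClass("hergSimError", "ODE solver failed in segment %d", s)
        if (any(sel)) {
            idx <- match(tloc, out[, 1])
            a[sel] <- out[idx, 2]
            r[sel] <- out[idx, 3]
            Vout[sel] <- volts[s]
        }
        nlast <- nrow(out)
        y <- c(a = unname(out[nlast, 2]), r = unname(out[nlast, 3]))
    }
    list(a = a, r = r, V = Vout)
}

# Clean current samples at arbitrary times (internal fast path used by the
# simulator, the fitting objective and the MCMC likelihood).
.currentAtTimes <- function(params, protocol, times,
                            constants = physicalConstants(),
                            method = c("analytic", "ode"),
                            absTol = 1e-8, relTol = 1e-10) {
    method <- match.arg(method)
    E_K <- nernstPotential(constants)
    tr <- if (method == "analytic") .gateTrajectory(params, protocol, times)
          else .gateTrajectoryODE(params, protocol, times, absTol, relTol)
    I <- params@theta[["g_Kr"]] * tr$a * tr$r * (tr$V - E_K)
    if (any(!is.finite(I)))
        .stopWithClass("hergSimError", "non-finite current in simulation")
    I
}

#' Simulate the hERG current under a voltage protocol
#'
#' Integrates the two gate ODEs da/dt = (a_inf - a)/tau_a,
#' dr/dt = (r_inf - r)/tau_r along a piecewise-constant voltage protocol
#' and returns the current I_Kr = g_Kr a r (V - E_K) sampled uniformly at
#' `sampleRate`. Gates are initialized at equilibrium for the protocol's
#' first segment voltage, so traces are fully determined by (params,
#' protocol).
#'
#' Within each constant-voltage segment the gate ODEs are linear with
#' constant coefficients, so the default `method = "analytic"` evaluates
#' the exact per-segment exponential solution (no discretization error).
#' `method = "ode"` integrates the same equations with an adaptive stiff
#' solver ([deSolve::lsoda()]) under the given tolerances and is kept as
#' an independent numerical cross-check.
#'
#' @param params A [ChannelParams-class] object.
#' @param protocol A [VoltageProtocol-class] object.
#' @param sampleRate Sampling rate in Hz (default 5000).
#' @param method `"analytic"` (exact, default) or `"ode"`.
#' @param constants A [PhysicalConstants-class] object.
#' @param absTol,relTol Solver tolerances for `method = "ode"`
#'   (defaults 1e-8 and 1e-10).
#' @return A [CurrentTrace-class] with `round(duration * sampleRate)`
#'   samples starting at t = 0.
#' @examples
#' tr <- simulateCurrent(demoParams(), staircaseProtocol(), sampleRate = 500)
#' @export
simulateCurrent <- function(params, protocol, sampleRate = 5000,
                            method = c("analytic", "ode"),
                            constants = physicalConstants(),
                            absTol = 1e-8, relTol = 1e-10) {
    stopifnot(is(params, "ChannelParams"), is(protocol, "VoltageProtocol"),
              sampleRate > 0)
    validObject(params)
    validObject(protocol)
    method <- match.arg(method)
    n <- round(totalDuration(protocol) * sampleRate)
    times <- (seq_len(n) - 1) / sampleRate
    I <- .currentAtTimes(params, protocol, times, constants, method,
                         absTol, relTol)
    currentTrace(I, sampleRate)
}

#' Literature-typical hERG channel parameters
#'
#' A representative room-temperature hERG parameter set (Beattie-type
#' Hodgkin-Huxley kinetics converted to 1/s and 1/V; conductance in
#' pA/V), used as the centre of the synthetic benchmark-cell population
#' and as a convenient demo value. It satisfies the default prior box
#' and the physiological rate constraints.
#'
#' @return A [ChannelParams-class] object.
#' @examples
#' checkConstraints(demoParams())   # TRUE
#' @export
demoParams <- function() {
    channelParams(g_Kr = 152400,
                  p1 = 0.226,  p2 = 69.9,
                  p3 = 0.0345, p4 = 54.6,
                  p5 = 87.3,   p6 = 8.91,
                  p7 = 5.15,   p8 = 31.6)
}

#' Read or write a current trace as CSV
#'
#' CSV with header `time_s,current_pA`; times must form a uniform grid
#' starting at 0.
#'
#' @param path File path.
#' @param trace A [CurrentTrace-class] object.
#' @return `readTraceCSV` returns a [CurrentTrace-class];
#'   `writeTraceCSV` returns `path` invisibly.
#' @export
readTraceCSV <- function(path) {
    df <- utils::read.csv(path)
    if (!all(c("time_s", "current_pA") %in% names(df)))
        stop("trace CSV must have columns time_s, current_pA")
    if (nrow(df) < 2)
        stop("trace CSV must contain at least two samples")
    dt <- diff(df$time_s)
    if (max(abs(dt - dt[1])) > 1e-9 * dt[1] + 1e-15)
        stop("trace CSV must be uniformly sampled")
    currentTrace(df$current_pA, 1 / dt[1])
}

#' @rdname readTraceCSV
#' @export
writeTraceCSV <- function(trace, path) {
    stopifnot(is(trace, "CurrentTrace"))
    df <- data.frame(time_s = sprintf("%.17g", sampleTimes(trace)),
                     current_pA = sprintf("%.17g", currents(trace)))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
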