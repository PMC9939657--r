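#' Voltage command at a given time
#'
#' Looks up the command voltage of a piecewise-constant protocol at time
#' `t` under the half-open convention: a sample exactly at a segment
#' boundary takes the later segment's voltage, so V(t) is single-valued
#' and right-continuous.
#'
#' @param protocol A [VoltageProtocol-class] object.
#' @param t Time(s) in seconds, each in `[0, totalDuration(protocol))`.
#' @return Voltage(s) in volts.
#' @examples
#' voltageAt(staircaseProtocol(), 0)
#' @export
voltageAt <- function(protocol, t) {
    stopifnot(is(protocol, "VoltageProtocol"))
    total <- totalDuration(protocol)
    if (any(t < 0 | t >= total))
        stop(sprintf("t must lie in [0, %g)", total))
    ends <- cumsum(protocol@durations)
    # segment s covers [start_s, end_s): the segment index is the number
    # of segment ends at or before t, plus one
    idx <- findInterval(t, ends) + 1L
    protocol@voltages[idx]
}

#' Default staircase-style voltage protocol
#'
#' A deterministic staircase-style voltage-clamp command built from
#' 500 ms constant-voltage core steps spanning the physiological window
#' [-0.12, 0.06] V, with a leading and trailing holding period at
#' -0.08 V, totalling exactly 15.4 s. The core contains a full ascending
#' and a full descending staircase in 20 mV increments plus alternating
#' activation/deactivation probe steps, so channel kinetics are probed
#' across the whole voltage window in both directions.
#'
#' This is a documented approximation with the same step length, voltage
#' window and total duration as the published staircase protocol, whose
#' exact step sequence is distributed graphically/externally rather than
#' as a table; for fidelity work supply the published protocol via
#' [readProtocolCSV()].
#'
#' @return A [VoltageProtocol-class] object named `"staircase-default"`.
#' @examples
#' totalDuration(staircaseProtocol())  # 15.4 s
#' @export
staircaseProtocol <- function() {
    core <- c(-0.12, -0.08,
              seq(-0.12, 0.06, by = 0.02),   # ascending staircase, 10 steps
              seq(0.04, -0.12, by = -0.02),  # descending staircase, 9 steps
              0.06, -0.12, 0.06, -0.08, 0.06, -0.12, -0.04)
    voltageProtocol(
        durations = c(0.9, rep(0.5, length(core)), 0.5),
        voltages = c(-0.08, core, -0.08),
        name = "staircase-default")
}

#' Read or write a voltage protocol as CSV
#'
#' Protocols are stored as CSV with header `duration_s,voltage_V`, one
#' segment per row. Values are written at full double precision, so a
#' write-then-read round trip reproduces the segments exactly and
#' writing the same protocol twice yields identical bytes.
#'
#' @param path File path.
#' @param protocol A [VoltageProtocol-class] object.
#' @param name Label for the protocol read from file (defaults to the
#'   file name).
#' @param voltageWindow Sanity window passed to [voltageProtocol()].
#' @return `readProtocolCSV` returns a [VoltageProtocol-class];
#'   `writeProtocolCSV` returns `path` invisibly.
#' @export
readProtocolCSV <- function(path, name = basename(path),
                            voltageWindow = c(-0.15, 0.10)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L)
        stop("protocol CSV is empty (need a header and at least one segment)")
    header <- trimws(strsplit(lines[1], ",", fixed = TRUE)[[1]])
    if (!identical(header, c("duration_s", "voltage_V")))
        stop("protocol CSV must have header 'duration_s,voltage_V'")
    n <- length(lines) - 1L
    durations <- numeric(n)
    voltages <- numeric(n)
    for (i in seq_len(n)) {
        fields <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
        vals <- suppressWarnings(as.numeric(trimws(fields)))
        if (length(vals) != 2L || any(is.na(vals)))
            stop(sprintf("malformed protocol row %d: '%s'", i, lines[i + 1L]))
        if (vals[1] <= 0)
            stop(sprintf("non-positive duration in protocol row %d", i))
        durations[i] <- vals[1]
        voltages[i] <- vals[2]
    }
    voltageProtocol(durations, voltages, name = name,
                    voltageWindow = voltageWindow)
}

#' @rdname readProtocolCSV
#' @export
writeProtocolCSV <- function(protocol, path) {
    stopifnot(is(protocol, "VoltageProtocol"))
    lines <- c("duration_s,voltage_V",
               sprintf("%.17g,%.17g", protocol@durations, protocol@voltages))
    writeLines(lines, path)
    invisible(path)
}
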