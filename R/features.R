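# Reflect an out-of-range 1-based index into [1, n] (period 2(n-1)),
# i.e. boundary-sample-excluded reflection padding, applied repeatedly
# for indices far outside the signal.
.reflectIndex <- function(idx, n) {
    if (n == 1L) return(rep(1L, length(idx)))
    m <- (idx - 1L) %% (2L * n - 2L)
    ifelse(m < n, m + 1L, 2L * n - 1L - m)
}

# Periodic Hann window of length `win`.
.hannWindow <- function(win) {
    0.5 * (1 - cos(2 * pi * (0:(win - 1)) / win))
}

#' Short-time Fourier transform spectrogram of a current trace
#'
#' Computes a one-sided magnitude spectrogram with centered framing:
#' frame m (m = 0, 1, ...) is the `nFFT`-sample window of the
#' reflect-padded signal centered on sample `m * hop`, multiplied by a
#' periodic Hann window of length `win` zero-padded symmetrically to
#' `nFFT`. The magnitude of the first `nFFT/2 + 1` DFT bins is
#' compressed with log1p. The frame count is `floor(n / hop) + 1`, so
#' the study's 1,540-sample decimated traces yield a 129 x 129 grid
#' with the default parameters.
#'
#' @param trace A [CurrentTrace-class] object (length >= `win`).
#' @param nFFT DFT length (default 256).
#' @param hop Hop length in samples (default 12).
#' @param win Window length in samples (default 48).
#' @param scale Divide the trace by this fixed global scale (pA) before
#'   transforming, so absolute amplitude information is preserved across
#'   traces. Default 1e4; use 1 for raw magnitudes.
#' @return A [Spectrogram-class] with `nFFT/2 + 1` rows.
#' @examples
#' tr <- currentTrace(sin(2 * pi * 5 * (0:1539) / 100), 100)
#' dim(stftSpectrogram(tr, scale = 1))
#' @export
stftSpectrogram <- function(trace, nFFT = 256, hop = 12, win = 48,
                            scale = 1e4) {
    stopifnot(is(trace, "CurrentTrace"), nFFT >= 2, hop >= 1, win >= 2,
              win <= nFFT, scale > 0)
    x <- currents(trace) / scale
    n <- length(x)
    if (n < win)
        stop(sprintf("trace length %d is below the window length %d", n, win))
    nFrames <- floor(n / hop) + 1L
    # window zero-padded symmetrically to nFFT
    w <- numeric(nFFT)
    off <- (nFFT - win) %/% 2L
    w[off + seq_len(win)] <- .hannWindow(win)
    # centered framing on the reflect-padded signal
    centers <- hop * (seq_len(nFrames) - 1L)          # 0-based center sample
    rel <- seq_len(nFFT) - 1L - (nFFT %/% 2L)          # frame-relative offsets
    idx <- outer(rel, centers, "+") + 1L               # nFFT x nFrames, 1-based
    frames <- matrix(x[.reflectIndex(idx, n)], nFFT, nFrames)
    spec <- Mod(stats::mvfft(frames * w))[seq_len(nFFT %/% 2L + 1L), , drop = FALSE]
    spectrogram(log1p(spec),
                stftParams = list(nFFT = nFFT, hop = hop, win = win,
                                  scale = scale))
}

#' Bilinearly resize a spectrogram
#'
#' Resamples the grid to `rows x cols` by separable bilinear
#' interpolation with corner alignment, so resizing to the original
#' shape is the identity, constants stay constant and non-negativity is
#' preserved.
#'
#' @param spec A [Spectrogram-class] object.
#' @param rows,cols Target shape (each >= 2).
#' @return A [Spectrogram-class] of shape `rows x cols`.
#' @examples
#' g <- spectrogram(matrix(runif(25), 5))
#' dim(resizeSpectrogram(g, 3, 7))
#' @export
resizeSpectrogram <- function(spec, rows, cols) {
    stopifnot(is(spec, "Spectrogram"), rows >= 2, cols >= 2)
    g <- spec@grid
    out <- .interpMatrix(rows, nrow(g)) %*% g %*% t(.interpMatrix(cols, ncol(g)))
    # clip tiny negative round-off from the interpolation weights
    out[out < 0] <- 0
    spectrogram(out, stftParams = spec@stftParams)
}

# nOut x nIn corner-aligned linear interpolation matrix.
.interpMatrix <- function(nOut, nIn) {
    M <- matrix(0, nOut, nIn)
    if (nIn == 1L) { M[, 1] <- 1; return(M) }
    pos <- (seq_len(nOut) - 1) * (nIn - 1) / (nOut - 1) + 1
    lo <- pmin(floor(pos), nIn - 1)
    frac <- pos - lo
    for (i in seq_len(nOut)) {
        M[i, lo[i]] <- 1 - frac[i]
        M[i, lo[i] + 1] <- M[i, lo[i] + 1] + frac[i]
    }
    M
}

#' Regressor input features for a current trace
#'
#' The fixed featurization pipeline used for training and prediction:
#' STFT spectrogram of the (globally scaled) trace, resized to the
#' requested square resolution.
#'
#' @param trace A [CurrentTrace-class] (a decimated noisy trace).
#' @param resolution Target side length (rows = cols).
#' @param nFFT,hop,win,scale Passed to [stftSpectrogram()].
#' @return A [Spectrogram-class] of shape `resolution x resolution`.
#' @export
traceFeatures <- function(trace, resolution = 129, nFFT = 256, hop = 12,
                          win = 48, scale = 1e4) {
    sp <- stftSpectrogram(trace, nFFT = nFFT, hop = hop, win = win,
                          scale = scale)
    if (nrow(sp@grid) == resolution && ncol(sp@grid) == resolution)
        return(sp)
    resizeSpectrogram(sp, resolution, resolution)
}
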