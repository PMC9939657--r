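# Brute-force STFT oracle: explicit reflect padding and per-frame matrix
# DFT, kept independent of the package's vectorized implementation.
bruteSpectrogram <- function(x, nFFT, hop, win) {
    n <- length(x)
    reflect <- function(i) {
        m <- (i - 1) %% (2 * n - 2)
        if (m < n) m + 1 else 2 * n - 1 - m
    }
    w <- numeric(nFFT)
    off <- (nFFT - win) %/% 2
    w[off + seq_len(win)] <- 0.5 * (1 - cos(2 * pi * (0:(win - 1)) / win))
    nFrames <- floor(n / hop) + 1
    half <- nFFT %/% 2
    dft <- exp(-2i * pi * outer(0:half, 0:(nFFT - 1)) / nFFT)
    out <- matrix(0, half + 1, nFrames)
    for (m in seq_len(nFrames)) {
        center <- hop * (m - 1)
        idx <- vapply(center - half + seq_len(nFFT) - 1 + 1, reflect, 1)
        out[, m] <- Mod(dft %*% (w * x[idx]))
    }
    log1p(out)
}

test_that("the spectrogram matches a frame-by-frame DFT oracle", {
    set.seed(41)
    cases <- list(c(n = 256, nFFT = 32, hop = 7, win = 20),
                  c(n = 100, nFFT = 64, hop = 12, win = 48),
                  c(n = 60, nFFT = 16, hop = 3, win = 10))
    for (cs in cases) {
        x <- rnorm(cs["n"])
        sp <- stftSpectrogram(currentTrace(x, 100), nFFT = cs["nFFT"],
                              hop = cs["hop"], win = cs["win"], scale = 1)
        oracle <- bruteSpectrogram(x, cs["nFFT"], cs["hop"], cs["win"])
        expect_equal(dim(sp), dim(oracle))
        expect_lt(max(abs(specGrid(sp) - oracle)), 1e-10)
        # shape law: rows = nFFT/2 + 1, cols = floor(n/hop) + 1
        expect_identical(dim(sp), as.integer(c(cs["nFFT"] / 2 + 1,
                                               cs["n"] %/% cs["hop"] + 1)))
    }
})

test_that("the study trace geometry yields a 129 x 129 spectrogram", {
    tr <- currentTrace(rnorm(1540), 100)
    expect_identical(dim(stftSpectrogram(tr)), c(129L, 129L))
})

test_that("degenerate traces transform as expected", {
    expect_true(all(specGrid(stftSpectrogram(currentTrace(numeric(200), 100),
                                             scale = 1)) == 0))
    # a DC trace concentrates energy in the zero-frequency row
    sp <- specGrid(stftSpectrogram(currentTrace(rep(3, 200), 100), scale = 1))
    interior <- sp[, 5:13]
    expect_true(all(interior[1, ] > apply(interior[-1, ], 2, max)))
    expect_error(stftSpectrogram(currentTrace(rnorm(10), 100)), "window")
})

test_that("scaling the trace never decreases spectrogram entries", {
    set.seed(5)
    x <- rnorm(300)
    a <- specGrid(stftSpectrogram(currentTrace(x, 100), scale = 1))
    b <- specGrid(stftSpectrogram(currentTrace(3 * x, 100), scale = 1))
    expect_true(all(b >= a - 1e-12))
})

test_that("bilinear resizing preserves shape contracts", {
    set.seed(6)
    g <- spectrogram(matrix(runif(129 * 129), 129))
    small <- resizeSpectrogram(g, 97, 97)
    expect_identical(dim(small), c(97L, 97L))
    expect_true(all(specGrid(small) >= 0))
    # identity resize
    same <- resizeSpectrogram(g, 129, 129)
    expect_identical(max(abs(specGrid(same) - specGrid(g))), 0)
    # constants stay constant
    flat <- resizeSpectrogram(spectrogram(matrix(2.5, 40, 50)), 21, 33)
    expect_equal(specGrid(flat), matrix(2.5, 21, 33), tolerance = 1e-12)
})
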