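# Minimal CNN engine on base-R matrix algebra (BLAS-backed).
#
# Activations are stored as 4-d arrays with layout (H, W, N, C): the two
# spatial dimensions first so a 3x3 convolution reduces to nine
# (H*W*N x Cin) %*% (Cin x Cout) products on contiguous slices of the
# zero-padded input, which is where nearly all the arithmetic lives.

.nnPad1 <- function(X) {
    d <- dim(X)
    P <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
    P[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- X
    P
}

# 3x3 same-padding convolution, forward. W: (3,3,Cin,Cout), b: (Cout).
.convForward <- function(X, W, b) {
    d <- dim(X)
    H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]; Cout <- dim(W)[4]
    P <- .nnPad1(X)
    M <- H * Wd * N
    out <- matrix(rep(b, each = M), M, Cout)
    for (i in 1:3) for (j in 1:3) {
        S <- P[i:(i + H - 1L), j:(j + Wd - 1L), , , drop = FALSE]
        dim(S) <- c(M, Cin)
        out <- out + S %*% matrix(W[i, j, , ], Cin, Cout)
    }
    dim(out) <- c(H, Wd, N, Cout)
    list(out = out, cache = list(X = X, W = W))
}

.convBackward <- function(dOut, cache) {
    X <- cache$X; W <- cache$W
    d <- dim(X)
    H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]; Cout <- dim(W)[4]
    M <- H * Wd * N
    P <- .nnPad1(X)
    dP <- array(0, dim(P))
    dmat <- dOut
    dim(dmat) <- c(M, Cout)
    dW <- array(0, dim(W))
    for (i in 1:3) for (j in 1:3) {
        S <- P[i:(i + H - 1L), j:(j + Wd - 1L), , , drop = FALSE]
        dim(S) <- c(M, Cin)
        dW[i, j, , ] <- crossprod(S, dmat)
        dS <- dmat %*% t(matrix(W[i, j, , ], Cin, Cout))
        dim(dS) <- c(H, Wd, N, Cin)
        dP[i:(i + H - 1L), j:(j + Wd - 1L), , ] <-
            dP[i:(i + H - 1L), j:(j + Wd - 1L), , , drop = FALSE] + dS
    }
    list(dX = dP[2:(H + 1L), 2:(Wd + 1L), , , drop = FALSE],
         dW = dW, db = colSums(dmat))
}

.reluForward <- function(X) {
    mask <- X > 0
    X[!mask] <- 0
    list(out = X, cache = mask)
}

.reluBackward <- function(dOut, mask) {
    dOut[!mask] <- 0
    dOut
}

# 2x2 max pooling, stride 2; odd trailing rows/cols are dropped.
.poolForward <- function(X) {
    d <- dim(X)
    H2 <- d[1] %/% 2L * 2L; W2 <- d[2] %/% 2L * 2L
    ri <- seq(1L, H2, by = 2L); ci <- seq(1L, W2, by = 2L)
    A <- list(X[ri, ci, , , drop = FALSE],  X[ri + 1L, ci, , , drop = FALSE],
              X[ri, ci + 1L, , , drop = FALSE], X[ri + 1L, ci + 1L, , , drop = FALSE])
    out <- pmax(pmax(A[[1]], A[[2]]), pmax(A[[3]], A[[4]]))
    list(out = out, cache = list(A = A, out = out, dimX = d))
}

.poolBackward <- function(dOut, cache) {
    d <- cache$dimX
    H2 <- d[1] %/% 2L * 2L; W2 <- d[2] %/% 2L * 2L
    ri <- seq(1L, H2, by = 2L); ci <- seq(1L, W2, by = 2L)
    dX <- array(0, d)
    taken <- array(FALSE, dim(dOut))
    offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
    for (k in 1:4) {
        m <- (cache$A[[k]] == cache$out) & !taken
        taken <- taken | m
        g <- dOut
        g[!m] <- 0
        dX[ri + offs[[k]][1], ci + offs[[k]][2], , ] <- g
    }
    dX
}

# Adaptive average pooling to a fixed (P x P) grid via two bin-average
# matrices, so the head is independent of the input resolution.
.adaptPoolMatrix <- function(P, n) {
    M <- matrix(0, P, n)
    edges <- floor((0:P) * n / P)
    for (k in seq_len(P)) {
        cols <- (edges[k] + 1L):edges[k + 1L]
        M[k, cols] <- 1 / length(cols)
    }
    M
}

# Contract the first dimension of array X with matrix M (nOut x dim(X)[1]).
.contract1 <- function(X, M) {
    d <- dim(X)
    Y <- M %*% matrix(X, d[1])
    dim(Y) <- c(nrow(M), d[-1])
    Y
}

.adaptPoolForward <- function(X, P) {
    d <- dim(X)
    Mr <- .adaptPoolMatrix(P, d[1])
    Mc <- .adaptPoolMatrix(P, d[2])
    Y <- .contract1(X, Mr)                       # (P, W, N, C)
    Y <- aperm(Y, c(2, 1, 3, 4))                 # (W, P, N, C)
    Y <- .contract1(Y, Mc)                       # (P, P, N, C) cols-first
    Y <- aperm(Y, c(2, 1, 3, 4))                 # (Prow, Pcol, N, C)
    list(out = Y, cache = list(Mr = Mr, Mc = Mc, dimX = d))
}

.adaptPoolBackward <- function(dOut, cache) {
    dY <- aperm(dOut, c(2, 1, 3, 4))
    dY <- .contract1(dY, t(cache$Mc))
    dY <- aperm(dY, c(2, 1, 3, 4))
    .contract1(dY, t(cache$Mr))
}

# (P, P, N, C) -> features x N matrix for the dense head.
.flattenForward <- function(X) {
    d <- dim(X)
    Y <- aperm(X, c(1, 2, 4, 3))
    dim(Y) <- c(d[1] * d[2] * d[4], d[3])
    list(out = Y, cache = d)
}

.flattenBackward <- function(dOut, d) {
    dim(dOut) <- c(d[1], d[2], d[4], d[3])
    aperm(dOut, c(1, 2, 4, 3))
}

.denseForward <- function(A, W, b) {
    list(out = W %*% A + b, cache = A)
}

.denseBackward <- function(dOut, cache, W) {
    list(dA = crossprod(W, dOut), dW = tcrossprod(dOut, cache),
         db = rowSums(dOut))
}

# He-normal initialization of the small CNN. `channels` gives the conv
# widths; the head sees poolDim^2 * last channel features.
.nnInit <- function(channels = c(8, 16, 32), poolDim = 6, hidden = 64,
                    nOut = 9, seed = 1) {
    .withSeed(seed, {
        w <- list()
        cin <- 1L
        for (l in seq_along(channels)) {
            cout <- channels[l]
            w[[paste0("convW", l)]] <-
                array(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                      c(3, 3, cin, cout))
            w[[paste0("convB", l)]] <- numeric(cout)
            cin <- cout
        }
        nf <- poolDim^2 * cin
        w$denseW1 <- matrix(stats::rnorm(hidden * nf, 0, sqrt(2 / nf)), hidden, nf)
        w$denseB1 <- numeric(hidden)
        w$denseW2 <- matrix(stats::rnorm(nOut * hidden, 0, sqrt(2 / hidden)),
                            nOut, hidden)
        w$denseB2 <- numeric(nOut)
        w
    })
}

# Forward pass. X: (H, W, N) or (H, W, N, 1). Returns nOut x N predictions
# and, if `keepCache`, the per-layer caches for backprop.
.nnForward <- function(w, X, nConv, poolDim, keepCache = FALSE) {
    if (length(dim(X)) == 3L) dim(X) <- c(dim(X), 1L)
    caches <- if (keepCache) vector("list", 16L) else NULL
    ci <- 0L
    keep <- function(x) if (keepCache) { ci <<- ci + 1L; caches[[ci]] <<- x }
    A <- X
    for (l in seq_len(nConv)) {
        cv <- .convForward(A, w[[paste0("convW", l)]], w[[paste0("convB", l)]])
        keep(cv$cache)
        rl <- .reluForward(cv$out)
        keep(rl$cache)
        A <- rl$out
        if (l < nConv) {
            pl <- .poolForward(A)
            keep(pl$cache)
            A <- pl$out
        }
    }
    ap <- .adaptPoolForward(A, poolDim)
    keep(ap$cache)
    fl <- .flattenForward(ap$out)
    keep(fl$cache)
    d1 <- .denseForward(fl$out, w$denseW1, w$denseB1)
    keep(d1$cache)
    r1 <- .reluForward(d1$out)
    keep(r1$cache)
    d2 <- .denseForward(r1$out, w$denseW2, w$denseB2)
    keep(d2$cache)
    list(pred = d2$out, caches = caches)
}

# Backward pass from dPred (nOut x N); returns gradient list matching w.
.nnBackward <- function(w, fw, dPred, nConv, poolDim) {
    caches <- fw$caches
    ci <- length(Filter(Negate(is.null), caches))
    pop <- function() { x <- caches[[ci]]; ci <<- ci - 1L; x }
    g <- list()
    b2 <- .denseBackward(dPred, pop(), w$denseW2)
    g$denseW2 <- b2$dW; g$denseB2 <- b2$db
    dA <- .reluBackward(b2$dA, pop())
    b1 <- .denseBackward(dA, pop(), w$denseW1)
    g$denseW1 <- b1$dW; g$denseB1 <- b1$db
    dA <- .flattenBackward(b1$dA, pop())
    dA <- .adaptPoolBackward(dA, pop())
    for (l in rev(seq_len(nConv))) {
        if (l < nConv)
            dA <- .poolBackward(dA, pop())
        dA <- .reluBackward(dA, pop())
        cb <- .convBackward(dA, pop())
        g[[paste0("convW", l)]] <- cb$dW
        g[[paste0("convB", l)]] <- cb$db
        dA <- cb$dX
    }
    g
}

.adamInit <- function(w) {
    list(m = lapply(w, function(x) x * 0), v = lapply(w, function(x) x * 0),
         t = 0L)
}

.adamStep <- function(w, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
    state$t <- state$t + 1L
    bc1 <- 1 - beta1^state$t
    bc2 <- 1 - beta2^state$t
    for (nm in names(w)) {
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
        w[[nm]] <- w[[nm]] - lr * (state$m[[nm]] / bc1) /
            (sqrt(state$v[[nm]] / bc2) + eps)
    }
    list(w = w, state = state)
}
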