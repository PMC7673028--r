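## Low-level neural-network engine: batched bidirectional LSTM with full
## backpropagation through time, 3x3 convolutions via im2col, 2x2 max
## pooling, dense layers, inverted dropout, Glorot initialization and ADAM.
## Sequence minibatches are arrays [B, D, T] (trace, feature, step) with a
## per-sequence valid length; updates at padded steps are masked out, so
## padding never contributes to outputs, loss or gradients.

## Glorot (uniform) initializer, fan-in/fan-out of the given matrix.
glorotMat <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

## LSTM gate parameters: W [D x 4H], U [H x 4H], b [4H]; gate column blocks
## are (input, forget, output, candidate) — the three sigmoid gates first so
## the nonlinearity applies to one contiguous block. Glorot is applied per
## gate block with fan (D + H); the forget-gate bias starts at 1.
initLSTMParams <- function(D, H) {
    gate <- function(nr) {
        lim <- sqrt(6 / (nr + H))
        matrix(stats::runif(nr * H, -lim, lim), nr, H)
    }
    W <- do.call(cbind, replicate(4L, gate(D), simplify = FALSE))
    U <- do.call(cbind, replicate(4L, gate(H), simplify = FALSE))
    b <- rep(0, 4L * H)
    b[(H + 1L):(2L * H)] <- 1
    list(W = W, U = U, b = b)
}

## Reverse each sequence in-place up to its own length (padding stays put).
reverseSeqArray <- function(X, lens) {
    T <- dim(X)[3L]
    if (all(lens == T)) return(X[, , T:1L, drop = FALSE])
    out <- X
    for (i in seq_along(lens)) {
        li <- lens[i]
        if (li > 1L) out[i, , seq_len(li)] <- X[i, , li:1L]
    }
    out
}

## ---- one-directional LSTM ---------------------------------------------------

## X [B, D, T]; returns running final state hT [B,H] (== h at each sequence's
## last valid step), all step outputs Hs [B, H, T], and the backward cache.
## The time loop runs in compiled code (src/lstm.cpp); caches come back as
## flat step-major [B*T, .] matrices.
lstmDirForward <- function(X, lens, params, needHs = TRUE,
                           needCache = TRUE) {
    fw <- cpp_lstm_forward(X, as.integer(lens), params$W, params$U,
                           params$b, needHs, needCache)
    fw$X <- X
    fw
}

## dHs [B, H, T] (zeros allowed), dhT gradient on the running final state.
lstmDirBackward <- function(fwd, lens, params, dHs = NULL, dhT = NULL) {
    r <- cpp_lstm_backward(fwd$X, as.integer(lens), params$W, params$U,
                           fwd$Gflat, fwd$tcFlat, fwd$cPrevFlat,
                           fwd$HprevFlat,
                           dHs %||% array(0, dim = c(0L, 0L, 0L)),
                           dhT %||% matrix(0, 0L, 0L))
    list(dX = r$dX,
         grads = list(W = r$dW, U = r$dU, b = as.vector(r$db)))
}

## ---- bidirectional LSTM layer ----------------------------------------------

## params: list(fwd = ..., bwd = ...). outputMode "seq2seq" -> [B, 2H, T]
## (backward-direction outputs re-aligned to original time); "seq2one" ->
## [B, 2H] (forward final state, backward final state).
bilstmForward <- function(X, lens, params, outputMode, needCache = TRUE) {
    needHs <- outputMode != "seq2one"
    ff <- lstmDirForward(X, lens, params$fwd, needHs = needHs,
                         needCache = needCache)
    Xr <- reverseSeqArray(X, lens)
    fb <- lstmDirForward(Xr, lens, params$bwd, needHs = needHs,
                         needCache = needCache)
    if (outputMode == "seq2one") {
        out <- cbind(ff$hT, fb$hT)
    } else {
        d <- dim(ff$Hs)
        out <- array(0, dim = c(d[1L], 2L * d[2L], d[3L]))
        out[, seq_len(d[2L]), ] <- ff$Hs
        out[, d[2L] + seq_len(d[2L]), ] <- reverseSeqArray(fb$Hs, lens)
    }
    list(out = out, cache = list(ff = ff, fb = fb, lens = lens,
                                 outputMode = outputMode))
}

bilstmBackward <- function(cache, params, dOut) {
    lens <- cache$lens
    H <- length(params$fwd$b) %/% 4L
    if (cache$outputMode == "seq2one") {
        bf <- lstmDirBackward(cache$ff, lens, params$fwd,
                              dhT = dOut[, seq_len(H), drop = FALSE])
        bb <- lstmDirBackward(cache$fb, lens, params$bwd,
                              dhT = dOut[, H + seq_len(H), drop = FALSE])
    } else {
        dFwd <- dOut[, seq_len(H), , drop = FALSE]
        dim(dFwd) <- dim(dFwd)[c(1L, 2L, 3L)]
        dBwd <- dOut[, H + seq_len(H), , drop = FALSE]
        dim(dBwd) <- dim(dBwd)[c(1L, 2L, 3L)]
        bf <- lstmDirBackward(cache$ff, lens, params$fwd, dHs = dFwd)
        bb <- lstmDirBackward(cache$fb, lens, params$bwd,
                              dHs = reverseSeqArray(dBwd, lens))
    }
    dX <- bf$dX + reverseSeqArray(bb$dX, lens)
    list(dX = dX,
         grads = list(fwd = bf$grads, bwd = bb$grads))
}

## ---- dense / dropout / softmax ----------------------------------------------

flattenSeq <- function(A) { # [B, K, T] -> [B*T, K]
    d <- dim(A)
    matrix(aperm(A, c(1L, 3L, 2L)), d[1L] * d[3L], d[2L])
}

unflattenSeq <- function(M, B, K, T) { # [B*T, K] -> [B, K, T]
    aperm(array(M, dim = c(B, T, K)), c(1L, 3L, 2L))
}

denseForward <- function(X, params) {
    if (is.matrix(X)) {
        Z <- X %*% params$W + matrix(params$b, nrow(X), length(params$b),
                                     byrow = TRUE)
        list(out = Z, cache = list(X = X, seq = FALSE))
    } else {
        d <- dim(X)
        M <- flattenSeq(X)
        Z <- M %*% params$W + matrix(params$b, nrow(M), length(params$b),
                                     byrow = TRUE)
        list(out = unflattenSeq(Z, d[1L], length(params$b), d[3L]),
             cache = list(X = M, seq = TRUE, B = d[1L], T = d[3L],
                          K = d[2L]))
    }
}

denseBackward <- function(cache, params, dOut) {
    if (cache$seq) {
        dM <- flattenSeq(dOut)
        grads <- list(W = crossprod(cache$X, dM), b = colSums(dM))
        dX <- unflattenSeq(dM %*% t(params$W), cache$B, cache$K, cache$T)
    } else {
        grads <- list(W = crossprod(cache$X, dOut), b = colSums(dOut))
        dX <- dOut %*% t(params$W)
    }
    list(dX = dX, grads = grads)
}

## Inverted dropout; on sequences ([B, K, T]) the mask is constant across
## time (one draw per trace and feature), the usual choice for recurrent
## stacks.
dropoutForward <- function(X, rate, training) {
    if (!training || rate <= 0)
        return(list(out = X, cache = NULL))
    if (is.matrix(X)) {
        mask <- matrix(stats::runif(length(X)) >= rate,
                       nrow(X), ncol(X)) / (1 - rate)
    } else {
        d <- dim(X)
        mask <- array((stats::runif(d[1L] * d[2L]) >= rate) / (1 - rate),
                      dim = d)   # recycled identically over the time axis
    }
    list(out = X * mask, cache = mask)
}

softmaxRows <- function(Z) {
    Z <- Z - apply(Z, 1L, max)
    E <- exp(Z)
    E / rowSums(E)
}

## ---- convolution / pooling (CNN path) ---------------------------------------

## A [B, S, S, C] -> patches [B*S*S, 9C] for 3x3 same-padding convolution.
im2col3 <- function(A) {
    d <- dim(A); B <- d[1L]; S <- d[2L]; C <- d[4L]
    P <- array(0, dim = c(B, S + 2L, S + 2L, C))
    P[, 2L:(S + 1L), 2L:(S + 1L), ] <- A
    cols <- matrix(0, B * S * S, 9L * C)
    k <- 0L
    for (ch in seq_len(C)) for (dy in 0:2) for (dx in 0:2) {
        k <- k + 1L
        cols[, k] <- as.vector(P[, dx + seq_len(S), dy + seq_len(S), ch])
    }
    cols
}

## Scatter-add of patch gradients back to the input (transpose of im2col3).
col2im3 <- function(dCols, B, S, C) {
    dP <- array(0, dim = c(B, S + 2L, S + 2L, C))
    k <- 0L
    for (ch in seq_len(C)) for (dy in 0:2) for (dx in 0:2) {
        k <- k + 1L
        dP[, dx + seq_len(S), dy + seq_len(S), ch] <-
            dP[, dx + seq_len(S), dy + seq_len(S), ch] +
            array(dCols[, k], dim = c(B, S, S))
    }
    dP[, 2L:(S + 1L), 2L:(S + 1L), , drop = FALSE]
}

convForward <- function(X, params) { # X [B,S,S,C]; W [9C x F]; relu output
    d <- dim(X); B <- d[1L]; S <- d[2L]
    F <- length(params$b)
    cols <- im2col3(X)
    Z <- cols %*% params$W + matrix(params$b, nrow(cols), F, byrow = TRUE)
    act <- Z > 0
    out <- array(Z * act, dim = c(B, S, S, F))
    list(out = out, cache = list(cols = cols, act = act, B = B, S = S,
                                 C = d[4L]))
}

convBackward <- function(cache, params, dOut) {
    F <- length(params$b)
    dZ <- matrix(dOut, cache$B * cache$S * cache$S, F) * cache$act
    grads <- list(W = crossprod(cache$cols, dZ), b = colSums(dZ))
    dX <- col2im3(dZ %*% t(params$W), cache$B, cache$S, cache$C)
    list(dX = dX, grads = grads)
}

poolForward <- function(X) { # 2x2 max pooling, stride 2; X [B,S,S,C]
    d <- dim(X); S <- d[2L]
    o <- seq(1L, S, by = 2L)
    a11 <- X[, o, o, , drop = FALSE];     a21 <- X[, o + 1L, o, , drop = FALSE]
    a12 <- X[, o, o + 1L, , drop = FALSE]; a22 <- X[, o + 1L, o + 1L, , drop = FALSE]
    m <- pmax(a11, a12, a21, a22)
    list(out = m, cache = list(w11 = a11 == m, w12 = a12 == m,
                               w21 = a21 == m, w22 = a22 == m, S = S))
}

poolBackward <- function(cache, dOut) {
    S <- cache$S
    o <- seq(1L, S, by = 2L)
    d <- dim(dOut)
    dX <- array(0, dim = c(d[1L], S, S, d[4L]))
    ## ties split the gradient among maxima (keeps the map a true adjoint)
    tot <- cache$w11 + cache$w12 + cache$w21 + cache$w22
    g <- dOut / tot
    dX[, o, o, ] <- g * cache$w11
    dX[, o, o + 1L, ] <- dX[, o, o + 1L, , drop = FALSE] + g * cache$w12
    dX[, o + 1L, o, ] <- dX[, o + 1L, o, , drop = FALSE] + g * cache$w21
    dX[, o + 1L, o + 1L, ] <- dX[, o + 1L, o + 1L, , drop = FALSE] +
        g * cache$w22
    dX
}

## ---- ADAM -------------------------------------------------------------------

adamInit <- function(params) {
    rapply(params, function(p) list(m = p * 0, v = p * 0),
           how = "list")
}

## Flat recursive update over nested parameter lists.
adamUpdate <- function(params, grads, state, lr, t, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
    upd <- function(p, g, s) {
        if (is.list(p)) {
            out <- Map(upd, p, g, s)
            return(list(p = lapply(out, `[[`, "p"),
                        s = lapply(out, `[[`, "s")))
        }
        m <- beta1 * s$m + (1 - beta1) * g
        v <- beta2 * s$v + (1 - beta2) * g * g
        mh <- m / (1 - beta1^t)
        vh <- v / (1 - beta2^t)
        list(p = p - lr * mh / (sqrt(vh) + eps), s = list(m = m, v = v))
    }
    res <- Map(upd, params, grads, state)
    list(params = lapply(res, `[[`, "p"), state = lapply(res, `[[`, "s"))
}
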