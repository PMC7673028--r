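#' @include AllClasses.R utils.R
NULL

#' Bin a trace into the LSTM input encoding
#'
#' Converts a raw trace with `T` intensity samples per channel into a
#' two-dimensional array of dimension `[nBin, floor(T/nBin)]` per channel,
#' with each group of `nBin` consecutive frames stacked into one column
#' (one LSTM time step). For two-channel traces the channel blocks are
#' stacked vertically (donor rows first), giving `2 * nBin` rows. Trailing
#' `T %% nBin` frames are dropped.
#'
#' @param trace numeric matrix `n_channels x T` (a single trace from a
#'   [TraceSet-class]), or a numeric vector (treated as one channel).
#' @param nBin frames per bin; default 10.
#' @return object of class `"BinnedTrace"`: list with `values`
#'   (`n_channels*nBin x floor(T/nBin)` matrix), `nBin`, `nChannels`,
#'   `framesUsed`.
#' @examples
#' bt <- binTrace(matrix(1:20, nrow = 1), nBin = 10)
#' bt$values    # column 1 = frames 1..10, column 2 = frames 11..20
#' @export
binTrace <- function(trace, nBin = 10L) {
    if (!is.matrix(trace)) trace <- matrix(as.numeric(trace), nrow = 1L)
    T <- ncol(trace)
    nBin <- as.integer(nBin)
    stopifnot(nBin >= 1L)
    if (T < nBin)
        stopWith("smtn_short_trace", "trace shorter than one bin (T=%d < nBin=%d)",
                 T, nBin)
    S <- T %/% nBin
    used <- S * nBin
    blocks <- lapply(seq_len(nrow(trace)), function(ch)
        matrix(trace[ch, seq_len(used)], nrow = nBin))
    structure(list(values = do.call(rbind, blocks), nBin = nBin,
                   nChannels = nrow(trace), framesUsed = used),
              class = "BinnedTrace")
}

#' Normalize a trace for network input
#'
#' @param trace numeric matrix `n_channels x T`.
#' @param method `"robust_z"` (per-channel median/MAD; the default LSTM input
#'   scaling), `"per_trace_max"` (all channels divided by the maximum over
#'   both channels), or `"none"`.
#' @return the normalized matrix, with the applied scaling recorded in
#'   `attr(, "scaling")` (`method`, per-channel `center` and `scale`) so the
#'   transform is reversible.
#' @export
normalizeTrace <- function(trace,
                           method = c("robust_z", "per_trace_max", "none")) {
    method <- match.arg(method)
    if (!is.matrix(trace)) trace <- matrix(as.numeric(trace), nrow = 1L)
    nch <- nrow(trace)
    if (method == "none") {
        attr(trace, "scaling") <- list(method = "none",
                                       center = rep(0, nch),
                                       scale = rep(1, nch))
        return(trace)
    }
    if (method == "per_trace_max") {
        mx <- max(trace)
        if (mx <= 0)
            stopWith("smtn_degenerate_trace",
                     "per_trace_max normalization undefined: trace maximum is <= 0")
        out <- trace / mx
        attr(out, "scaling") <- list(method = method, center = rep(0, nch),
                                     scale = rep(mx, nch))
        return(out)
    }
    center <- apply(trace, 1L, stats::median)
    scale <- apply(trace, 1L, stats::mad)
    ## a flat channel has MAD 0; fall back to sd, then to 1
    flat <- scale <= .Machine$double.eps
    if (any(flat)) {
        sds <- apply(trace, 1L, stats::sd)
        scale[flat] <- ifelse(sds[flat] > 0, sds[flat], 1)
    }
    out <- (trace - center) / scale
    attr(out, "scaling") <- list(method = method, center = center,
                                 scale = scale)
    out
}

#' Convert a two-channel trace to a 32x32 donor/acceptor scatter image
#'
#' Plots framewise donor (x) and acceptor (y) intensities as a 2-D occupancy
#' histogram down-sampled to 32x32 pixels — the CNN input encoding. Both axes
#' span `[0, max]` where `max` is the maximum intensity over both channels;
#' each frame increments exactly one pixel (values below 0 or above `max`
#' are clamped into the edge bins). The returned `pixels` are scaled to
#' \[0, 1\] by the maximum pixel count; raw counts are retained.
#'
#' @param trace numeric matrix `2 x T` (donor row first).
#' @param size image side length in pixels (default 32).
#' @return object of class `"ScatterImage"`: list with `pixels` (size x size,
#'   scaled), `counts` (raw occupancy; sums to `T`), `range` (per-axis bin
#'   range), `framesUsed`.
#' @export
traceToScatterImage <- function(trace, size = 32L) {
    if (!is.matrix(trace) || nrow(trace) != 2L)
        stopWith("smtn_channel_mismatch", "CNN path requires two channels")
    size <- as.integer(size)
    T <- ncol(trace)
    mx <- max(trace)
    if (!is.finite(mx) || mx <= 0)
        stopWith("smtn_degenerate_trace",
                 "scatter image undefined: no positive intensity in trace")
    brk <- seq(0, mx, length.out = size + 1L)
    ix <- findInterval(trace[1L, ], brk, rightmost.closed = TRUE,
                       all.inside = TRUE)
    iy <- findInterval(trace[2L, ], brk, rightmost.closed = TRUE,
                       all.inside = TRUE)
    ix <- pmin(pmax(ix, 1L), size)
    iy <- pmin(pmax(iy, 1L), size)
    counts <- matrix(0, size, size)
    tb <- table(factor(ix, levels = seq_len(size)),
                factor(iy, levels = seq_len(size)))
    counts[] <- as.numeric(tb)
    structure(list(pixels = counts / max(counts), counts = counts,
                   range = c(0, mx), framesUsed = T),
              class = "ScatterImage")
}

#' Collapse a per-frame mask to per-bin labels, and expand back
#'
#' `binMaskLabels` assigns each bin of `nBin` consecutive frames the majority
#' label of its frames (ties count as accepted). `expandBinLabels` maps one
#' label per bin back to one label per frame (each repeated `nBin` times; the
#' trailing `T %% nBin` frames inherit the last bin's label), optionally
#' removing accepted runs shorter than `minRun` frames.
#'
#' @param mask logical vector, length `T` (TRUE = frame accepted).
#' @param nBin frames per bin.
#' @return `binMaskLabels`: logical vector of length `floor(T/nBin)`.
#' @export
binMaskLabels <- function(mask, nBin = 10L) {
    S <- length(mask) %/% nBin
    if (S < 1L)
        stopWith("smtn_short_trace", "mask shorter than one bin")
    m <- matrix(mask[seq_len(S * nBin)], nrow = nBin)
    colMeans(m) >= 0.5
}

#' @rdname binMaskLabels
#' @param binLabels logical vector, one label per bin.
#' @param nFrames total frames `T` of the original trace.
#' @param minRun accepted runs shorter than this many frames are dropped
#'   (0 disables smoothing).
#' @return `expandBinLabels`: logical vector of length `nFrames`.
#' @export
expandBinLabels <- function(binLabels, nBin, nFrames, minRun = 0L) {
    out <- rep(binLabels, each = nBin)
    if (length(out) < nFrames)
        out <- c(out, rep(binLabels[length(binLabels)],
                          nFrames - length(out)))
    out <- out[seq_len(nFrames)]
    if (minRun > 0L && any(out)) {
        r <- rle(out)
        r$values[r$values & r$lengths < minRun] <- FALSE
        out <- inverse.rle(r)
    }
    out
}

## ---- batch encoders (internal) --------------------------------------------

## Encode a TraceSet as a padded LSTM minibatch:
## list(X = array [B, D, Smax], lens = per-trace step counts, D, steps, ...)
encodeLSTMBatch <- function(ts, nBin = 10L, normalize = "robust_z") {
    nch <- unique(nChannels(ts))
    if (length(nch) != 1L)
        stopWith("smtn_channel_mismatch",
                 "mixed channel counts in one batch: %s",
                 paste(nch, collapse = ", "))
    B <- nTraces(ts)
    binned <- lapply(seq_len(B), function(i) {
        m <- normalizeTrace(intensities(ts, i), normalize)
        binTrace(m, nBin)$values
    })
    lens <- vapply(binned, ncol, integer(1))
    D <- nch * nBin
    steps <- max(lens)
    X <- array(0, dim = c(B, D, steps))
    for (i in seq_len(B)) X[i, , seq_len(lens[i])] <- binned[[i]]
    list(X = X, lens = lens, D = D, steps = steps, nBin = as.integer(nBin),
         framesUsed = lens * as.integer(nBin),
         nFrames = traceLengths(ts))
}

## Encode a TraceSet as a CNN minibatch: array [B, size, size]
encodeImageBatch <- function(ts, size = 32L) {
    if (any(nChannels(ts) != 2L))
        stopWith("smtn_channel_mismatch", "CNN path requires two channels")
    B <- nTraces(ts)
    arr <- array(0, dim = c(B, size, size))
    for (i in seq_len(B))
        arr[i, , ] <- traceToScatterImage(intensities(ts, i), size)$pixels
    arr
}
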