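## Shared fixtures and small utilities for the test suite.

## A tiny deterministic two-channel TraceSet.
tinyFretSet <- function(n = 3L, T = 120L, seed = 11L) {
    simulateAcceptedFret(n, simParams(nFrames = T), seed = seed)
}

## Perturb one entry of a (possibly nested) parameter list.
perturbParam <- function(params, path, i, delta) {
    if (!length(path)) {
        params[i] <- params[i] + delta
        return(params)
    }
    params[[path[1L]]] <- perturbParam(params[[path[1L]]], path[-1L], i,
                                       delta)
    params
}

## Finite-difference gradient check of every parameterized layer of `model`
## against `lossOf(model)`; returns the max relative error over sampled
## coordinates. Dropout must be disabled by the caller (rate 0 or
## training = FALSE in lossOf).
checkGradients <- function(model, lossOf, grads, nPerMat = 5L,
                           eps = 1e-6) {
    maxerr <- 0
    for (j in seq_along(model@layers)) {
        g <- grads[[j]]
        if (is.null(g)) next
        nm1 <- names(model@layers[[j]]$params)
        paths <- if (all(nm1 %in% c("fwd", "bwd")))
            unlist(lapply(nm1, function(a)
                lapply(c("W", "U", "b"), function(b) c(a, b))),
                recursive = FALSE)
        else lapply(nm1, identity)
        for (path in paths) {
            p <- model@layers[[j]]$params; gx <- g
            for (nm in path) { p <- p[[nm]]; gx <- gx[[nm]] }
            for (ii in sample(length(p), min(nPerMat, length(p)))) {
                m2 <- model
                m2@layers[[j]]$params <-
                    perturbParam(model@layers[[j]]$params, path, ii, eps)
                lp <- lossOf(m2)
                m2@layers[[j]]$params <-
                    perturbParam(model@layers[[j]]$params, path, ii, -eps)
                lm_ <- lossOf(m2)
                num <- (lp - lm_) / (2 * eps)
                maxerr <- max(maxerr, abs(num - gx[ii]) /
                                  max(1e-8, abs(num) + abs(gx[ii])))
            }
        }
    }
    maxerr
}

## Boundary of the accepted segment: end of the longest accepted run
## (frames, 0-based exclusive); 0 if nothing is accepted.
acceptedBoundary <- function(mask) {
    r <- rle(mask)
    if (!any(r$values)) return(0L)
    k <- which(r$values)
    k <- k[which.max(r$lengths[k])]
    sum(r$lengths[seq_len(k)])
}

## First-bleach frame per trace (T where no fluorophore bleached in-window).
firstBleachFrames <- function(ts) {
    gt <- groundTruth(ts)
    fb <- suppressWarnings(pmin(gt$donorBleach, gt$acceptorBleach,
                                na.rm = TRUE))
    fb[is.na(gt$donorBleach) & is.na(gt$acceptorBleach)] <-
        traceLengths(ts)[is.na(gt$donorBleach) & is.na(gt$acceptorBleach)]
    as.integer(fb)
}
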