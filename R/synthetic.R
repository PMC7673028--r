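#' @include AllClasses.R utils.R
NULL

#' Simulation parameters for two-channel smFRET traces
#'
#' Defaults reproduce the reference simulation conditions: two FRET states
#' with efficiencies drawn uniformly on \[0, 1\], per-trace transition rates
#' drawn from an exponential distribution with mean 0.05 per frame,
#' independent single-exponential photobleaching of each fluorophore at
#' 0.0025 per frame (0.025 s^-1 at the default 0.1 s frame interval), a mean
#' total (donor + acceptor) intensity of 1000 AU, and additive Gaussian noise
#' whose standard deviation is a per-trace fraction of the total signal.
#'
#' @param nFrames frames per trace (default 3000).
#' @param kBleach per-frame photobleaching rate of each fluorophore
#'   (default 0.0025).
#' @param meanKTrans mean of the exponential distribution from which the two
#'   per-trace state-transition rates are drawn, per frame (default 0.05).
#' @param totalIntensity mean donor + acceptor signal, AU (default 1000).
#' @param noiseRange interval from which each trace's Gaussian noise s.d.
#'   (as a fraction of `totalIntensity`) is drawn uniformly
#'   (default `c(0.05, 0.3)`).
#' @param frameInterval seconds per frame (default 0.1; per-frame rates are
#'   primary, seconds are derived).
#' @param directExcitationFrames optional length of a leading
#'   acceptor-direct-excitation window (acceptor high, donor dark) prepended
#'   to each trace and excluded from the ground-truth frame mask; 0 (default)
#'   disables it.
#' @return a validated parameter list.
#' @export
simParams <- function(nFrames = 3000L, kBleach = 0.0025, meanKTrans = 0.05,
                      totalIntensity = 1000, noiseRange = c(0.05, 0.3),
                      frameInterval = 0.1, directExcitationFrames = 0L) {
    stopifnot(nFrames >= 1L, kBleach > 0, meanKTrans > 0, totalIntensity > 0,
              length(noiseRange) == 2L, all(noiseRange >= 0),
              all(noiseRange < 1), noiseRange[1] <= noiseRange[2],
              directExcitationFrames >= 0L)
    list(nFrames = as.integer(nFrames), kBleach = kBleach,
         meanKTrans = meanKTrans, totalIntensity = totalIntensity,
         noiseRange = noiseRange, frameInterval = frameInterval,
         directExcitationFrames = as.integer(directExcitationFrames))
}

#' Simulation parameters for one-channel kinetic-fingerprinting traces
#'
#' @param nFrames frames per trace.
#' @param kOn,kOff per-frame probe binding / dissociation rates.
#' @param amplitude bound-state intensity, AU.
#' @param noiseRange per-trace Gaussian noise s.d. interval, as a fraction of
#'   `amplitude`.
#' @param backgroundKinds nonspecific behaviours sampled for WT-labeled
#'   traces: `single_event` (one isolated binding event), `rare_long`
#'   (10x slower kinetics, few long events), `drift` (transition-free slow
#'   baseline drift).
#' @param frameInterval seconds per frame.
#' @return a validated parameter list.
#' @export
simrepsParams <- function(nFrames = 3000L, kOn = 0.02, kOff = 0.02,
                          amplitude = 1000, noiseRange = c(0.05, 0.3),
                          backgroundKinds = c("single_event", "rare_long",
                                              "drift"),
                          frameInterval = 0.1) {
    stopifnot(nFrames >= 1L, kOn > 0, kOff > 0, amplitude > 0,
              length(noiseRange) == 2L, all(noiseRange >= 0),
              all(noiseRange < 1), noiseRange[1] <= noiseRange[2],
              all(backgroundKinds %in% c("single_event", "rare_long",
                                         "drift")))
    list(nFrames = as.integer(nFrames), kOn = kOn, kOff = kOff,
         amplitude = amplitude, noiseRange = noiseRange,
         backgroundKinds = backgroundKinds, frameInterval = frameInterval)
}

## Two-state (or n-state) Markov state path by geometric dwell sampling.
## pLeave: per-state probability of leaving per frame; s0: 1-based start.
## Returns integer vector length T of 1-based state indices.
statePathMarkov <- function(T, pLeave, s0) {
    nStates <- length(pLeave)
    out <- integer(0)
    cur <- s0
    while (length(out) < T) {
        d <- if (pLeave[cur] <= 0) T else stats::rgeom(1L, pLeave[cur]) + 1L
        out <- c(out, rep.int(cur, min(d, T - length(out))))
        cur <- if (nStates == 2L) 3L - cur
               else sample((seq_len(nStates))[-cur], 1L)
    }
    out
}

## One geometric "first bleach frame" draw (0-based); frame >= T means the
## fluorophore survives the whole trace and is reported as NA ("never").
drawBleachFrame <- function(T, kBleach) {
    f <- stats::rgeom(1L, 1 - exp(-kBleach))
    if (f >= T) NA_integer_ else f
}

## Assemble donor/acceptor signal for a two-state FRET trace with bleaching.
## Frames are 0-based internally; column j of the matrix is frame j-1.
fretSignal <- function(statePath, E, total, donorBleach, acceptorBleach) {
    T <- length(statePath)
    Ef <- E[statePath]
    donor <- total * (1 - Ef)
    acceptor <- total * Ef
    frames <- seq_len(T) - 1L
    aB <- if (is.na(acceptorBleach)) T else acceptorBleach
    dB <- if (is.na(donorBleach)) T else donorBleach
    ## acceptor bleached, donor still emitting: all energy stays on the donor
    sel <- frames >= aB & frames < dB
    acceptor[sel] <- 0
    donor[sel] <- total
    ## donor bleached: no excitation reaches either fluorophore
    sel <- frames >= dB
    donor[sel] <- 0
    acceptor[sel] <- 0
    if (aB < dB) { # acceptor dark earlier also when donor dies later
        sel <- frames >= max(aB, dB)
        acceptor[sel] <- 0
    }
    rbind(donor = donor, acceptor = acceptor)
}

## Freeze a state path from the first bleach event onward (the molecule's
## FRET state is unobservable and by convention constant after bleaching).
freezePostBleach <- function(statePath, firstBleach) {
    if (is.na(firstBleach) || firstBleach >= length(statePath))
        return(statePath)
    if (firstBleach == 0L) frozen <- statePath[1L]
    else frozen <- statePath[firstBleach]
    statePath[(firstBleach + 1L):length(statePath)] <- frozen
    statePath
}

buildFretTraceSet <- function(mats, gt, params, label, prefix, seed) {
    ids <- sprintf("%s_%05d", prefix, seq_along(mats))
    names(mats) <- ids
    td <- S4Vectors::DataFrame(
        nChannels = rep(2L, length(mats)),
        frameInterval = rep(params$frameInterval, length(mats)),
        movieID = rep(sprintf("sim_%s", prefix), length(mats)),
        classLabel = rep(label, length(mats)),
        artifactKind = gt$artifactKind,
        E1 = gt$E1, E2 = gt$E2, k12 = gt$k12, k21 = gt$k21,
        nStates = gt$nStates %||% rep(2L, length(mats)),
        donorBleach = gt$donorBleach, acceptorBleach = gt$acceptorBleach,
        noiseFraction = gt$noiseFraction,
        statePath = I(gt$statePath), frameMask = I(gt$frameMask),
        row.names = ids)
    new("TraceSet", traces = mats, traceData = td,
        metadata = list(generator = prefix, seed = seed, params = params))
}

#' Simulate accepted (high-quality) two-channel smFRET traces
#'
#' Monte-Carlo generator of two-state FRET traces with full ground truth.
#' Per trace: efficiencies `E1`, `E2 ~ U(0, 1)`; transition rates
#' `k12`, `k21 ~ Exp(mean = meanKTrans)`; a discrete-frame two-state Markov
#' chain (per-frame switch probability `1 - exp(-k)`) started from its
#' stationary distribution; independent geometric photobleaching of donor and
#' acceptor at `kBleach`; donor intensity `total * (1 - E)` and acceptor
#' `total * E` before bleaching, donor recovering to `total` after acceptor
#' bleach and both channels dark after donor bleach; and i.i.d. Gaussian
#' noise with s.d. `noiseFraction * total` per channel, `noiseFraction` drawn
#' uniformly from `params$noiseRange` per trace.
#'
#' Ground truth is stored in [traceData()]: `classLabel` (`"ACCEPT"`),
#' `E1`, `E2`, `k12`, `k21`, `donorBleach`/`acceptorBleach` (0-based first
#' dark frame; `NA` = never bleached), `noiseFraction`, the per-frame
#' `statePath` (frozen after the first bleach event), and `frameMask`
#' (`TRUE` on frames preceding the first bleach event — the analyzable
#' segment).
#'
#' @param n number of traces.
#' @param params a [simParams()] list.
#' @param seed integer seed; identical `(params, n, seed)` give bit-identical
#'   output. `NULL` uses the current RNG stream.
#' @return a [TraceSet-class] with ground-truth `traceData`.
#' @examples
#' ts <- simulateAcceptedFret(3, simParams(nFrames = 200), seed = 1)
#' groundTruth(ts)[, c("E1", "E2", "donorBleach")]
#' @export
simulateAcceptedFret <- function(n, params = simParams(), seed = NULL) {
    stopifnot(n >= 1L)
    withLocalSeed(seed, {
        T <- params$nFrames
        pre <- params$directExcitationFrames
        total <- params$totalIntensity
        mats <- vector("list", n)
        gt <- list(E1 = numeric(n), E2 = numeric(n), k12 = numeric(n),
                   k21 = numeric(n), donorBleach = integer(n),
                   acceptorBleach = integer(n), noiseFraction = numeric(n),
                   artifactKind = rep(NA_character_, n),
                   statePath = vector("list", n),
                   frameMask = vector("list", n))
        for (i in seq_len(n)) {
            E <- stats::runif(2L)
            k <- stats::rexp(2L, rate = 1 / params$meanKTrans)
            p <- 1 - exp(-k)
            s0 <- if (stats::runif(1L) < p[2L] / (p[1L] + p[2L])) 1L else 2L
            sp <- statePathMarkov(T, p, s0)
            dB <- drawBleachFrame(T, params$kBleach)
            aB <- drawBleachFrame(T, params$kBleach)
            firstB <- suppressWarnings(min(dB, aB, na.rm = TRUE))
            if (is.infinite(firstB)) firstB <- NA_integer_
            sp <- freezePostBleach(sp, firstB)
            sig <- fretSignal(sp, E, total, dB, aB)
            nf <- stats::runif(1L, params$noiseRange[1L],
                               params$noiseRange[2L])
            mask <- if (is.na(firstB)) rep(TRUE, T)
                    else seq_len(T) - 1L < firstB
            if (pre > 0L) {
                sig <- cbind(rbind(rep(0, pre), rep(total, pre)), sig)
                sp <- c(rep(sp[1L], pre), sp)
                mask <- c(rep(FALSE, pre), mask)
                if (!is.na(dB)) dB <- dB + pre
                if (!is.na(aB)) aB <- aB + pre
            }
            sig <- sig + matrix(stats::rnorm(length(sig), 0, nf * total),
                                nrow = 2L)
            rownames(sig) <- c("donor", "acceptor")
            mats[[i]] <- sig
            gt$E1[i] <- E[1L]; gt$E2[i] <- E[2L]
            gt$k12[i] <- k[1L]; gt$k21[i] <- k[2L]
            gt$donorBleach[i] <- dB; gt$acceptorBleach[i] <- aB
            gt$noiseFraction[i] <- nf
            gt$statePath[[i]] <- sp
            gt$frameMask[[i]] <- mask
        }
        buildFretTraceSet(mats, gt, params, "ACCEPT", "fret", seed)
    })
}

#' Simulate rejected (artifact) two-channel traces
#'
#' Generates the disqualifying behaviours that trace curation screens out:
#' \describe{
#'   \item{`multi_state`}{3-5 FRET states (distinct efficiencies) instead of
#'     two.}
#'   \item{`uncorrelated`}{donor and acceptor fluctuate as independent
#'     two-level processes, with no FRET anticorrelation.}
#'   \item{`low_snr`}{two-state FRET construction but noise s.d. drawn from
#'     \[0.8, 0.95\] of the total signal.}
#'   \item{`early_bleach`}{both fluorophores bleach within the first 5% of
#'     frames.}
#'   \item{`acceptor_only`}{no acceptor signal at all (failed labeling):
#'     donor constant at full intensity.}
#' }
#'
#' @param kind artifact kind (one of the five above).
#' @param n number of traces.
#' @param params a [simParams()] list.
#' @param seed integer seed (see [simulateAcceptedFret()]).
#' @return a [TraceSet-class] labeled `"REJECT"` with `artifactKind` ground
#'   truth; the ground-truth `frameMask` is all-`FALSE` (no analyzable
#'   segment).
#' @export
simulateRejectedFret <- function(kind, n, params = simParams(),
                                 seed = NULL) {
    kinds <- c("multi_state", "uncorrelated", "low_snr", "early_bleach",
               "acceptor_only")
    if (!kind %in% kinds)
        stopWith("smtn_bad_kind", "unknown artifact kind '%s'; must be one of: %s",
                 kind, paste(kinds, collapse = ", "))
    stopifnot(n >= 1L)
    withLocalSeed(seed, {
        T <- params$nFrames
        total <- params$totalIntensity
        mats <- vector("list", n)
        gt <- list(E1 = rep(NA_real_, n), E2 = rep(NA_real_, n),
                   k12 = rep(NA_real_, n), k21 = rep(NA_real_, n),
                   nStates = rep(2L, n),
                   donorBleach = rep(NA_integer_, n),
                   acceptorBleach = rep(NA_integer_, n),
                   noiseFraction = numeric(n),
                   artifactKind = rep(kind, n),
                   statePath = vector("list", n),
                   frameMask = replicate(n, rep(FALSE, T), simplify = FALSE))
        for (i in seq_len(n)) {
            nf <- stats::runif(1L, params$noiseRange[1L],
                               params$noiseRange[2L])
            if (kind == "multi_state") {
                nStates <- sample(3:5, 1L)
                gt$nStates[i] <- nStates
                E <- stats::runif(nStates)
                k <- stats::rexp(nStates, rate = 1 / params$meanKTrans)
                sp <- statePathMarkov(T, 1 - exp(-k), sample(nStates, 1L))
                dB <- drawBleachFrame(T, params$kBleach)
                aB <- drawBleachFrame(T, params$kBleach)
                sig <- fretSignal(sp, E, total, dB, aB)
                gt$E1[i] <- E[1L]; gt$E2[i] <- E[2L]
                gt$donorBleach[i] <- dB; gt$acceptorBleach[i] <- aB
            } else if (kind == "uncorrelated") {
                lv <- function() sort(stats::runif(2L, 0.1, 1)) * total
                kd <- stats::rexp(2L, rate = 1 / params$meanKTrans)
                ka <- stats::rexp(2L, rate = 1 / params$meanKTrans)
                spd <- statePathMarkov(T, 1 - exp(-kd), sample(2L, 1L))
                spa <- statePathMarkov(T, 1 - exp(-ka), sample(2L, 1L))
                dl <- lv(); al <- lv()
                sig <- rbind(donor = dl[spd], acceptor = al[spa])
                sp <- spd
            } else if (kind == "low_snr") {
                nf <- stats::runif(1L, 0.8, 0.95)
                E <- stats::runif(2L)
                k <- stats::rexp(2L, rate = 1 / params$meanKTrans)
                sp <- statePathMarkov(T, 1 - exp(-k), sample(2L, 1L))
                dB <- drawBleachFrame(T, params$kBleach)
                aB <- drawBleachFrame(T, params$kBleach)
                sig <- fretSignal(sp, E, total, dB, aB)
                gt$E1[i] <- E[1L]; gt$E2[i] <- E[2L]
                gt$k12[i] <- k[1L]; gt$k21[i] <- k[2L]
                gt$donorBleach[i] <- dB; gt$acceptorBleach[i] <- aB
            } else if (kind == "early_bleach") {
                E <- stats::runif(2L)
                k <- stats::rexp(2L, rate = 1 / params$meanKTrans)
                sp <- statePathMarkov(T, 1 - exp(-k), sample(2L, 1L))
                lim <- max(1L, as.integer(floor(0.05 * T)))
                dB <- sample.int(lim, 1L) - 1L
                aB <- sample.int(lim, 1L) - 1L
                sig <- fretSignal(sp, E, total, dB, aB)
                gt$E1[i] <- E[1L]; gt$E2[i] <- E[2L]
                gt$donorBleach[i] <- dB; gt$acceptorBleach[i] <- aB
            } else { # acceptor_only
                sig <- rbind(donor = rep(total, T), acceptor = rep(0, T))
                sp <- rep(1L, T)
            }
            sp <- if (kind %in% c("multi_state", "low_snr", "early_bleach"))
                freezePostBleach(sp, suppressWarnings(
                    min(gt$donorBleach[i], gt$acceptorBleach[i],
                        na.rm = TRUE)))
            else sp
            if (length(sp) == 0L || is.infinite(sp[1L])) sp <- rep(1L, T)
            sig <- sig + matrix(stats::rnorm(length(sig), 0, nf * total),
                                nrow = 2L)
            rownames(sig) <- c("donor", "acceptor")
            mats[[i]] <- sig
            gt$noiseFraction[i] <- nf
            gt$statePath[[i]] <- sp
        }
        buildFretTraceSet(mats, gt, params, "REJECT",
                          paste0("rej_", kind), seed)
    })
}

#' Simulate one-channel kinetic-fingerprinting traces
#'
#' `MUT`-labeled traces are two-state on/off telegraph processes (repeated
#' probe binding and dissociation at `kOn`/`kOff` per frame). `WT`-labeled
#' traces draw one of `params$backgroundKinds` per trace: a single isolated
#' binding event, rare long events (10x slower kinetics), or a
#' transition-free slow baseline drift.
#'
#' @param classLabel `"MUT"` or `"WT"`.
#' @param n number of traces.
#' @param params a [simrepsParams()] list.
#' @param seed integer seed (determinism contract as in
#'   [simulateAcceptedFret()]).
#' @return a [TraceSet-class]; ground-truth columns include `classLabel`,
#'   `artifactKind` (the background kind for WT), `kOn`, `kOff` and the
#'   on/off `statePath` (1 = unbound, 2 = bound).
#' @export
simulateSimreps <- function(classLabel, n, params = simrepsParams(),
                            seed = NULL) {
    stopifnot(classLabel %in% c("MUT", "WT"), n >= 1L)
    withLocalSeed(seed, {
        T <- params$nFrames
        amp <- params$amplitude
        pOn <- 1 - exp(-params$kOn)
        pOff <- 1 - exp(-params$kOff)
        mats <- vector("list", n)
        kind <- rep(NA_character_, n)
        nf <- numeric(n)
        paths <- vector("list", n)
        for (i in seq_len(n)) {
            nf[i] <- stats::runif(1L, params$noiseRange[1L],
                                  params$noiseRange[2L])
            if (classLabel == "MUT") {
                s0 <- if (stats::runif(1L) < pOn / (pOn + pOff)) 2L else 1L
                sp <- statePathMarkov(T, c(pOn, pOff), s0)
                sig <- amp * (sp == 2L)
            } else {
                kind[i] <- sample(params$backgroundKinds, 1L)
                if (kind[i] == "single_event") {
                    d <- stats::rgeom(1L, pOff) + 1L
                    start <- sample.int(T, 1L) - 1L
                    sp <- rep(1L, T)
                    idx <- which(seq_len(T) - 1L >= start &
                                 seq_len(T) - 1L < start + d)
                    sp[idx] <- 2L
                    sig <- amp * (sp == 2L)
                } else if (kind[i] == "rare_long") {
                    pOnS <- 1 - exp(-params$kOn / 10)
                    pOffS <- 1 - exp(-params$kOff / 10)
                    s0 <- if (stats::runif(1L) < pOnS / (pOnS + pOffS)) 2L
                          else 1L
                    sp <- statePathMarkov(T, c(pOnS, pOffS), s0)
                    sig <- amp * (sp == 2L)
                } else { # drift
                    sp <- rep(1L, T)
                    top <- stats::runif(1L, 0.3, 0.8) * amp
                    sig <- seq(0, top, length.out = T)
                }
            }
            sig <- sig + stats::rnorm(T, 0, nf[i] * amp)
            mats[[i]] <- matrix(sig, nrow = 1L,
                                dimnames = list("intensity", NULL))
            paths[[i]] <- sp
        }
        ids <- sprintf("simreps_%s_%05d", tolower(classLabel), seq_len(n))
        names(mats) <- ids
        td <- S4Vectors::DataFrame(
            nChannels = rep(1L, n),
            frameInterval = rep(params$frameInterval, n),
            movieID = rep("sim_simreps", n),
            classLabel = rep(classLabel, n),
            artifactKind = kind,
            kOn = rep(params$kOn, n), kOff = rep(params$kOff, n),
            noiseFraction = nf, statePath = I(paths),
            row.names = ids)
        new("TraceSet", traces = mats, traceData = td,
            metadata = list(generator = "simreps", seed = seed,
                            params = params))
    })
}

#' Draw per-trace FRET kinetic parameters
#'
#' Samples the generative prior used by [simulateAcceptedFret()]:
#' efficiencies i.i.d. uniform on \[0, 1\], transition rates i.i.d.
#' exponential with mean `meanKTrans` per frame.
#'
#' @param nDraws number of draws.
#' @param params a [simParams()] list (only `meanKTrans` is used).
#' @param seed integer seed.
#' @return data.frame with columns `E1`, `E2`, `k12`, `k21`.
#' @export
sampleKinetics <- function(nDraws, params = simParams(), seed = NULL) {
    stopifnot(nDraws >= 1L)
    withLocalSeed(seed, {
        data.frame(E1 = stats::runif(nDraws), E2 = stats::runif(nDraws),
                   k12 = stats::rexp(nDraws, rate = 1 / params$meanKTrans),
                   k21 = stats::rexp(nDraws, rate = 1 / params$meanKTrans))
    })
}
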