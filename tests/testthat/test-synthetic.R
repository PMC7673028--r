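test_that("accepted-trace generator is deterministic and conserves signal", {
    p <- simParams(nFrames = 150, noiseRange = c(0, 0))
    t1 <- simulateAcceptedFret(4, p, seed = 9)
    t2 <- simulateAcceptedFret(4, p, seed = 9)
    expect_identical(t1@traces, t2@traces)
    expect_identical(groundTruth(t1), groundTruth(t2))

    ## noiseless: pre-bleach frames take exactly two (donor, acceptor) value
    ## pairs, each summing to the total intensity
    gt <- groundTruth(t1)
    for (i in seq_len(4)) {
        fb <- firstBleachFrames(t1)[i]
        if (fb < 2) next
        m <- intensities(t1, i)[, seq_len(fb), drop = FALSE]
        expect_true(all(abs(colSums(m) - 1000) < 1e-9))
        expect_lte(nrow(unique(t(m))), 2L)
    }
})

test_that("bleaching empties channels in the simulated signal", {
    p <- simParams(nFrames = 200, noiseRange = c(0, 0))
    ts <- simulateAcceptedFret(30, p, seed = 21)
    gt <- groundTruth(ts)
    for (i in seq_len(30)) {
        m <- intensities(ts, i)
        dB <- gt$donorBleach[i]; aB <- gt$acceptorBleach[i]
        if (!is.na(dB) && dB < 200)
            expect_true(all(m[, (dB + 1):200] == 0))
        else if (!is.na(aB) && aB < 200) {
            expect_true(all(m[2, (aB + 1):200] == 0))
            expect_true(all(m[1, (aB + 1):200] == 1000))
        }
    }
})

test_that("pre-bleach donor/acceptor are anticorrelated in accepted traces", {
    p <- simParams(nFrames = 2000, noiseRange = c(0.05, 0.1))
    ts <- simulateAcceptedFret(40, p, seed = 33)
    gt <- groundTruth(ts)
    fb <- firstBleachFrames(ts)
    checked <- 0
    for (i in seq_len(40)) {
        if (fb[i] < 200) next
        sp <- gt$statePath[[i]][seq_len(fb[i])]
        if (length(unique(sp)) < 2) next
        ## r = -Var_sig / (Var_sig + Var_noise): the anticorrelation is only
        ## strong when the occupancy-weighted state separation resolves the
        ## noise, |dE| sqrt(pi1 pi2) >= 2.5 x noise fraction
        p1 <- mean(sp == 1L)
        sepOverNoise <- abs(gt$E1[i] - gt$E2[i]) * sqrt(p1 * (1 - p1)) /
            gt$noiseFraction[i]
        if (sepOverNoise < 2.5) next
        m <- intensities(ts, i)
        r <- cor(m[1, seq_len(fb[i])], m[2, seq_len(fb[i])])
        expect_lt(r, -0.8)
        checked <- checked + 1
    }
    expect_gte(checked, 5)
})

test_that("reject artifacts have their disqualifying features", {
    p <- simParams(nFrames = 3000)
    unc <- simulateRejectedFret("uncorrelated", 10,
                                simParams(nFrames = 2000,
                                          noiseRange = c(0.05, 0.05)),
                                seed = 41)
    for (i in seq_len(10)) {
        m <- intensities(unc, i)
        expect_gt(cor(m[1, ], m[2, ]), -0.2)
    }
    eb <- simulateRejectedFret("early_bleach", 10, p, seed = 42)
    gt <- groundTruth(eb)
    expect_true(all(gt$donorBleach < 150))
    expect_true(all(gt$acceptorBleach < 150))

    ms <- simulateRejectedFret("multi_state", 10, p, seed = 43)
    expect_true(all(groundTruth(ms)$nStates >= 3))

    ls <- simulateRejectedFret("low_snr", 5, p, seed = 44)
    expect_true(all(groundTruth(ls)$noiseFraction >= 0.8))

    expect_error(simulateRejectedFret("sparkly", 2, p, seed = 1),
                 class = "smtn_bad_kind")
    expect_true(all(classLabels(unc) == "REJECT"))
})

test_that("kinetic-fingerprinting generator matches renewal-theory rates", {
    p <- simrepsParams(nFrames = 3000, kOn = 0.02, kOff = 0.02,
                       noiseRange = c(0, 0))
    ts <- simulateSimreps("MUT", 1000, p, seed = 55)
    nEvents <- vapply(groundTruth(ts)$statePath, function(s)
        sum(diff(s) != 0), integer(1))
    ## stationary two-state chain: E[transitions] = (T-1) * 2 p q / (p + q)
    pOn <- 1 - exp(-0.02)
    expect_theory <- 2999 * 2 * pOn * pOn / (2 * pOn)
    se <- sd(nEvents) / sqrt(length(nEvents))
    expect_lt(abs(mean(nEvents) - expect_theory), 3 * se)

    ## pooled ON-dwell law (censored boundary dwells excluded):
    ## the ML exponential rate 1/mean(dwell) is within 5% of k_off
    dwells <- unlist(lapply(groundTruth(ts)$statePath, function(s) {
        r <- rle(s)
        k <- which(r$values == 2L)
        k <- setdiff(k, c(1L, length(r$values)))
        r$lengths[k]
    }))
    expect_gt(length(dwells), 5000)
    expect_lt(abs(1 / mean(dwells) - 0.02) / 0.02, 0.05)
})

test_that("WT background kinds behave as declared", {
    p <- simrepsParams(nFrames = 1000, noiseRange = c(0.05, 0.1),
                       backgroundKinds = "single_event")
    ts <- simulateSimreps("WT", 10, p, seed = 66)
    for (sp in groundTruth(ts)$statePath) {
        r <- rle(sp)
        expect_lte(sum(r$values == 2L), 1L)
    }
    expect_true(all(groundTruth(ts)$artifactKind == "single_event"))

    t1 <- simulateSimreps("WT", 5, simrepsParams(nFrames = 500), seed = 8)
    t2 <- simulateSimreps("WT", 5, simrepsParams(nFrames = 500), seed = 8)
    expect_identical(t1@traces, t2@traces)
})

test_that("direct-excitation preamble is prepended and masked out", {
    p <- simParams(nFrames = 100, noiseRange = c(0, 0),
                   directExcitationFrames = 50L)
    ts <- simulateAcceptedFret(3, p, seed = 91)
    gt <- groundTruth(ts)
    for (i in 1:3) {
        m <- intensities(ts, i)
        expect_equal(ncol(m), 150L)
        expect_true(all(m[2, 1:50] == 1000))  # acceptor directly excited
        expect_true(all(m[1, 1:50] == 0))
        expect_false(any(gt$frameMask[[i]][1:50]))
    }
})

test_that("sampleKinetics draws the generative prior", {
    k <- sampleKinetics(10000, simParams(), seed = 77)
    expect_equal(names(k), c("E1", "E2", "k12", "k21"))
    se <- sd(k$k12) / sqrt(nrow(k))
    expect_lt(abs(mean(k$k12) - 0.05), 3 * se)
    expect_gt(stats::ks.test(k$E1, "punif")$p.value, 0.01)
    one <- sampleKinetics(1, simParams(), seed = 5)
    expect_identical(one, sampleKinetics(1, simParams(), seed = 5))
})
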