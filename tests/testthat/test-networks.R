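test_that("canonical specs have the documented layer counts and defaults", {
    expect_length(networkSpec("simreps_lstm")@layers, 5L)
    expect_length(networkSpec("fret_classifier_lstm")@layers, 7L)
    expect_length(networkSpec("fret_segmenter_lstm")@layers, 8L)
    spec <- networkSpec("fret_classifier_lstm")
    expect_equal(spec@hiddenWidth, 100L)
    expect_equal(spec@nBin, 10L)
    expect_equal(spec@nClasses, 2L)
    expect_equal(formals(networkSpec)$hiddenWidth, 100L)
})

test_that("weightedCrossEntropy reproduces the defining identities", {
    ## perfect prediction -> zero loss
    expect_equal(weightedCrossEntropy(rbind(c(1, 0)), rbind(c(1, 0)),
                                      c(A = 1, B = 1)), 0)
    ## heavily weighted miss: w * ln 2
    L <- weightedCrossEntropy(rbind(c(0.5, 0.5)), rbind(c(0, 1)),
                              c(MUT = 1, WT = 1e6))
    expect_equal(L, 1e6 * log(2), tolerance = 1e-12)
    expect_equal(L, 693147.2, tolerance = 1e-6)

    ## oracle equivalence at uniform weights against an independently coded
    ## plain cross-entropy
    set.seed(20)
    P <- matrix(runif(60), 20, 3)
    P <- P / rowSums(P)
    Y <- t(vapply(sample(3, 20, TRUE), function(k) as.numeric(seq_len(3) == k),
                  numeric(3)))
    plainCE <- -sum(log(P[Y == 1]))
    expect_lt(abs(weightedCrossEntropy(P, Y, c(1, 1, 1)) - plainCE), 1e-10)

    ## zero probability at a true label -> large finite value, message
    expect_message(
        L0 <- weightedCrossEntropy(rbind(c(1, 0)), rbind(c(0, 1)),
                                   c(1, 1)),
        "floored")
    expect_true(is.finite(L0) && L0 > 20)
    expect_error(weightedCrossEntropy(rbind(c(0.6, 0.6)), rbind(c(1, 0)),
                                      c(1, 1)), class = "smtn_bad_probs")
})

test_that("the printed weight configurations load as family defaults", {
    expect_equal(defaultClassWeights("simreps_lstm"), c(MUT = 1, WT = 1e6))
    expect_equal(defaultClassWeights("fret_classifier_lstm"),
                 c(ACCEPT = 1, REJECT = 1))
    expect_equal(defaultClassWeights("fret_segmenter_lstm"),
                 c(ACCEPT = 10, REJECT = 1))
})

test_that("classifier output is a normalized per-trace score", {
    ts <- tinyFretSet(6, T = 60)
    model <- buildNetwork(networkSpec("fret_classifier_lstm"),
                          trainConfig(seed = 3))
    enc <- smTraceNet:::encodeForModel(model, ts)
    fw <- networkForward(model, enc)
    P <- smTraceNet:::softmaxRows(fw$logits)
    expect_true(all(abs(rowSums(P) - 1) < 1e-6))
    s <- classifyTraces(model, ts)
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(names(s), traceIDs(ts))
})

test_that("classification is independent of batch composition and order", {
    ts <- tinyFretSet(9, T = 60)
    model <- buildNetwork(networkSpec("fret_classifier_lstm"),
                          trainConfig(seed = 3))
    s1 <- classifyTraces(model, ts, batchSize = 4)
    s2 <- classifyTraces(model, ts[sample(9)], batchSize = 9)
    expect_equal(s1[names(s2)], s2, tolerance = 1e-12)
})

test_that("family/channel mismatches are rejected", {
    onech <- simulateSimreps("MUT", 2, simrepsParams(nFrames = 60), seed = 1)
    model <- buildNetwork(networkSpec("fret_classifier_lstm"),
                          trainConfig(seed = 3))
    expect_error(classifyTraces(model, onech),
                 class = "smtn_channel_mismatch")
    seg <- buildNetwork(networkSpec("fret_segmenter_lstm"),
                        trainConfig(seed = 3))
    expect_error(classifyTraces(seg, tinyFretSet(2)),
                 class = "smtn_bad_family")
    expect_error(segmentTraces(model, tinyFretSet(2)),
                 class = "smtn_bad_family")
})

test_that("segmenter emits one label per frame", {
    ts <- tinyFretSet(3, T = 127)
    model <- buildNetwork(networkSpec("fret_segmenter_lstm"),
                          trainConfig(seed = 9))
    masks <- segmentTraces(model, ts)
    expect_equal(vapply(masks, length, integer(1)),
                 setNames(rep(127L, 3), traceIDs(ts)))
})

test_that("training is seed-deterministic and validates its inputs", {
    p <- simParams(nFrames = 100)
    ts <- c(simulateAcceptedFret(12, p, seed = 1),
            simulateRejectedFret("low_snr", 12, p, seed = 2))
    cfg <- trainConfig(epochs = 2, batchSize = 8, seed = 77,
                       learningRate = 1e-3)
    m0 <- buildNetwork(networkSpec("fret_classifier_lstm", hiddenWidth = 8),
                       cfg)
    m1 <- trainNetwork(m0, ts, cfg)
    m2 <- trainNetwork(m0, ts, cfg)
    expect_identical(m1@layers, m2@layers)
    expect_equal(nrow(trainingHistory(m1)), 2L)
    expect_true(m1@trained)

    ## class absent -> error
    onlyAcc <- simulateAcceptedFret(6, p, seed = 3)
    expect_error(trainNetwork(m0, onlyAcc, cfg),
                 class = "smtn_missing_class")
    expect_error(trainNetwork(m0, ts, cfg,
                              labels = rep("BANANA", nTraces(ts))),
                 class = "smtn_bad_label")
})

test_that("end-to-end seeded pipeline reproduces identical decision tables", {
    p <- simParams(nFrames = 100)
    run <- function() {
        ts <- c(simulateAcceptedFret(10, p, seed = 4),
                simulateRejectedFret("low_snr", 10, p, seed = 5))
        cfg <- trainConfig(epochs = 1, batchSize = 10, seed = 6)
        m <- trainNetwork(buildNetwork(
            networkSpec("fret_classifier_lstm", hiddenWidth = 6), cfg),
            ts, cfg)
        applyThreshold(classifyTraces(m, ts))
    }
    expect_identical(as.data.frame(run()), as.data.frame(run()))
})

test_that("transfer learning freezes the early stack bitwise", {
    p <- simParams(nFrames = 100)
    ts <- c(simulateAcceptedFret(10, p, seed = 7),
            simulateRejectedFret("low_snr", 10, p, seed = 8))
    cfg <- trainConfig(epochs = 1, batchSize = 10, seed = 9,
                       learningRate = 1e-2)
    pre <- trainNetwork(buildNetwork(
        networkSpec("fret_classifier_lstm", hiddenWidth = 8), cfg), ts, cfg)
    tl <- transferLearn(pre, ts, trainConfig(epochs = 2, batchSize = 10,
                                             seed = 10,
                                             learningRate = 1e-2))
    frozen <- frozenLayers(tl)
    expect_equal(frozen, layerNames(pre)[1:4])
    for (nm in frozen) {
        j <- which(layerNames(pre) == nm)
        expect_identical(tl@layers[[j]]$params, pre@layers[[j]]$params)
    }
    ## the tail must actually have moved
    jd <- which(layerNames(pre) == "dense_out")
    expect_false(identical(tl@layers[[jd]]$params, pre@layers[[jd]]$params))
    ## trainable fraction is a tiny share of all parameters
    frac <- attr(trainingHistory(tl), "trainableFraction")
    expect_lt(frac, 0.01)
    expect_error(transferLearn(pre, ts, cfg, nTrainableTailLayers = 7),
                 class = "smtn_bad_spec")
})

test_that("model checkpoints round-trip through the store", {
    m <- buildNetwork(networkSpec("simreps_lstm", hiddenWidth = 5),
                      trainConfig(seed = 12))
    f <- withr::local_tempfile(fileext = ".rds")
    saveModel(m, f)
    back <- loadModel(f)
    expect_identical(back@layers, m@layers)
    expect_equal(modelFamily(back), "simreps_lstm")
    saveRDS(list(schema = "other"), f)
    expect_error(loadModel(f), class = "smtn_bad_schema")
})

test_that("a tiny CNN trains on well-separated scatter images", {
    p1 <- simParams(nFrames = 400, noiseRange = c(0.03, 0.08))
    acc <- simulateAcceptedFret(40, p1, seed = 13)
    rej <- simulateRejectedFret("low_snr", 40, simParams(nFrames = 400),
                                seed = 14)
    ts <- c(acc, rej)
    cfg <- trainConfig(epochs = 6, batchSize = 20, seed = 15,
                       learningRate = 3e-3)
    m <- trainNetwork(buildNetwork(networkSpec("fret_cnn"), cfg), ts, cfg)
    te <- c(simulateAcceptedFret(20, p1, seed = 16),
            simulateRejectedFret("low_snr", 20, simParams(nFrames = 400),
                                 seed = 17))
    s <- classifyTraces(m, te)
    acc_rate <- mean((s > 0.5) == (classLabels(te) == "ACCEPT"))
    expect_gt(acc_rate, 0.8)
})
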