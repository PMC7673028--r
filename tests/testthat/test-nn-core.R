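test_that("biLSTM classifier gradients match finite differences", {
    set.seed(3)
    spec <- networkSpec("fret_classifier_lstm", nBin = 2, hiddenWidth = 3,
                        dropoutRate = 0)
    model <- buildNetwork(spec, trainConfig(seed = 11))
    B <- 4L; D <- 4L; T <- 5L
    enc <- list(X = array(rnorm(B * D * T), dim = c(B, D, T)),
                lens = c(5L, 3L, 5L, 4L), D = D, steps = T, nBin = 2L)
    yIdx <- c(1L, 2L, 1L, 2L); w2 <- c(1, 2.5)
    lossOf <- function(m)
        classifierLossGrad(networkForward(m, enc, training = TRUE)$logits,
                           yIdx, w2)$loss
    fw <- networkForward(model, enc, training = TRUE)
    lg <- classifierLossGrad(fw$logits, yIdx, w2)
    grads <- networkBackward(model, fw, lg$dLogits)
    expect_lt(checkGradients(model, lossOf, grads), 1e-3)
})

test_that("segmenter (sequence-to-sequence) gradients match finite differences", {
    set.seed(5)
    spec <- networkSpec("fret_segmenter_lstm", nBin = 2, hiddenWidth = 3,
                        dropoutRate = 0)
    model <- buildNetwork(spec, trainConfig(seed = 5))
    B <- 4L; D <- 4L; T <- 5L
    enc <- list(X = array(rnorm(B * D * T), dim = c(B, D, T)),
                lens = c(5L, 3L, 5L, 4L), D = D, steps = T, nBin = 2L)
    yb <- matrix(sample(c(1L, 2L), B * T, TRUE), B, T)
    for (b in seq_len(B))
        if (enc$lens[b] < T) yb[b, (enc$lens[b] + 1):T] <- NA
    lossOf <- function(m)
        segmenterLossGrad(networkForward(m, enc, training = TRUE)$logits,
                          yb, c(1, 10))$loss
    fw <- networkForward(model, enc, training = TRUE)
    lg <- segmenterLossGrad(fw$logits, yb, c(1, 10))
    grads <- networkBackward(model, fw, lg$dLogits)
    expect_lt(checkGradients(model, lossOf, grads), 1e-3)
})

test_that("CNN gradients match finite differences", {
    set.seed(2)
    spec <- networkSpec("fret_cnn", imageSize = 8, cnnFilters = c(2L, 3L),
                        dropoutRate = 0)
    model <- buildNetwork(spec, trainConfig(seed = 4))
    enc <- array(runif(3 * 8 * 8), dim = c(3, 8, 8))
    yIdx <- c(1L, 2L, 2L)
    lossOf <- function(m)
        classifierLossGrad(networkForward(m, enc)$logits, yIdx, c(1, 1))$loss
    fw <- networkForward(model, enc)
    lg <- classifierLossGrad(fw$logits, yIdx, c(1, 1))
    grads <- networkBackward(model, fw, lg$dLogits)
    expect_lt(checkGradients(model, lossOf, grads), 1e-4)
})

test_that("padded batches reproduce per-trace results (mask correctness)", {
    set.seed(6)
    spec <- networkSpec("fret_classifier_lstm", nBin = 2, hiddenWidth = 4,
                        dropoutRate = 0)
    model <- buildNetwork(spec, trainConfig(seed = 7))
    D <- 4L
    X3 <- array(rnorm(1 * D * 3), dim = c(1, D, 3))
    X5 <- array(rnorm(1 * D * 5), dim = c(1, D, 5))
    ## same short trace alone vs padded next to a longer one
    Xb <- array(0, dim = c(2, D, 5))
    Xb[1, , 1:3] <- X3[1, , ]
    Xb[2, , ] <- X5[1, , ]
    solo <- networkForward(model, list(X = X3, lens = 3L), FALSE)$logits
    batch <- networkForward(model, list(X = Xb, lens = c(3L, 5L)),
                            FALSE)$logits
    expect_equal(batch[1, ], solo[1, ], tolerance = 1e-12)
})

test_that("Glorot initialization is seed-deterministic and in range", {
    spec <- networkSpec("simreps_lstm", hiddenWidth = 10)
    m1 <- buildNetwork(spec, trainConfig(seed = 42))
    m2 <- buildNetwork(spec, trainConfig(seed = 42))
    expect_identical(m1@layers, m2@layers)
    m3 <- buildNetwork(spec, trainConfig(seed = 43))
    expect_false(identical(m1@layers[[2]]$params$fwd$W,
                           m3@layers[[2]]$params$fwd$W))
    W <- m1@layers[[2]]$params$fwd$W          # D = 10, H = 10 per gate
    expect_true(all(abs(W) <= sqrt(6 / 20)))
})

test_that("sequence reversal respects per-trace lengths", {
    X <- array(seq_len(2 * 1 * 4), dim = c(2, 1, 4))
    r <- reverseSeqArray(X, c(4L, 2L))
    expect_equal(as.vector(r[1, 1, ]), rev(X[1, 1, ]))
    expect_equal(as.vector(r[2, 1, 1:2]), rev(X[2, 1, 1:2]))
    expect_equal(as.vector(r[2, 1, 3:4]), as.vector(X[2, 1, 3:4]))
    ## double reversal is the identity
    expect_identical(reverseSeqArray(r, c(4L, 2L)), X)
})
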