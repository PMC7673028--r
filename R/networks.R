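#' @include AllClasses.R AllGenerics.R utils.R nn-core.R preprocess.R
NULL

#' Canonical network architectures
#'
#' Builds the layer template for one of the four model families (see
#' [NetworkSpec-class]). The LSTM families take binned traces
#' ([binTrace()]) as input; the CNN takes 32x32 donor/acceptor scatter
#' images ([traceToScatterImage()]).
#'
#' @param family one of `"simreps_lstm"`, `"fret_classifier_lstm"`,
#'   `"fret_segmenter_lstm"`, `"fret_cnn"`.
#' @param nBin frames binned per LSTM step (default 10).
#' @param hiddenWidth bidirectional LSTM cells per direction (default 100).
#' @param nChannels input channel count; defaults to 1 for `simreps_lstm`
#'   and 2 for the smFRET families.
#' @param dropoutRate dropout rate after each LSTM stage (default 0.2).
#' @param cnnFilters filters of the two convolution stages (default
#'   `c(8, 16)`).
#' @param imageSize CNN input side length (default 32).
#' @param minRun segmenter post-processing: accepted runs shorter than this
#'   many frames are removed when expanding bin labels to frames.
#' @return a [NetworkSpec-class].
#' @examples
#' networkSpec("fret_classifier_lstm")
#' @export
networkSpec <- function(family = c("simreps_lstm", "fret_classifier_lstm",
                                   "fret_segmenter_lstm", "fret_cnn"),
                        nBin = 10L, hiddenWidth = 100L, nChannels = NULL,
                        dropoutRate = 0.2, cnnFilters = c(8L, 16L),
                        imageSize = 32L, minRun = 10L) {
    family <- match.arg(family)
    nChannels <- as.integer(nChannels %||%
                                if (family == "simreps_lstm") 1L else 2L)
    H <- as.integer(hiddenWidth)
    layers <- switch(family,
        simreps_lstm = list(
            list(name = "sequence_input", kind = "input_seq"),
            list(name = "bilstm_1", kind = "bilstm", width = H,
                 outputMode = "seq2one"),
            list(name = "dropout_1", kind = "dropout", rate = dropoutRate),
            list(name = "dense_out", kind = "dense", units = 2L),
            list(name = "softmax_out", kind = "softmax")),
        fret_classifier_lstm = list(
            list(name = "sequence_input", kind = "input_seq"),
            list(name = "bilstm_1", kind = "bilstm", width = H,
                 outputMode = "seq2seq"),
            list(name = "dropout_1", kind = "dropout", rate = dropoutRate),
            list(name = "bilstm_2", kind = "bilstm", width = H,
                 outputMode = "seq2one"),
            list(name = "dropout_2", kind = "dropout", rate = dropoutRate),
            list(name = "dense_out", kind = "dense", units = 2L),
            list(name = "softmax_out", kind = "softmax")),
        fret_segmenter_lstm = list(
            list(name = "sequence_input", kind = "input_seq"),
            list(name = "bilstm_1", kind = "bilstm", width = H,
                 outputMode = "seq2seq"),
            list(name = "dropout_1", kind = "dropout", rate = dropoutRate),
            list(name = "bilstm_2", kind = "bilstm", width = H,
                 outputMode = "seq2seq"),
            list(name = "dropout_2", kind = "dropout", rate = dropoutRate),
            list(name = "dense_out", kind = "dense", units = 2L,
                 perStep = TRUE),
            list(name = "softmax_out", kind = "softmax"),
            list(name = "frame_expand", kind = "expand",
                 minRun = as.integer(minRun))),
        fret_cnn = list(
            list(name = "image_input", kind = "input_image",
                 size = as.integer(imageSize)),
            list(name = "conv_1", kind = "conv",
                 filters = as.integer(cnnFilters[1L])),
            list(name = "pool_1", kind = "pool"),
            list(name = "conv_2", kind = "conv",
                 filters = as.integer(cnnFilters[2L])),
            list(name = "pool_2", kind = "pool"),
            list(name = "dense_out", kind = "dense", units = 2L),
            list(name = "softmax_out", kind = "softmax")))
    new("NetworkSpec", family = family, layers = layers,
        nBin = as.integer(nBin), hiddenWidth = H, nChannels = nChannels,
        nClasses = 2L)
}

## Class label order per family; column 2 of the softmax output is the
## positive class whose probability is the reported score.
specClasses <- function(spec) {
    if (spec@family == "simreps_lstm") c("WT", "MUT")
    else c("REJECT", "ACCEPT")
}

#' Default per-class loss weights
#'
#' The reference weight configurations of the weighted cross-entropy loss:
#' `w_MUT = 1`, `w_WT = 1e6` for the one-channel kinetic-fingerprinting
#' classifier (false positives in a wild-type-only sample are heavily
#' penalized); `w_accepted = 1`, `w_rejected = 1` for smFRET trace
#' classification; `w_accepted = 10`, `w_rejected = 1` for smFRET
#' segmentation (manually selected segments are a small fraction of all
#' frames).
#'
#' @param family a model family name (see [networkSpec()]).
#' @return named numeric vector of positive weights.
#' @export
defaultClassWeights <- function(family) {
    switch(family,
        simreps_lstm = c(MUT = 1, WT = 1e6),
        fret_classifier_lstm = c(ACCEPT = 1, REJECT = 1),
        fret_cnn = c(ACCEPT = 1, REJECT = 1),
        fret_segmenter_lstm = c(ACCEPT = 10, REJECT = 1),
        stop("unknown family: ", family))
}

#' Reference composition of the one-channel training set
#'
#' Per-class trace counts of the reference kinetic-fingerprinting training
#' set (mutant-only and wild-type-only experiments) mirrored by the
#' package's benchmark recipes: 706 MUT and 1478 WT traces, 2184 in total.
#'
#' @return named integer vector `c(MUT = 706, WT = 1478)`.
#' @export
simrepsReferenceCounts <- function() c(MUT = 706L, WT = 1478L)

#' Build an untrained network
#'
#' Instantiates the parameters of a [networkSpec()] template with Glorot
#' (uniform) initialization, using the seed of `config`; two builds with the
#' same spec and seed have identical initial parameters.
#'
#' @param spec a [NetworkSpec-class].
#' @param config a [trainConfig()]; its `seed` drives initialization.
#' @param modelID identifier carried into decision tables.
#' @return an untrained [TrainedModel-class].
#' @export
buildNetwork <- function(spec, config = trainConfig(),
                         modelID = spec@family) {
    validObject(spec)
    withLocalSeed(deriveSeed(config@seed, 1L), {
        inDim <- spec@nChannels * spec@nBin
        H <- spec@hiddenWidth
        imgC <- 1L
        imgS <- NULL
        layers <- lapply(spec@layers, function(ly) {
            st <- list(name = ly$name, kind = ly$kind, conf = ly,
                       params = NULL)
            if (ly$kind == "input_image") imgS <<- ly$size
            if (ly$kind == "bilstm") {
                st$params <- list(fwd = initLSTMParams(inDim, H),
                                  bwd = initLSTMParams(inDim, H))
                inDim <<- 2L * H
            } else if (ly$kind == "conv") {
                lim <- sqrt(6 / (9L * imgC + ly$filters))
                st$params <- list(
                    W = matrix(stats::runif(9L * imgC * ly$filters,
                                            -lim, lim),
                               9L * imgC, ly$filters),
                    b = rep(0, ly$filters))
                imgC <<- ly$filters
            } else if (ly$kind == "pool") {
                imgS <<- imgS %/% 2L
            } else if (ly$kind == "dense") {
                K <- if (spec@family == "fret_cnn")
                         imgS * imgS * imgC else inDim
                st$params <- list(W = glorotMat(K, ly$units),
                                  b = rep(0, ly$units))
            }
            st
        })
        new("TrainedModel", spec = spec, layers = layers, config = config,
            history = data.frame(epoch = integer(), loss = numeric()),
            modelID = modelID, trained = FALSE)
    })
}

## ---- forward / backward orchestration ---------------------------------------

## enc: encodeLSTMBatch() output for LSTM families, [B,S,S] array for CNN.
## Returns logits ([B,2] or [B,2,T]), per-layer caches, lens.
networkForward <- function(model, enc, training = FALSE) {
    spec <- model@spec
    isCNN <- spec@family == "fret_cnn"
    if (isCNN) {
        d <- dim(enc)
        cur <- array(enc, dim = c(d[1L], d[2L], d[3L], 1L))
        lens <- NULL
    } else {
        cur <- enc$X
        lens <- enc$lens
        if (dim(cur)[2L] != spec@nChannels * spec@nBin)
            stopWith("smtn_channel_mismatch",
                     "layer 'sequence_input': got %d features, spec expects %d",
                     dim(cur)[2L], spec@nChannels * spec@nBin)
    }
    caches <- vector("list", length(model@layers))
    for (j in seq_along(model@layers)) {
        ly <- model@layers[[j]]
        if (ly$kind %in% c("input_seq", "input_image", "softmax", "expand"))
            next
        if (ly$kind == "bilstm") {
            r <- bilstmForward(cur, lens, ly$params, ly$conf$outputMode,
                               needCache = training)
        } else if (ly$kind == "dropout") {
            r <- dropoutForward(cur, ly$conf$rate, training)
        } else if (ly$kind == "dense") {
            if (isCNN && !is.matrix(cur)) {
                d <- dim(cur)
                cnnDims <- d
                cur <- matrix(cur, d[1L], prod(d[-1L]))
                r <- denseForward(cur, ly$params)
                r$cache$cnnDims <- cnnDims
            } else r <- denseForward(cur, ly$params)
        } else if (ly$kind == "conv") {
            r <- convForward(cur, ly$params)
        } else if (ly$kind == "pool") {
            r <- poolForward(cur)
        } else {
            stopWith("smtn_bad_spec", "layer '%s': unknown kind '%s'",
                     ly$name, ly$kind)
        }
        caches[[j]] <- r$cache
        cur <- r$out
    }
    list(logits = cur, caches = caches, lens = lens)
}

## dLogits flows back from the loss; gradients returned per layer name.
## Backward stops below `stopAt` (the earliest trainable layer index) so a
## frozen lower stack costs nothing — used by transfer learning.
networkBackward <- function(model, fw, dLogits, stopAt = 1L) {
    n <- length(model@layers)
    grads <- stats::setNames(vector("list", n), layerNames(model))
    d <- dLogits
    for (j in rev(seq_len(n))) {
        ly <- model@layers[[j]]
        if (ly$kind %in% c("softmax", "expand", "input_seq", "input_image"))
            next
        if (j < stopAt) break
        if (ly$kind == "dense") {
            r <- denseBackward(fw$caches[[j]], ly$params, d)
            grads[[j]] <- r$grads
            d <- r$dX
            if (!is.null(fw$caches[[j]]$cnnDims))
                d <- array(d, dim = fw$caches[[j]]$cnnDims)
        } else if (ly$kind == "dropout") {
            if (!is.null(fw$caches[[j]])) d <- d * fw$caches[[j]]
        } else if (ly$kind == "bilstm") {
            r <- bilstmBackward(fw$caches[[j]], ly$params, d)
            grads[[j]] <- r$grads
            d <- r$dX
        } else if (ly$kind == "conv") {
            r <- convBackward(fw$caches[[j]], ly$params, d)
            grads[[j]] <- r$grads
            d <- r$dX
        } else if (ly$kind == "pool") {
            d <- poolBackward(fw$caches[[j]], d)
        }
    }
    grads
}

## ---- loss --------------------------------------------------------------------

#' Weighted cross-entropy loss
#'
#' `L = -sum_i sum_j w_i Y_ij log P_ij` over traces `j` and labels `i`
#' (here rows are traces, columns are labels). Probabilities at true labels
#' are floored at `eps = 1e-12` so that a zero prediction yields a large
#' finite loss rather than infinity; flooring is reported via a message.
#'
#' @param P numeric matrix `n x n_labels` of predicted probabilities; rows
#'   must sum to 1 (tolerance 1e-6).
#' @param Y one-hot truth matrix of the same dimension.
#' @param w named positive weights, one per label; matched to `colnames(P)`
#'   when present, otherwise taken in column order.
#' @return the scalar loss (>= 0; 0 iff every true label is predicted with
#'   probability 1).
#' @examples
#' P <- rbind(c(0.5, 0.5))
#' Y <- rbind(c(0, 1))
#' weightedCrossEntropy(P, Y, c(MUT = 1, WT = 1e6))  # 1e6 * log(2)
#' @export
weightedCrossEntropy <- function(P, Y, w) {
    stopifnot(is.matrix(P), is.matrix(Y), all(dim(P) == dim(Y)),
              all(w > 0))
    if (any(abs(rowSums(P) - 1) > 1e-6))
        stopWith("smtn_bad_probs", "rows of P must sum to 1")
    if (!is.null(colnames(P)) && !is.null(names(w)))
        w <- w[colnames(P)]
    if (length(w) != ncol(P))
        stopWith("smtn_bad_weights", "need one weight per label column")
    eps <- 1e-12
    atTruth <- P[Y == 1]
    if (any(atTruth < eps))
        message("weightedCrossEntropy: ", sum(atTruth < eps),
                " true-label probabilities floored at 1e-12")
    W <- matrix(w, nrow(P), ncol(P), byrow = TRUE)
    -sum(W * Y * log(pmax(P, eps)))
}

## Per-trace classifier loss + gradient w.r.t. logits. yIdx in {1,2};
## normalized by the total weight in the batch so step size is scale-free.
classifierLossGrad <- function(logits, yIdx, w2) {
    B <- nrow(logits)
    P <- softmaxRows(logits)
    wv <- w2[yIdx]
    norm <- sum(wv)
    pTrue <- pmax(P[cbind(seq_len(B), yIdx)], 1e-12)
    loss <- -sum(wv * log(pTrue)) / norm
    Yh <- matrix(0, B, 2L)
    Yh[cbind(seq_len(B), yIdx)] <- 1
    dLogits <- wv * (P - Yh) / norm
    list(loss = loss, dLogits = dLogits)
}

## Per-step segmentation loss. logits [B,2,S]; yIdx [B,S] in {1,2}, NA at
## padded steps.
segmenterLossGrad <- function(logits, yIdx, w2) {
    d <- dim(logits)
    M <- flattenSeq(logits)          # [B*S, 2]
    yv <- as.vector(yIdx)            # column-major == flattenSeq order
    valid <- !is.na(yv)
    P <- softmaxRows(M[valid, , drop = FALSE])
    yi <- yv[valid]
    wv <- w2[yi]
    norm <- sum(wv)
    pTrue <- pmax(P[cbind(seq_along(yi), yi)], 1e-12)
    loss <- -sum(wv * log(pTrue)) / norm
    Yh <- matrix(0, nrow(P), 2L)
    Yh[cbind(seq_along(yi), yi)] <- 1
    dM <- matrix(0, nrow(M), 2L)
    dM[valid, ] <- wv * (P - Yh) / norm
    list(loss = loss, dLogits = unflattenSeq(dM, d[1L], 2L, d[3L]))
}

## ---- training ----------------------------------------------------------------

## Build the per-trace (classifier) or per-step (segmenter) integer targets.
trainingTargets <- function(model, ts, labels, masks) {
    spec <- model@spec
    cls <- specClasses(spec)
    if (spec@family == "fret_segmenter_lstm") {
        if (is.null(masks)) {
            masks <- traceData(ts)$frameMask
            if (is.null(masks))
                stopWith("smtn_missing_labels",
                         "segmenter training needs per-frame masks (frameMask)")
        }
        enc <- NULL
        return(list(kind = "mask", masks = masks))
    }
    if (is.null(labels)) labels <- classLabels(ts)
    if (is.null(labels))
        stopWith("smtn_missing_labels",
                 "no class labels found in traceData and none supplied")
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), cls)
    if (length(bad))
        stopWith("smtn_bad_label",
                 "unknown label(s) %s; this family uses {%s}",
                 paste(bad, collapse = ", "), paste(cls, collapse = ", "))
    if (length(unique(labels)) < 2L)
        stopWith("smtn_missing_class",
                 "training data must contain at least one example per class (%s)",
                 paste(cls, collapse = ", "))
    list(kind = "class", yIdx = match(labels, cls))
}

encodeForModel <- function(model, ts) {
    spec <- model@spec
    if (any(nChannels(ts) != spec@nChannels))
        stopWith("smtn_channel_mismatch",
                 "model family %s expects %d-channel traces",
                 spec@family, spec@nChannels)
    if (spec@family == "fret_cnn")
        encodeImageBatch(ts, spec@layers[[1L]]$size)
    else encodeLSTMBatch(ts, spec@nBin, "robust_z")
}

sliceEnc <- function(enc, idx, isCNN) {
    if (isCNN) return(enc[idx, , , drop = FALSE])
    list(X = enc$X[idx, , , drop = FALSE], lens = enc$lens[idx],
         D = enc$D, steps = enc$steps, nBin = enc$nBin,
         framesUsed = enc$framesUsed[idx], nFrames = enc$nFrames[idx])
}

## Per-step targets for a segmenter batch: majority label per bin, NA at pads.
maskTargets <- function(masks, idx, nBin, steps, lens) {
    B <- length(idx)
    y <- matrix(NA_integer_, B, steps)
    for (b in seq_len(B)) {
        bl <- binMaskLabels(masks[[idx[b]]], nBin)
        y[b, seq_len(lens[b])] <- ifelse(bl[seq_len(lens[b])], 2L, 1L)
    }
    y
}

#' Train a network
#'
#' Minibatch training with ADAM (initial learning rate from `config`),
#' weighted cross-entropy loss (class weights from `config` or the family
#' defaults, see [defaultClassWeights()]), optional layer freezing, and
#' early stopping when the training loss plateaus. All randomness
#' (shuffling, dropout) derives from `config@seed`; a repeated run with the
#' same model, data and config yields identical parameters.
#'
#' @param model a [TrainedModel-class] from [buildNetwork()].
#' @param ts training [TraceSet-class].
#' @param config a [trainConfig()]; defaults to the model's.
#' @param labels per-trace class labels (defaults to
#'   `classLabels(ts)`); ignored by the segmenter family.
#' @param masks per-trace logical frame masks for segmenter training
#'   (defaults to the ground-truth `frameMask` column).
#' @return the trained model, with per-epoch losses in
#'   [trainingHistory()].
#' @export
trainNetwork <- function(model, ts, config = model@config, labels = NULL,
                         masks = NULL) {
    spec <- model@spec
    validObject(config)
    isCNN <- spec@family == "fret_cnn"
    isSeg <- spec@family == "fret_segmenter_lstm"
    tgt <- trainingTargets(model, ts, labels, masks)
    w2 <- config@classWeights
    if (!length(w2)) w2 <- defaultClassWeights(spec@family)
    cls <- specClasses(spec)
    if (!all(cls %in% names(w2)))
        stopWith("smtn_bad_weights", "classWeights must name %s",
                 paste(cls, collapse = " and "))
    w2 <- unname(w2[cls])
    enc <- encodeForModel(model, ts)
    n <- nTraces(ts)
    frozen <- config@frozenLayers
    lnames <- layerNames(model)
    bad <- setdiff(frozen, lnames)
    if (length(bad))
        stopWith("smtn_bad_spec", "unknown frozen layer(s): %s",
                 paste(bad, collapse = ", "))
    trainable <- which(!lnames %in% frozen &
                       !vapply(model@layers, function(l) is.null(l$params),
                               logical(1)))
    if (!length(trainable))
        stopWith("smtn_bad_spec", "all parameterized layers are frozen")
    stopAt <- min(trainable)
    params <- lapply(model@layers, `[[`, "params")
    adamState <- lapply(params, function(p) if (is.null(p)) NULL
                        else adamInit(p))
    step <- 0L
    history <- model@history
    withLocalSeed(deriveSeed(config@seed, 2L), {
        bestLoss <- Inf; stale <- 0L
        for (ep in seq_len(config@epochs)) {
            ord <- sample.int(n)
            batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
            epLoss <- 0
            for (bi in batches) {
                eb <- sliceEnc(enc, bi, isCNN)
                for (j in trainable)
                    model@layers[[j]]$params <- params[[j]]
                fw <- networkForward(model, eb, training = TRUE)
                if (isSeg) {
                    y <- maskTargets(tgt$masks, bi, spec@nBin,
                                     dim(fw$logits)[3L], eb$lens)
                    lg <- segmenterLossGrad(fw$logits, y, w2)
                } else {
                    lg <- classifierLossGrad(fw$logits, tgt$yIdx[bi], w2)
                }
                if (!is.finite(lg$loss))
                    stopWith("smtn_nan_loss",
                             "non-finite loss at epoch %d; try a lower learning rate",
                             ep)
                epLoss <- epLoss + lg$loss * length(bi)
                grads <- networkBackward(model, fw, lg$dLogits,
                                         stopAt = stopAt)
                step <- step + 1L
                for (j in trainable) {
                    if (is.null(grads[[j]])) next
                    up <- adamUpdate(params[[j]], grads[[j]],
                                     adamState[[j]], config@learningRate,
                                     step)
                    params[[j]] <- up$params
                    adamState[[j]] <- up$state
                }
            }
            epLoss <- epLoss / n
            history <- rbind(history,
                             data.frame(epoch = nrow(history) + 1L,
                                        loss = epLoss))
            if (config@patience > 0L) {
                if (epLoss < bestLoss - 1e-6) {
                    bestLoss <- epLoss; stale <- 0L
                } else {
                    stale <- stale + 1L
                    if (stale >= config@patience) break
                }
            }
        }
    })
    for (j in trainable) model@layers[[j]]$params <- params[[j]]
    model@config <- config
    model@history <- history
    model@trained <- TRUE
    model
}

## ---- inference ----------------------------------------------------------------

#' Classify traces
#'
#' Applies a classifier model to a [TraceSet-class] and returns one score
#' per trace in \[0, 1\]: the probability that the trace belongs to the
#' positive class (`MUT` for the one-channel family, `ACCEPT` for the
#' smFRET families). Scores are independent of batch composition and order.
#'
#' @param model a trained classifier ([buildNetwork()] families
#'   `simreps_lstm`, `fret_classifier_lstm`, `fret_cnn`).
#' @param ts a [TraceSet-class] with the channel count the model expects.
#' @param batchSize traces per forward pass.
#' @return named numeric vector of scores, in trace order.
#' @export
classifyTraces <- function(model, ts, batchSize = 256L) {
    if (model@spec@family == "fret_segmenter_lstm")
        stopWith("smtn_bad_family",
                 "model is a segmenter; use segmentTraces()")
    n <- nTraces(ts)
    scores <- numeric(n)
    isCNN <- model@spec@family == "fret_cnn"
    for (start in seq(1L, n, by = batchSize)) {
        idx <- start:min(start + batchSize - 1L, n)
        enc <- encodeForModel(model, ts[idx])
        fw <- networkForward(model, enc, training = FALSE)
        scores[idx] <- softmaxRows(fw$logits)[, 2L]
    }
    stats::setNames(scores, traceIDs(ts))
}

#' Segment traces
#'
#' Applies a per-frame segmenter to each trace and returns a logical mask of
#' length `T` per trace (`TRUE` = frame accepted for analysis). The network
#' emits one label per `nBin`-frame step; labels are expanded back to frames
#' with [expandBinLabels()], and accepted runs shorter than the spec's
#' `minRun` frames are removed.
#'
#' @param model a trained `fret_segmenter_lstm` model.
#' @param ts a two-channel [TraceSet-class].
#' @param batchSize traces per forward pass.
#' @return named list of logical vectors (one per trace, length = trace
#'   frames).
#' @export
segmentTraces <- function(model, ts, batchSize = 256L) {
    if (model@spec@family != "fret_segmenter_lstm")
        stopWith("smtn_bad_family", "model family %s cannot segment",
                 model@spec@family)
    n <- nTraces(ts)
    out <- vector("list", n)
    minRun <- model@spec@layers[[length(model@spec@layers)]]$minRun %||% 0L
    for (start in seq(1L, n, by = batchSize)) {
        idx <- start:min(start + batchSize - 1L, n)
        enc <- encodeForModel(model, ts[idx])
        fw <- networkForward(model, enc, training = FALSE)
        for (b in seq_along(idx)) {
            S <- enc$lens[b]
            lgt <- fw$logits[b, , seq_len(S), drop = FALSE]
            accept <- lgt[1L, 2L, ] > lgt[1L, 1L, ]
            out[[idx[b]]] <- expandBinLabels(accept, enc$nBin,
                                             enc$nFrames[b], minRun)
        }
    }
    stats::setNames(out, traceIDs(ts))
}

#' Adapt a trained network to a new dataset (transfer learning)
#'
#' Freezes all but the last `nTrainableTailLayers` layers of a pretrained
#' model and retrains the tail on a (typically small) labeled dataset from
#' the new system. Frozen parameters are bit-identical before and after;
#' the trainable tail is a tiny fraction of the total parameters (for the
#' 7-layer classifier: the final dense head, well under 1%).
#'
#' @param pretrained a trained [TrainedModel-class].
#' @param ts labeled [TraceSet-class] from the new system (a few hundred
#'   traces suffice).
#' @param config a [trainConfig()] for the adaptation run.
#' @param nTrainableTailLayers how many trailing layers stay trainable
#'   (default 3, e.g. dropout + dense + softmax of the classifier).
#' @param labels,masks as in [trainNetwork()].
#' @return the adapted model; `frozenLayers()` lists the frozen stack and
#'   `attr(trainingHistory(model), "trainableFraction")` records the
#'   trainable parameter fraction.
#' @export
transferLearn <- function(pretrained, ts, config = trainConfig(),
                          nTrainableTailLayers = 3L, labels = NULL,
                          masks = NULL) {
    nl <- length(pretrained@spec@layers)
    if (nTrainableTailLayers >= nl)
        stopWith("smtn_bad_spec",
                 "nTrainableTailLayers (%d) must be < total layers (%d)",
                 nTrainableTailLayers, nl)
    lnames <- layerNames(pretrained)
    frozen <- lnames[seq_len(nl - nTrainableTailLayers)]
    config@frozenLayers <- frozen
    perLayer <- nParameters(pretrained, perLayer = TRUE)
    frac <- sum(perLayer[!names(perLayer) %in% frozen]) / sum(perLayer)
    model <- trainNetwork(pretrained, ts, config, labels = labels,
                          masks = masks)
    attr(model@history, "trainableFraction") <- frac
    model
}

## ---- model store ---------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding the architecture spec, all parameters,
#' the training config (including frozen-layer bookkeeping) and the per-epoch
#' history, under a versioned schema.
#'
#' @param model a [TrainedModel-class].
#' @param path file path.
#' @return `saveModel`: `path`, invisibly. `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
    obj <- list(schema = "smTraceNet-model-1",
                spec = model@spec, layers = model@layers,
                config = model@config, history = model@history,
                modelID = model@modelID, trained = model@trained)
    saveRDS(obj, path)
    invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
    obj <- readRDS(path)
    if (!identical(obj$schema, "smTraceNet-model-1"))
        stopWith("smtn_bad_schema", "not a smTraceNet model checkpoint: %s",
                 path)
    new("TrainedModel", spec = obj$spec, layers = obj$layers,
        config = obj$config, history = obj$history, modelID = obj$modelID,
        trained = obj$trained)
}
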