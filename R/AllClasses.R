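#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
NULL

#' TraceSet: a collection of single-molecule intensity time traces
#'
#' A `TraceSet` holds an ordered, named collection of per-molecule
#' intensity-versus-time records. Each trace is a numeric matrix with one row
#' per fluorescence channel (1 for kinetic-fingerprinting data, 2 for
#' donor/acceptor smFRET data) and one column per camera frame. Per-trace
#' metadata (channel count, frame interval, movie of origin, and -- for
#' simulated data -- the generative ground truth) live in a parallel
#' [S4Vectors::DataFrame] whose rows match the traces.
#'
#' @slot traces named list of numeric matrices, `n_channels x T` each.
#' @slot traceData `DataFrame` with one row per trace. Always contains
#'   `nChannels`, `frameInterval` (seconds per frame) and `movieID`;
#'   simulator output adds ground-truth columns (see [simulateAcceptedFret()]).
#' @slot metadata free-form provenance list.
#'
#' @seealso [TraceSet()] constructor, [simulateAcceptedFret()],
#'   [readTraceTable()].
#' @export
setClass("TraceSet",
    slots = c(traces = "list", traceData = "DataFrame", metadata = "list"))

setValidity("TraceSet", function(object) {
    tr <- object@traces
    msg <- character()
    if (length(tr) > 0L) {
        ids <- names(tr)
        if (is.null(ids) || anyNA(ids) || any(ids == ""))
            msg <- c(msg, "all traces must be named by a non-empty trace_id")
        else if (anyDuplicated(ids))
            msg <- c(msg, "trace_ids must be unique within a TraceSet")
        ok <- vapply(tr, function(m) {
            is.matrix(m) && is.numeric(m) && nrow(m) %in% c(1L, 2L) &&
                ncol(m) >= 1L && all(is.finite(m))
        }, logical(1))
        if (!all(ok))
            msg <- c(msg, sprintf(
                "trace '%s' is not a finite numeric matrix with 1 or 2 channel rows",
                names(tr)[which(!ok)[1L]]))
    }
    if (nrow(object@traceData) != length(tr))
        msg <- c(msg, "traceData must have one row per trace")
    if (length(msg)) msg else TRUE
})

#' Construct a TraceSet
#'
#' @param traces named list of numeric matrices (`n_channels x T`), or a
#'   single matrix (wrapped as one trace).
#' @param traceData optional `DataFrame`/data.frame of per-trace metadata;
#'   missing standard columns (`nChannels`, `frameInterval`, `movieID`) are
#'   filled in.
#' @param frameInterval seconds per frame used when `traceData` lacks the
#'   column (default 0.1 s, i.e. per-frame rates x 10 give per-second rates).
#' @param metadata free-form provenance list.
#' @return A [TraceSet-class] object.
#' @examples
#' ts <- TraceSet(list(t1 = matrix(rnorm(200, 1000, 50), nrow = 2)))
#' nTraces(ts)
#' @export
TraceSet <- function(traces, traceData = NULL, frameInterval = 0.1,
                     metadata = list()) {
    if (is.matrix(traces)) traces <- list(trace_1 = traces)
    if (is.null(names(traces)) && length(traces) > 0L)
        names(traces) <- sprintf("trace_%d", seq_along(traces))
    traces <- lapply(traces, function(m) {
        if (!is.matrix(m)) m <- matrix(as.numeric(m), nrow = 1L)
        storage.mode(m) <- "double"
        m
    })
    n <- length(traces)
    if (is.null(traceData)) {
        traceData <- S4Vectors::DataFrame(row.names = names(traces))
    } else {
        traceData <- as(traceData, "DataFrame")
        rownames(traceData) <- names(traces)
    }
    if (is.null(traceData$nChannels))
        traceData$nChannels <- vapply(traces, nrow, integer(1))
    if (is.null(traceData$frameInterval))
        traceData$frameInterval <- rep(frameInterval, n)
    if (is.null(traceData$movieID))
        traceData$movieID <- rep(NA_character_, n)
    new("TraceSet", traces = traces, traceData = traceData,
        metadata = metadata)
}

#' NetworkSpec: architecture description for a trace network
#'
#' Describes one of the four canonical model families:
#' \describe{
#'   \item{`simreps_lstm`}{5 layers: binned sequence input, one bidirectional
#'     LSTM (sequence-to-one), dropout, dense, 2-way softmax. For one-channel
#'     kinetic-fingerprinting traces.}
#'   \item{`fret_classifier_lstm`}{7 layers: adds a second bidirectional LSTM
#'     stage. Per-trace Accept/Reject scores for two-channel smFRET traces.}
#'   \item{`fret_segmenter_lstm`}{8 layers: two sequence-to-sequence
#'     bidirectional LSTMs, per-step dense + softmax, and a label-expansion
#'     layer mapping one label per input bin back to one label per frame.}
#'   \item{`fret_cnn`}{convolutional classifier over the 32x32 donor/acceptor
#'     scatter image of a trace.}
#' }
#'
#' @slot family character, one of the four families above.
#' @slot layers ordered list of named layer descriptors (kind, sizes,
#'   direction, output mode).
#' @slot nBin frames binned per LSTM step (default 10).
#' @slot hiddenWidth bidirectional LSTM cells per direction (default 100).
#' @slot nChannels expected channel count of input traces.
#' @slot nClasses number of output classes (always 2).
#' @seealso [networkSpec()], [buildNetwork()].
#' @export
setClass("NetworkSpec",
    slots = c(family = "character", layers = "list", nBin = "integer",
              hiddenWidth = "integer", nChannels = "integer",
              nClasses = "integer"))

setValidity("NetworkSpec", function(object) {
    fams <- c("simreps_lstm", "fret_classifier_lstm", "fret_segmenter_lstm",
              "fret_cnn")
    msg <- character()
    if (length(object@family) != 1L || !object@family %in% fams)
        msg <- c(msg, paste("family must be one of:",
                            paste(fams, collapse = ", ")))
    if (object@nClasses != 2L)
        msg <- c(msg, "nClasses must be 2")
    kinds <- vapply(object@layers, `[[`, character(1), "kind")
    if (sum(kinds %in% c("softmax")) != 1L)
        msg <- c(msg, "spec must contain exactly one softmax output head")
    if (length(msg)) msg else TRUE
})

#' TrainConfig: optimizer and training-loop settings
#'
#' Defaults follow the reference training recipe: ADAM with initial learning
#' rate 1e-4 and Glorot (uniform) initialization.
#'
#' @slot optimizer character, `"adam"`.
#' @slot learningRate initial learning rate (default `1e-4`).
#' @slot initializer character, `"glorot"`.
#' @slot epochs training epochs.
#' @slot batchSize minibatch size.
#' @slot seed integer seed controlling initialization, shuffling and dropout.
#' @slot classWeights named positive weights, one per class label, used by the
#'   weighted cross-entropy loss (see [weightedCrossEntropy()] and
#'   [defaultClassWeights()]).
#' @slot frozenLayers names of layers excluded from updates (transfer
#'   learning).
#' @slot patience early-stopping patience in epochs (0 disables).
#' @seealso [trainConfig()], [trainNetwork()], [transferLearn()].
#' @export
setClass("TrainConfig",
    slots = c(optimizer = "character", learningRate = "numeric",
              initializer = "character", epochs = "integer",
              batchSize = "integer", seed = "integer",
              classWeights = "numeric", frozenLayers = "character",
              patience = "integer"))

setValidity("TrainConfig", function(object) {
    msg <- character()
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (length(object@classWeights) &&
        (is.null(names(object@classWeights)) ||
         any(object@classWeights <= 0)))
        msg <- c(msg, "classWeights must be named and strictly positive")
    if (length(msg)) msg else TRUE
})

#' Create a training configuration
#'
#' @param epochs number of passes over the training data.
#' @param batchSize minibatch size.
#' @param seed integer seed; all randomness in a training run (parameter
#'   initialization, shuffling, dropout masks) derives from it.
#' @param learningRate initial ADAM learning rate (default `1e-4`).
#' @param classWeights named positive per-class loss weights; `NULL` means
#'   the model family's defaults (see [defaultClassWeights()]).
#' @param frozenLayers character vector of layer names to freeze.
#' @param patience early-stopping patience on the training loss plateau, in
#'   epochs; 0 disables early stopping.
#' @param optimizer,initializer currently `"adam"` and `"glorot"`.
#' @return A [TrainConfig-class] object.
#' @export
trainConfig <- function(epochs = 10L, batchSize = 100L, seed = 1L,
                        learningRate = 1e-4, classWeights = numeric(),
                        frozenLayers = character(), patience = 0L,
                        optimizer = "adam", initializer = "glorot") {
    if (is.null(classWeights)) classWeights <- numeric()
    new("TrainConfig", optimizer = optimizer, learningRate = learningRate,
        initializer = initializer, epochs = as.integer(epochs),
        batchSize = as.integer(batchSize), seed = as.integer(seed),
        classWeights = classWeights, frozenLayers = frozenLayers,
        patience = as.integer(patience))
}

#' TrainedModel: a network with its parameters and provenance
#'
#' @slot spec the [NetworkSpec-class].
#' @slot layers list of layer states; each trainable layer carries its
#'   parameter matrices (addressable per layer for transfer learning).
#' @slot config the [TrainConfig-class] used to initialize/train the model.
#' @slot history data.frame with one row per completed epoch (`epoch`,
#'   `loss`, and held-out metrics when provided).
#' @slot modelID short identifier carried into decision tables.
#' @slot trained logical; `FALSE` for a freshly built network.
#' @seealso [buildNetwork()], [trainNetwork()], [classifyTraces()],
#'   [segmentTraces()], [transferLearn()].
#' @export
setClass("TrainedModel",
    slots = c(spec = "NetworkSpec", layers = "list", config = "TrainConfig",
              history = "data.frame", modelID = "character",
              trained = "logical"))
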