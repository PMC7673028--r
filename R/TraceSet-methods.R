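#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn TraceSet number of traces
#' @param x a `TraceSet`
#' @export
setMethod("nTraces", "TraceSet", function(x) length(x@traces))

#' @describeIn TraceSet trace identifiers, in file/creation order
#' @export
setMethod("traceIDs", "TraceSet", function(x) names(x@traces))

#' @describeIn TraceSet the `n_channels x T` intensity matrix of trace `i`
#'   (index or trace_id)
#' @param i trace index or trace_id
#' @export
setMethod("intensities", "TraceSet", function(x, i) {
    m <- x@traces[[i]]
    if (is.null(m)) stop("no trace '", i, "' in TraceSet")
    m
})

#' @describeIn TraceSet integer vector of trace lengths (frames)
#' @export
setMethod("traceLengths", "TraceSet",
    function(x) vapply(x@traces, ncol, integer(1)))

#' @describeIn TraceSet per-trace channel counts
#' @export
setMethod("nChannels", "TraceSet", function(x) x@traceData$nChannels)

#' @describeIn TraceSet per-trace metadata `DataFrame`
#' @export
setMethod("traceData", "TraceSet", function(x) x@traceData)

#' @describeIn TraceSet replace the per-trace metadata
#' @param value replacement `DataFrame` (one row per trace)
#' @export
setMethod("traceData<-", "TraceSet", function(x, value) {
    x@traceData <- as(value, "DataFrame")
    validObject(x)
    x
})

#' @describeIn TraceSet simulator ground truth (the `traceData` columns
#'   written by the synthetic generators), or NULL for experimental data
#' @export
setMethod("groundTruth", "TraceSet", function(x) {
    gt <- c("classLabel", "artifactKind", "E1", "E2", "k12", "k21",
            "nStates", "donorBleach", "acceptorBleach", "noiseFraction",
            "kOn", "kOff", "statePath", "frameMask")
    keep <- intersect(gt, colnames(x@traceData))
    if (!length(keep)) return(NULL)
    x@traceData[, keep, drop = FALSE]
})

#' @describeIn TraceSet per-trace class labels (`classLabel` column), or NULL
#' @export
setMethod("classLabels", "TraceSet", function(x) {
    lab <- x@traceData$classLabel
    if (is.null(lab)) NULL else stats::setNames(lab, traceIDs(x))
})

#' @describeIn TraceSet number of traces (alias of `nTraces`)
#' @export
setMethod("length", "TraceSet", function(x) length(x@traces))

#' @describeIn TraceSet subset by index, logical vector or trace_id
#' @param j,drop,... ignored
#' @export
setMethod("[", "TraceSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) {
        miss <- setdiff(i, names(x@traces))
        if (length(miss))
            stop("unknown trace_ids: ", paste(miss, collapse = ", "))
    }
    new("TraceSet", traces = x@traces[i],
        traceData = x@traceData[i, , drop = FALSE], metadata = x@metadata)
})

#' Concatenate TraceSets
#'
#' @param x,... `TraceSet` objects with disjoint trace_ids.
#' @return the combined `TraceSet`
#' @export
setMethod("c", "TraceSet", function(x, ...) {
    all <- c(list(x), list(...))
    traces <- do.call(c, lapply(all, function(s) s@traces))
    tds <- lapply(all, function(s) s@traceData)
    cols <- unique(unlist(lapply(tds, colnames)))
    tds <- lapply(tds, function(td) {
        for (cl in setdiff(cols, colnames(td))) td[[cl]] <- NA
        td[, cols, drop = FALSE]
    })
    new("TraceSet", traces = traces, traceData = do.call(rbind, tds),
        metadata = x@metadata)
})

setMethod("show", "TraceSet", function(object) {
    n <- nTraces(object)
    cat("TraceSet with", n, "traces\n")
    if (n > 0L) {
        ch <- unique(object@traceData$nChannels)
        len <- range(traceLengths(object))
        cat("  channels:", paste(ch, collapse = "/"),
            " frames:", if (len[1] == len[2]) len[1]
                        else paste(len[1], "-", len[2]), "\n")
        lab <- object@traceData$classLabel
        if (!is.null(lab))
            cat("  labels: ",
                paste(sprintf("%s=%d", names(table(lab)), table(lab)),
                      collapse = ", "), "\n", sep = "")
        ids <- traceIDs(object)
        cat("  trace_ids:", paste(utils::head(ids, 4L), collapse = ", "),
            if (n > 4L) "..." else "", "\n")
    }
    invisible(object)
})

setMethod("show", "NetworkSpec", function(object) {
    cat("NetworkSpec:", object@family, "(", length(object@layers),
        "layers )\n")
    for (ly in object@layers)
        cat("  -", ly$name, ":", ly$kind,
            if (!is.null(ly$width)) paste0("[", ly$width, "]") else "", "\n")
    invisible(object)
})

setMethod("show", "TrainedModel", function(object) {
    cat("TrainedModel <", object@modelID, "> family:", object@spec@family,
        if (object@trained) "(trained)" else "(untrained)", "\n")
    cat("  parameters:", nParameters(object), "\n")
    fr <- frozenLayers(object)
    if (length(fr)) cat("  frozen layers:", paste(fr, collapse = ", "), "\n")
    if (nrow(object@history))
        cat("  epochs trained:", max(object@history$epoch), " final loss:",
            signif(utils::tail(object@history$loss, 1L), 4), "\n")
    invisible(object)
})

#' @describeIn TrainedModel the architecture family
#' @param x a `TrainedModel`
#' @export
setMethod("modelFamily", "TrainedModel", function(x) x@spec@family)

#' @describeIn TrainedModel ordered layer names
#' @export
setMethod("layerNames", "TrainedModel",
    function(x) vapply(x@spec@layers, `[[`, character(1), "name"))

#' @describeIn TrainedModel total (or per-layer) parameter count
#' @param perLayer return a named per-layer vector instead of the total
#' @export
setMethod("nParameters", "TrainedModel", function(x, perLayer = FALSE) {
    cnt <- vapply(x@layers, function(ly) {
        if (is.null(ly$params)) 0L
        else sum(rapply(ly$params, length, how = "unlist"))
    }, integer(1))
    names(cnt) <- layerNames(x)
    if (perLayer) cnt else sum(cnt)
})

#' @describeIn TrainedModel names of layers frozen during the last training
#' @export
setMethod("frozenLayers", "TrainedModel",
    function(x) x@config@frozenLayers)

#' @describeIn TrainedModel per-epoch loss record
#' @export
setMethod("trainingHistory", "TrainedModel", function(x) x@history)
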