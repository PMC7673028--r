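#' @include AllClasses.R utils.R
NULL

## On-disk conventions (this package's own, the field has no standard):
##  * delimited dialect: one long-format CSV/TSV with a header and columns
##    trace_id, frame (0-based), channel_1[, channel_2]; a file without a
##    trace_id column is read as a single trace named after the file.
##  * container dialect: a single-file serialized hierarchy (versioned
##    schema), one group per movie, one dataset per trace_id.
##  * label files: CSV with columns trace_id, <scheme>[, mask] where the
##    label column is named after its scheme ("accept_reject" or "mut_wt")
##    and masks are half-open 0-based runs "start:end;start:end" or a
##    per-frame 0/1 string.

sniffSep <- function(path) {
    l1 <- readLines(path, n = 1L)
    if (grepl("\t", l1)) "\t" else ","
}

#' Read a trace table
#'
#' @param path input file.
#' @param dialect `"delimited"` (long-format CSV/TSV, header required) or
#'   `"container"` (single-file hierarchical container written by
#'   [writeTraceTable()]).
#' @param frameInterval seconds per frame recorded on the traces
#'   (delimited dialect only; default 0.1).
#' @return a [TraceSet-class]; traces appear in file order, channel count is
#'   inferred from the column count.
#' @export
readTraceTable <- function(path, dialect = c("delimited", "container"),
                           frameInterval = 0.1) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stopWith("smtn_io", "file not found: %s", path)
    if (dialect == "container") return(readTraceContainer(path))
    sep <- sniffSep(path)
    df <- utils::read.csv(path, sep = sep, colClasses = "character",
                          check.names = FALSE)
    if (nrow(df) == 0L)
        stopWith("smtn_parse", "no data rows in %s", path)
    hasID <- "trace_id" %in% colnames(df)
    numCols <- setdiff(colnames(df), c("trace_id", "frame"))
    if (!"frame" %in% colnames(df) || length(numCols) < 1L ||
        length(numCols) > 2L)
        stopWith("smtn_parse",
                 "%s: need columns [trace_id,] frame, and 1 or 2 intensity columns",
                 path)
    vals <- lapply(df[numCols], function(x) suppressWarnings(as.numeric(x)))
    for (cn in numCols) {
        bad <- which(is.na(vals[[cn]]) & !(df[[cn]] %in% c("NA", "")))
        if (length(bad))
            stopWith("smtn_parse",
                     "%s: non-numeric value '%s' in column '%s' at line %d",
                     path, df[[cn]][bad[1L]], cn, bad[1L] + 1L)
    }
    isNA <- Reduce(`|`, lapply(vals, is.na))
    ids <- if (hasID) df$trace_id
           else rep(tools::file_path_sans_ext(basename(path)), nrow(df))
    traces <- list()
    nchPer <- integer()
    for (id in unique(ids)) {
        rows <- which(ids == id)
        chans <- lapply(vals, `[`, rows)
        present <- !vapply(chans, function(v) all(is.na(v)), logical(1))
        if (any(vapply(chans[present], anyNA, logical(1))))
            stopWith("smtn_format",
                     "%s: trace '%s' mixes channel counts (missing values in an intensity column)",
                     path, id)
        m <- do.call(rbind, chans[present])
        rownames(m) <- names(chans)[present]
        traces[[id]] <- m
        nchPer[id] <- sum(present)
    }
    if (length(unique(nchPer)) > 1L)
        stopWith("smtn_format",
                 "%s: mixed channel counts in one file (%s)",
                 path, paste(unique(nchPer), collapse = ", "))
    TraceSet(traces, frameInterval = frameInterval,
             metadata = list(source = path, dialect = "delimited"))
}

#' Write a trace table
#'
#' @param ts a nonempty [TraceSet-class].
#' @param path output file.
#' @param dialect `"delimited"` writes one long-format CSV (full double
#'   precision, so a write/read round trip reproduces intensities exactly);
#'   `"container"` writes the single-file hierarchical container (one group
#'   per movie, one dataset per trace).
#' @return `path`, invisibly.
#' @export
writeTraceTable <- function(ts, path, dialect = c("delimited", "container")) {
    dialect <- match.arg(dialect)
    if (nTraces(ts) == 0L)
        stopWith("smtn_empty", "refusing to write an empty TraceSet")
    if (dialect == "container") return(writeTraceContainer(ts, path))
    ids <- traceIDs(ts)
    nch <- max(nChannels(ts))
    if (length(unique(nChannels(ts))) > 1L)
        stopWith("smtn_format",
                 "delimited dialect cannot mix channel counts in one file")
    chNames <- if (nch == 2L) c("donor", "acceptor") else "intensity"
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("trace_id", "frame", chNames), collapse = ","), con)
    for (i in seq_along(ids)) {
        m <- intensities(ts, i)
        T <- ncol(m)
        cols <- apply(m, 1L, function(x) sprintf("%.17g", x))
        if (is.null(dim(cols))) cols <- matrix(cols, ncol = nrow(m))
        writeLines(paste(ids[i], seq_len(T) - 1L,
                         apply(cols, 1L, paste, collapse = ","),
                         sep = ","), con)
    }
    invisible(path)
}

## container schema: one group per movie, datasets named by trace_id;
## the flat `order` vector preserves file order across groups.
writeTraceContainer <- function(ts, path) {
    ids <- traceIDs(ts)
    movies <- traceData(ts)$movieID
    movies[is.na(movies)] <- "ungrouped"
    groups <- lapply(split(seq_along(ids), movies), function(idx) {
        lapply(stats::setNames(idx, ids[idx]),
               function(i) intensities(ts, i))
    })
    obj <- list(schema = "smTraceNet-traces-1",
                groups = groups,
                order = ids,
                frameInterval = traceData(ts)$frameInterval,
                nChannels = traceData(ts)$nChannels)
    saveRDS(obj, path)
    invisible(path)
}

readTraceContainer <- function(path) {
    obj <- tryCatch(readRDS(path), error = function(e)
        stopWith("smtn_parse", "not a readable container: %s", path))
    if (!identical(obj$schema, "smTraceNet-traces-1"))
        stopWith("smtn_parse", "unknown container schema in %s", path)
    flat <- do.call(c, unname(obj$groups))
    flat <- flat[obj$order]
    movieOf <- rep(names(obj$groups),
                   vapply(obj$groups, length, integer(1)))
    names(movieOf) <- unlist(lapply(obj$groups, names))
    td <- S4Vectors::DataFrame(
        nChannels = obj$nChannels,
        frameInterval = obj$frameInterval,
        movieID = unname(movieOf[obj$order]),
        row.names = obj$order)
    new("TraceSet", traces = flat, traceData = td,
        metadata = list(source = path, dialect = "container"))
}

## ---- label files ------------------------------------------------------------

labelSchemes <- list(accept_reject = c("ACCEPT", "REJECT"),
                     mut_wt = c("MUT", "WT"))

#' Read a label file
#'
#' A label file is a CSV with a `trace_id` column, a label column named
#' after its scheme (`accept_reject` with tokens ACCEPT/REJECT, or `mut_wt`
#' with tokens MUT/WT), and an optional `mask` column holding per-frame
#' selections as half-open, 0-based runs (`"0:400"` or `"0:100;250:600"`)
#' or as a per-frame 0/1 string.
#'
#' @param path label CSV.
#' @return a `DataFrame` with columns `trace_id`, `label`, `mask`
#'   (character run spec or `NA`); the scheme is in
#'   `metadata(x)$scheme`. Materialize masks with [maskFromSpec()].
#' @export
readLabels <- function(path) {
    if (!file.exists(path))
        stopWith("smtn_io", "file not found: %s", path)
    df <- utils::read.csv(path, colClasses = "character")
    scheme <- intersect(names(labelSchemes), colnames(df))
    if (!"trace_id" %in% colnames(df) || length(scheme) != 1L)
        stopWith("smtn_parse",
                 "%s: need columns trace_id and one of [%s]",
                 path, paste(names(labelSchemes), collapse = ", "))
    allowed <- labelSchemes[[scheme]]
    bad <- setdiff(unique(df[[scheme]]), allowed)
    if (length(bad))
        stopWith("smtn_bad_label",
                 "%s: unknown label '%s'; allowed tokens: {%s}",
                 path, bad[1L], paste(allowed, collapse = ", "))
    out <- S4Vectors::DataFrame(
        trace_id = df$trace_id,
        label = df[[scheme]],
        mask = if ("mask" %in% colnames(df)) {
            m <- df$mask
            m[m == ""] <- NA_character_
            m
        } else rep(NA_character_, nrow(df)))
    S4Vectors::metadata(out) <- list(scheme = scheme, source = path)
    out
}

#' Write a label file
#'
#' @param labels data.frame/DataFrame with `trace_id`, `label` and optional
#'   `mask` columns (mask as run spec string, see [readLabels()]), or the
#'   result of [maskToSpec()] for logical masks.
#' @param path output CSV.
#' @param scheme `"accept_reject"` or `"mut_wt"`.
#' @return `path`, invisibly.
#' @export
writeLabels <- function(labels, path, scheme = c("accept_reject", "mut_wt")) {
    scheme <- match.arg(scheme)
    allowed <- labelSchemes[[scheme]]
    labels <- as.data.frame(labels)
    bad <- setdiff(unique(labels$label), allowed)
    if (length(bad))
        stopWith("smtn_bad_label", "label '%s' not in scheme %s {%s}",
                 bad[1L], scheme, paste(allowed, collapse = ", "))
    out <- data.frame(trace_id = labels$trace_id)
    out[[scheme]] <- labels$label
    if (!is.null(labels$mask)) out$mask <- labels$mask
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Materialize / serialize per-frame masks
#'
#' `maskFromSpec` turns a run spec (`"0:400"`, `"0:100;250:600"`; half-open
#' `[start, end)`, 0-based) or a per-frame 0/1 string into a logical vector
#' of length `nFrames`. `maskToSpec` is the inverse (always emits runs).
#'
#' @param spec character run spec or 0/1 string (or `NA` for an all-false
#'   mask).
#' @param nFrames trace length `T`.
#' @return logical vector of length `nFrames`.
#' @examples
#' maskFromSpec("0:400", 600)  # TRUE on frames [0, 400), FALSE elsewhere
#' @export
maskFromSpec <- function(spec, nFrames) {
    out <- rep(FALSE, nFrames)
    if (is.na(spec) || !nzchar(spec)) return(out)
    if (!grepl(":", spec, fixed = TRUE)) {
        bits <- strsplit(spec, "")[[1L]]
        if (!all(bits %in% c("0", "1")))
            stopWith("smtn_parse", "mask string must be 0/1 or start:end runs")
        if (length(bits) != nFrames)
            stopWith("smtn_parse",
                     "per-frame mask has %d entries for a %d-frame trace",
                     length(bits), nFrames)
        return(bits == "1")
    }
    for (run in strsplit(spec, ";", fixed = TRUE)[[1L]]) {
        se <- suppressWarnings(as.integer(strsplit(run, ":",
                                                   fixed = TRUE)[[1L]]))
        if (length(se) != 2L || anyNA(se) || se[1L] < 0 || se[2L] < se[1L])
            stopWith("smtn_parse", "malformed mask run '%s'", run)
        se[2L] <- min(se[2L], nFrames)
        if (se[1L] < se[2L]) out[(se[1L] + 1L):se[2L]] <- TRUE
    }
    out
}

#' @rdname maskFromSpec
#' @param mask logical vector.
#' @export
maskToSpec <- function(mask) {
    if (!any(mask)) return("")
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    paste(sprintf("%d:%d", starts[r$values], ends[r$values]),
          collapse = ";")
}
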