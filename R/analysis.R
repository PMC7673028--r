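#' @include AllClasses.R utils.R
NULL

#' Threshold classifier scores into Accept/Reject decisions
#'
#' A trace is accepted iff its score is strictly greater than the threshold
#' (default 0.5); a score exactly equal to the threshold is rejected.
#'
#' @param scores named numeric vector in \[0, 1\] (names = trace_ids), e.g.
#'   from [classifyTraces()].
#' @param threshold decision threshold (default 0.5).
#' @param modelID identifier recorded in the table.
#' @return a `DataFrame` (the decision table) with columns `trace_id`,
#'   `score`, `decision` (`"ACCEPT"`/`"REJECT"`), `model_id`.
#' @examples
#' applyThreshold(c(a = 0.7, b = 0.5, c = 0.2))
#' @export
applyThreshold <- function(scores, threshold = 0.5, modelID = "model") {
    stopifnot(all(scores >= 0 & scores <= 1))
    ids <- names(scores) %||% as.character(seq_along(scores))
    S4Vectors::DataFrame(
        trace_id = ids,
        score = unname(scores),
        decision = unname(ifelse(scores > threshold, "ACCEPT", "REJECT")),
        model_id = rep(modelID, length(scores)))
}

#' Concordance between automated and manual classification
#'
#' Trace-level concordance is the number of traces on which the two label
#' sets agree divided by the total number of traces. Sensitivity and
#' specificity are computed relative to the `manual` labels (not a ground
#' truth). Frame-level concordance compares per-frame masks over all frames
#' of all traces (a trace absent from one mask list counts as all-rejected).
#'
#' @param pred decision table from [applyThreshold()], or a named character
#'   vector of labels; for `level = "frame"`, a named list of logical masks.
#' @param manual named character labels (or [readLabels()] output), or a
#'   named list of logical masks for frame level.
#' @param level `"trace"` or `"frame"`.
#' @param positive the label counted as positive (default `"ACCEPT"`, or
#'   `"MUT"` if present in the manual labels).
#' @return a list of class `"ConcordanceReport"`: `n_agree`, `n_total`,
#'   `concordance`, `sensitivity`, `specificity`, `level`.
#' @export
concordance <- function(pred, manual, level = c("trace", "frame"),
                        positive = NULL) {
    level <- match.arg(level)
    if (level == "frame") {
        ids <- union(names(pred), names(manual))
        agree <- 0; total <- 0; tp <- 0; fn <- 0; fp <- 0; tn <- 0
        for (id in ids) {
            T <- length(pred[[id]] %||% manual[[id]])
            p <- pred[[id]] %||% rep(FALSE, T)
            m <- manual[[id]] %||% rep(FALSE, T)
            if (length(p) != length(m))
                stopWith("smtn_id_mismatch",
                         "mask length differs for trace '%s'", id)
            agree <- agree + sum(p == m); total <- total + T
            tp <- tp + sum(p & m); fn <- fn + sum(!p & m)
            fp <- fp + sum(p & !m); tn <- tn + sum(!p & !m)
        }
        rep_ <- list(n_agree = agree, n_total = total,
                     concordance = agree / total,
                     sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA,
                     specificity = if (tn + fp > 0) tn / (tn + fp) else NA,
                     level = "frame")
        class(rep_) <- "ConcordanceReport"
        return(rep_)
    }
    predLab <- if (is(pred, "DataFrame") || is.data.frame(pred))
        stats::setNames(as.character(pred$decision %||% pred$label),
                        pred$trace_id)
    else pred
    manLab <- if (is(manual, "DataFrame") || is.data.frame(manual))
        stats::setNames(as.character(manual$label), manual$trace_id)
    else manual
    miss <- setdiff(names(manLab), names(predLab))
    if (length(miss))
        stopWith("smtn_id_mismatch", "trace_ids missing from predictions: %s",
                 paste(utils::head(miss, 5L), collapse = ", "))
    predLab <- predLab[names(manLab)]
    if (is.null(positive))
        positive <- if ("MUT" %in% manLab) "MUT" else "ACCEPT"
    agree <- sum(predLab == manLab)
    total <- length(manLab)
    mp <- manLab == positive
    pp <- predLab == positive
    rep_ <- list(n_agree = agree, n_total = total,
                 concordance = agree / total,
                 sensitivity = if (any(mp)) sum(pp & mp) / sum(mp) else NA,
                 specificity = if (any(!mp)) sum(!pp & !mp) / sum(!mp)
                               else NA,
                 level = "trace")
    class(rep_) <- "ConcordanceReport"
    rep_
}

#' @export
print.ConcordanceReport <- function(x, ...) {
    cat(sprintf("ConcordanceReport (%s level): %d/%d agree (%.1f%%)\n",
                x$level, x$n_agree, x$n_total, 100 * x$concordance))
    cat(sprintf("  sensitivity %.3f, specificity %.3f (vs manual labels)\n",
                x$sensitivity, x$specificity))
    invisible(x)
}

#' ROC curve and AUC of scores against manual labels
#'
#' Sweeps the decision threshold over the unique scores and reports
#' (sensitivity, 1 - specificity) pairs and the trapezoid-rule area under
#' the curve. Sensitivity/specificity are relative to the supplied labels.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels character/factor labels aligned with `scores`.
#' @param positive the positive label (default `"ACCEPT"` or `"MUT"` if
#'   present).
#' @return list with `points` (data.frame `threshold`, `sensitivity`,
#'   `fpr`), and `auc`.
#' @export
rocCurve <- function(scores, labels, positive = NULL) {
    labels <- as.character(labels)
    if (is.null(positive))
        positive <- if ("MUT" %in% labels) "MUT" else "ACCEPT"
    pos <- labels == positive
    if (!any(pos) || all(pos))
        stopWith("smtn_single_class",
                 "ROC needs both classes present (positive = %s)", positive)
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
    auc <- sum(diff(fpr) * (utils::head(sens, -1L) + utils::tail(sens, -1L)) / 2)
    list(points = data.frame(threshold = thr, sensitivity = sens,
                             fpr = fpr),
         auc = auc)
}

#' Per-frame FRET efficiency series
#'
#' Computes the uncorrected proximity ratio `E = acceptor / (donor +
#' acceptor)` on the masked frames of a two-channel trace, clipped to
#' \[0, 1\]. Frames whose total intensity is <= 0 are dropped (counted, not
#' fatal).
#'
#' @param trace numeric matrix `2 x T` (donor, acceptor).
#' @param mask logical vector length `T`; defaults to all frames.
#' @param traceID id recorded alongside the values.
#' @return list of class `"FretSeries"`: `E` (values in \[0, 1\]),
#'   `n_dropped`, `trace_id`.
#' @export
fretSeries <- function(trace, mask = NULL, traceID = "trace") {
    if (!is.matrix(trace) || nrow(trace) != 2L)
        stopWith("smtn_channel_mismatch", "FRET series requires two channels")
    T <- ncol(trace)
    if (is.null(mask)) mask <- rep(TRUE, T)
    if (length(mask) != T)
        stopWith("smtn_id_mismatch", "mask length %d != trace length %d",
                 length(mask), T)
    d <- trace[1L, mask]
    a <- trace[2L, mask]
    tot <- d + a
    ok <- tot > 0
    E <- pmin(pmax(a[ok] / tot[ok], 0), 1)
    structure(list(E = E, n_dropped = sum(!ok), trace_id = traceID),
              class = "FretSeries")
}

#' Fit a two-component Gaussian mixture to a FRET histogram
#'
#' Bins the efficiency values on \[0, 1\] and fits the sum of two Gaussian
#' components to the histogram counts by nonlinear least squares
#' (Levenberg-Marquardt, means constrained to \[0, 1\], multiple jittered
#' restarts). Populations are the normalized component areas. Components are
#' reported in increasing order of mean.
#'
#' @param series a `"FretSeries"` (or numeric vector of efficiencies).
#' @param nBins histogram bins on \[0, 1\] (default 50).
#' @param nRestarts jittered restarts around the peak-based initialization.
#' @return list of class `"GaussianFit"`: `mean`, `sd`, `population`
#'   (each length 2, ordered by mean; populations sum to 1), `degenerate`
#'   (TRUE when one component absorbs >= 95% of the population or collapses
#'   to a point), `converged`, `fitted` (data.frame bin_center, count,
#'   fit).
#' @export
fitTwoGaussians <- function(series, nBins = 50L, nRestarts = 5L) {
    E <- if (inherits(series, "FretSeries")) series$E else as.numeric(series)
    if (length(E) < 12L)
        stopWith("smtn_too_few", "need at least 12 efficiency values (got %d)",
                 length(E))
    brk <- seq(0, 1, length.out = nBins + 1L)
    h <- hist(pmin(pmax(E, 0), 1), breaks = brk, plot = FALSE)
    x <- h$mids; y <- h$counts
    bw <- diff(brk)[1L]
    n <- length(E)
    ## initialization: the two tallest local peaks at least 0.15 apart
    ord <- order(y, decreasing = TRUE)
    mu1 <- x[ord[1L]]
    mu2 <- NA_real_
    for (k in ord[-1L]) if (abs(x[k] - mu1) >= 0.15) { mu2 <- x[k]; break }
    if (is.na(mu2)) mu2 <- min(1, mu1 + 0.2)
    model <- function(p, xx) {
        a1 <- plogis(p[1L]); m1 <- plogis(p[2L]); s1 <- exp(p[3L])
        m2 <- plogis(p[4L]); s2 <- exp(p[5L])
        n * bw * (a1 * stats::dnorm(xx, m1, s1) +
                  (1 - a1) * stats::dnorm(xx, m2, s2))
    }
    start0 <- c(0, stats::qlogis(pmin(pmax(mu1, 0.02), 0.98)), log(0.05),
                stats::qlogis(pmin(pmax(mu2, 0.02), 0.98)), log(0.05))
    best <- NULL
    for (r in seq_len(nRestarts)) {
        st <- start0 + if (r == 1L) 0 else stats::rnorm(5L, 0, 0.3)
        fit <- tryCatch(
            minpack.lm::nls.lm(par = st,
                               fn = function(p) y - model(p, x),
                               control = minpack.lm::nls.lm.control(
                                   maxiter = 200L)),
            error = function(e) NULL)
        if (!is.null(fit)) {
            rss <- sum(fit$fvec^2)
            if (is.null(best) || rss < best$rss)
                best <- list(fit = fit, rss = rss)
        }
    }
    if (is.null(best))
        stopWith("smtn_no_convergence",
                 "two-Gaussian fit failed to converge after %d restarts from means (%.2f, %.2f)",
                 nRestarts, mu1, mu2)
    p <- best$fit$par
    a1 <- plogis(p[1L])
    mus <- plogis(p[c(2L, 4L)])
    sds <- exp(p[c(3L, 5L)])
    pops <- c(a1, 1 - a1)
    o <- order(mus)
    mus <- mus[o]; sds <- sds[o]; pops <- pops[o]
    degenerate <- max(pops) >= 0.95 || any(sds < 1e-4)
    structure(list(mean = mus, sd = sds, population = pops,
                   degenerate = degenerate,
                   converged = best$fit$info %in% 1:4,
                   fitted = data.frame(bin_center = x, count = y,
                                       fit = model(p, x))),
              class = "GaussianFit")
}

#' @export
print.GaussianFit <- function(x, ...) {
    cat(sprintf(
        "GaussianFit: mu = (%.3f, %.3f), sd = (%.3f, %.3f), pop = (%.1f%%, %.1f%%)%s\n",
        x$mean[1L], x$mean[2L], x$sd[1L], x$sd[2L],
        100 * x$population[1L], 100 * x$population[2L],
        if (x$degenerate) "  [degenerate]" else ""))
    invisible(x)
}

#' Kinetic summary of a one-channel trace
#'
#' Idealizes the trace to a two-state (low/high) path by two-means
#' thresholding with a hysteresis band: the low and high levels are fitted
#' by 1-D k-means, and the state switches only when the signal crosses the
#' midpoint by more than `0.25 * delta` (delta = level separation), which
#' suppresses noise-induced chatter. Reports the number of binding plus
#' dissociation events and mean dwell times.
#'
#' @param trace numeric matrix `1 x T` or numeric vector.
#' @param frameInterval seconds per frame (for the dwell times in seconds).
#' @return list of class `"KineticSummary"`: `n_bind_dissociate`,
#'   `tau_bound` / `tau_unbound` (mean dwell in frames; `NA` when the state
#'   never completes a dwell), `tau_bound_s`, `idealized` (integer state
#'   path, 1 = low, 2 = high), `levels`.
#' @export
kineticSummary <- function(trace, frameInterval = 0.1) {
    x <- if (is.matrix(trace)) {
        if (nrow(trace) != 1L)
            stopWith("smtn_channel_mismatch",
                     "kinetic summary requires a one-channel trace")
        trace[1L, ]
    } else as.numeric(trace)
    T <- length(x)
    km <- tryCatch(stats::kmeans(x, centers = 2L, nstart = 5L),
                   error = function(e) NULL)
    ## a single-state trace: level separation not resolvable above the
    ## within-level spread (a unimodal Gaussian splits at ~1.6 sd with
    ## ~0.6 sd within, so the factor 3 rejects it)
    withinSD <- if (is.null(km)) Inf else sqrt(km$tot.withinss / T)
    if (is.null(km) ||
        abs(diff(range(km$centers))) < 3 * max(withinSD, 1e-12)) {
        out <- list(n_bind_dissociate = 0L, tau_bound = NA_real_,
                    tau_unbound = NA_real_, tau_bound_s = NA_real_,
                    idealized = rep(1L, T),
                    levels = c(low = min(x), high = max(x)))
        class(out) <- "KineticSummary"
        return(out)
    }
    lv <- sort(as.vector(km$centers))
    mid <- mean(lv)
    delta <- diff(lv)
    up <- mid + 0.25 * delta
    dn <- mid - 0.25 * delta
    state <- integer(T)
    state[1L] <- if (x[1L] > mid) 2L else 1L
    for (t in 2:T) {
        state[t] <- state[t - 1L]
        if (state[t - 1L] == 1L && x[t] > up) state[t] <- 2L
        else if (state[t - 1L] == 2L && x[t] < dn) state[t] <- 1L
    }
    r <- rle(state)
    nTrans <- length(r$lengths) - 1L
    ## dwell means exclude the censored first/last dwell; with no
    ## transitions at all, dwells are undefined
    dwellOf <- function(s) {
        if (length(r$lengths) < 2L) return(NA_real_)
        keep <- rep(TRUE, length(r$lengths))
        keep[c(1L, length(keep))] <- FALSE
        d <- r$lengths[r$values == s & keep]
        if (length(d)) mean(d) else NA_real_
    }
    tb <- dwellOf(2L)
    out <- list(n_bind_dissociate = nTrans,
                tau_bound = tb, tau_unbound = dwellOf(1L),
                tau_bound_s = tb * frameInterval,
                idealized = state, levels = c(low = lv[1L], high = lv[2L]))
    class(out) <- "KineticSummary"
    out
}

#' @export
print.KineticSummary <- function(x, ...) {
    cat(sprintf(
        "KineticSummary: N_b+d = %d, tau_bound = %s frames, levels %.0f/%.0f\n",
        x$n_bind_dissociate,
        if (is.na(x$tau_bound)) "NA" else sprintf("%.1f", x$tau_bound),
        x$levels[1L], x$levels[2L]))
    invisible(x)
}
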