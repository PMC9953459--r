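# Pre-stimulus instantaneous phase estimation.
#
# PHASTIMATE-style forecast: demean -> zero-phase forward-backward FIR
# band-pass -> trim filter edges -> Yule-Walker AR fit -> forward prediction
# through the target time -> analytic-signal phase at the target sample.
# Phase convention throughout: degrees in [0, 360), 0 = positive peak of the
# band-limited oscillation (cosine convention), increasing in time.

.firBand <- function(band, fs, order) {
    signal::fir1(as.integer(order), c(band@lo, band@hi) / (fs / 2),
                 type = "pass")
}

# forward-backward FIR filtering with odd-reflection padding at both ends
# (keeps startup transients out of the retained samples; plain zero padding
# leaves a phase-biasing ramp inside the edge-trim margin)
.zeroPhase <- function(x, b) {
    b <- as.numeric(b)
    n <- length(x)
    p <- min(3 * length(b), n - 1)
    xx <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    y <- signal::filter(b, 1, xx)
    y <- rev(signal::filter(b, 1, rev(y)))
    y[(p + 1):(p + n)]
}

.wrapDeg <- function(x) x %% 360

# AR forward prediction by Yule-Walker: x extended by n_ahead samples.
# The shrunk (1/n) autocovariance normalization of stats::ar.yw keeps the
# fitted poles inside the unit circle, which matters more for a multi-cycle
# forecast than the small frequency bias it introduces.
.arPredict <- function(x, order, n_ahead) {
    fit <- tryCatch(ar(x, aic = FALSE, order.max = order,
                       method = "yule-walker", demean = FALSE),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit$ar) == 0L) return(rep(NaN, n_ahead))
    a <- fit$ar
    p <- length(a)
    buf <- c(tail(x, p), numeric(n_ahead))
    for (k in seq_len(n_ahead))
        buf[p + k] <- sum(a * buf[(p + k - 1):(k)])
    buf[(p + 1):(p + n_ahead)]
}

#' Forecast instantaneous phase from pre-stimulus data
#'
#' Estimates the band-limited oscillatory phase at `target_time_ms` using
#' only a data window ending at `t_end_ms` (default -4 ms, the last sample
#' unaffected by artifact excision and its interpolation edge). The window is
#' demeaned, band-pass filtered forward and backward (zero phase), trimmed by
#' `edgeMs` at both ends, extended by Yule--Walker autoregressive forward
#' prediction through the target, and the analytic-signal angle of the final
#' `hilbertWindow` samples is read at the sample nearest the target.
#' Filter boundaries are handled by extending the raw window with an
#' autoregressive forecast (and odd reflection elsewhere) so that the
#' filter's end transient never touches the samples anchoring the
#' prediction.
#'
#' @param x numeric vector (one trial) or samples x trials matrix; the last
#'   sample is taken to lie at `t_end_ms`. Must cover at least
#'   `params@windowMs`.
#' @param params a [PhastimateParams-class].
#' @param band a [BandSpec-class].
#' @param fs sampling rate, Hz.
#' @param t_end_ms time of the last input sample, ms.
#' @param target_time_ms time the returned phase refers to; must be
#'   `>= t_end_ms`.
#' @return numeric vector of phases in degrees in \[0, 360), one per trial;
#'   `NA` (with a warning) for trials whose AR forecast is non-finite, which
#'   flags them for exclusion.
#' @export
phastimatePhase <- function(x, params, band, fs, t_end_ms = -4,
                            target_time_ms = 0) {
    x <- as.matrix(x)
    nw <- round(params@windowMs * fs / 1000)
    if (nrow(x) < nw)
        stop(sprintf("window of %d samples required, got %d", nw, nrow(x)))
    if (target_time_ms < t_end_ms)
        stop("target_time_ms must not precede t_end_ms")
    x <- x[(nrow(x) - nw + 1):nrow(x), , drop = FALSE]
    e <- round(params@edgeMs * fs / 1000)
    hw <- as.integer(params@hilbertWindow)
    # predict half a Hilbert window beyond the target so the target sample
    # sits at the centre of the analytic-signal window, where the FFT
    # transform is free of edge distortion
    half <- hw %/% 2L
    n_ahead <- e + round((target_time_ms - t_end_ms) * fs / 1000) + half
    b <- .firBand(band, fs, params@filterOrder)
    out <- numeric(ncol(x))
    bad <- FALSE
    npad <- as.integer(params@filterOrder) + 1L
    for (j in seq_len(ncol(x))) {
        xd <- x[, j] - mean(x[, j])
        # extend the window by an AR forecast of the raw data before
        # filtering, so the filter's end transient falls on the synthetic
        # extension rather than on the samples anchoring the forecast
        # (Table-1 edge trims are shorter than the filter transient)
        xf <- .zeroPhase(c(xd, .arPredict(xd, params@arOrder, npad)),
                         b)[seq_len(nw)]
        xf <- xf[(e + 1):(nw - e)]
        ext <- if (n_ahead > 0)
            c(xf, .arPredict(xf, params@arOrder, n_ahead)) else xf
        if (!all(is.finite(ext))) {
            out[j] <- NA_real_
            bad <- TRUE
            next
        }
        seg <- tail(ext, hw)
        out[j] <- .wrapDeg(Arg(.analyticVector(seg)[length(seg) - half]) *
                               180 / pi)
    }
    if (bad)
        warning("non-finite AR forecast on some trial(s); returned NA ",
                "(flagged for exclusion)")
    out
}

#' Reference (oracle) instantaneous phase from the full signal
#'
#' Band-passes the complete, uncut signal with the same zero-phase FIR as the
#' forecasting estimator and reads the analytic-signal angle at `t_ms`. Used
#' as the ground-truth reference when tuning or validating the forecaster.
#'
#' @param x numeric vector or samples x trials matrix (full trials).
#' @param band a [BandSpec-class].
#' @param fs sampling rate, Hz.
#' @param times time axis in ms for the rows of `x`.
#' @param t_ms time at which the phase is read; must be at least one filter
#'   length away from both signal edges.
#' @param filter_order FIR order (default 3 cycles of the band's low edge).
#' @return phases in degrees in \[0, 360), one per trial.
#' @export
hilbertOraclePhase <- function(x, band, fs, times, t_ms,
                               filter_order = NULL) {
    x <- as.matrix(x)
    if (is.null(filter_order))
        filter_order <- round(3 * fs / band@lo)
    i <- .timeIndex(times, t_ms)
    guard <- filter_order
    if (i <= guard || i > nrow(x) - guard)
        stop("t_ms too close to the signal edge for a reliable oracle phase")
    b <- .firBand(band, fs, filter_order)
    xf <- apply(x, 2, function(v) .zeroPhase(v - mean(v), b))
    .wrapDeg(Arg(.analyticMatrix(xf)[i, ]) * 180 / pi)
}

#' Circular standard deviation of angular errors
#'
#' Wraps pairwise differences between two angle lists to (-180, 180\]
#' degrees, computes the mean resultant length \eqn{\bar R} of the
#' differences, and returns \eqn{\sqrt{-2 \ln \bar R}} in radians. A
#' vanishing resultant (uniformly dispersed errors) yields `Inf` with a
#' warning.
#'
#' @param estimates,references equal-length angle vectors in degrees.
#' @return circular standard deviation in radians.
#' @export
circularErrorSD <- function(estimates, references) {
    stopifnot(length(estimates) == length(references),
              length(estimates) >= 1L)
    keep <- is.finite(estimates) & is.finite(references)
    d <- (estimates[keep] - references[keep]) * pi / 180
    R <- Mod(mean(exp(1i * d)))
    if (R < 1e-12) {
        warning("zero mean resultant length: dispersion is undefined ",
                "(infinite)")
        return(Inf)
    }
    sqrt(-2 * log(R))
}

#' Tune estimator parameters against the oracle on training data
#'
#' Exhaustive grid search: each candidate parameter row is evaluated by
#' forecasting the phase at `t_train_ms` from data ending `margin_ms` before
#' it and comparing to [hilbertOraclePhase()] at `t_train_ms` by
#' [circularErrorSD()]. The row with the smallest circular error wins; ties
#' are broken by smaller AR order, then smaller filter order. Deterministic.
#'
#' @param x samples x trials matrix of full training trials.
#' @param times time axis in ms for the rows of `x`.
#' @param band a [BandSpec-class].
#' @param grid data.frame with columns `filter_order`, `window_ms`,
#'   `edge_ms`, `ar_order`, `hilbert_window`.
#' @param fs sampling rate, Hz.
#' @param t_train_ms training target time (default -1000 ms, far from any
#'   stimulus effect).
#' @param margin_ms gap between the last usable sample and the target
#'   (default 4 ms, matching the artifact-excision margin).
#' @return the winning row as a [PhastimateParams-class], with the achieved
#'   circular error (radians) in attribute `"error"` and the evaluated grid
#'   in attribute `"grid"`.
#' @export
optimizePhastimate <- function(x, times, band, grid, fs,
                               t_train_ms = -1000, margin_ms = 4) {
    if (nrow(grid) == 0L) stop("empty parameter grid")
    x <- as.matrix(x)
    ref <- hilbertOraclePhase(x, band, fs, times, t_train_ms)
    i_end <- max(which(times <= t_train_ms - margin_ms + 1e-9))
    errs <- vapply(seq_len(nrow(grid)), function(r) {
        g <- grid[r, ]
        p <- phastimateParams(g$filter_order, g$window_ms, g$edge_ms,
                              g$ar_order, g$hilbert_window)
        nw <- round(p@windowMs * fs / 1000)
        if (i_end < nw) return(Inf)
        win <- x[(i_end - nw + 1):i_end, , drop = FALSE]
        est <- suppressWarnings(
            phastimatePhase(win, p, band, fs, t_end_ms = times[i_end],
                            target_time_ms = t_train_ms))
        circularErrorSD(est, ref)
    }, numeric(1))
    ord <- order(errs, grid$ar_order, grid$filter_order)
    best <- grid[ord[1L], ]
    out <- phastimateParams(best$filter_order, best$window_ms, best$edge_ms,
                            best$ar_order, best$hilbert_window)
    attr(out, "error") <- errs[ord[1L]]
    attr(out, "grid") <- cbind(grid, error_rad = errs)
    out
}
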