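# Pre-stimulus band power by Welch's method, plus the two trial-partitioning
# rules built on it (median split, mean-power threshold).

#' Band-integrated Welch power of pre-stimulus windows
#'
#' Segmented averaged periodogram: the window is cut into Hann-tapered
#' segments of `seg_frac` times the window length with `overlap` fractional
#' overlap, each segment is demeaned, and the one-sided spectral density is
#' averaged across segments and integrated over \[`band@lo`, `band@hi`\].
#' Density normalization is such that a unit-amplitude in-band sinusoid
#' yields approximately `1/2` (amplitude squared over two), i.e. the result
#' is the band's contribution to signal variance in uV^2.
#'
#' @param x numeric vector or samples x trials matrix; its length should be
#'   the band's `powerWindowMs` (within one sample) when used per protocol.
#' @param band a [BandSpec-class].
#' @param fs sampling rate, Hz.
#' @param seg_frac segment length as a fraction of the window (default 1/2).
#' @param overlap fractional segment overlap (default 1/2).
#' @return numeric vector of band powers in uV^2, one per trial.
#' @export
welchBandPower <- function(x, band, fs, seg_frac = 0.5, overlap = 0.5) {
    x <- as.matrix(x)
    n <- nrow(x)
    nseg <- max(2L, round(n * seg_frac))
    if (n < nseg) stop("window shorter than one Welch segment")
    step <- max(1L, round(nseg * (1 - overlap)))
    starts <- seq(1L, n - nseg + 1L, by = step)
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1))
    acc <- matrix(0, nseg, ncol(x))
    for (s in starts) {
        seg <- x[s:(s + nseg - 1L), , drop = FALSE]
        seg <- sweep(seg, 2, colMeans(seg)) * w
        acc <- acc + Mod(mvfft(seg))^2
    }
    psd <- acc * (2 / (length(starts) * fs * sum(w^2)))   # one-sided density
    f <- (0:(nseg - 1)) * fs / nseg
    sel <- f >= band@lo & f <= band@hi & f <= fs / 2
    df <- fs / nseg
    colSums(psd[sel, , drop = FALSE]) * df
}

#' Extract the protocol pre-anchor power window and compute band power
#'
#' Convenience wrapper: takes the `band@powerWindowMs` samples immediately
#' before `anchor_ms` (samples with `anchor - W <= t < anchor`) from an
#' [EpochSet-class] and returns their Welch band power per trial.
#'
#' @param es an [EpochSet-class].
#' @param band a [BandSpec-class].
#' @param anchor_ms window end, ms: 0 for the stimulated condition, the
#'   control phase-anchor time for the control condition.
#' @param ... passed to [welchBandPower()].
#' @return numeric vector of band powers in uV^2, one per trial.
#' @export
prestimPower <- function(es, band, anchor_ms = 0, ...) {
    t <- epochTimes(es)
    sel <- t >= anchor_ms - band@powerWindowMs - 1e-9 & t < anchor_ms - 1e-9
    if (!any(sel))
        stop("power window lies outside the epoch")
    n_expect <- round(band@powerWindowMs * samplingRate(es) / 1000)
    if (abs(sum(sel) - n_expect) > 1L)
        stop(sprintf("power window truncated by the epoch: %d of %d samples",
                     sum(sel), n_expect))
    welchBandPower(epochSignal(es)[sel, , drop = FALSE], band,
                   samplingRate(es), ...)
}

#' Median split of trials by band power
#'
#' Trials strictly below the median are labelled `"low"`, strictly above
#' `"high"`; trials exactly at the median are assigned alternately starting
#' with `"low"` (in trial order), so that for continuous power the two
#' groups each comprise half the data and group sizes differ by at most one.
#'
#' @param powers numeric vector of per-trial band powers (one dataset, one
#'   band); length >= 2.
#' @return character vector of labels `"low"`/`"high"`, one per trial.
#' @export
medianSplit <- function(powers) {
    stopifnot(length(powers) >= 2L)
    med <- median(powers)
    lab <- ifelse(powers < med, "low", ifelse(powers > med, "high", NA))
    ties <- which(is.na(lab))
    if (length(ties))
        lab[ties] <- rep(c("low", "high"), length.out = length(ties))
    lab
}

#' Mean-power threshold trial retention
#'
#' Retains the trials whose band power is strictly greater than the
#' dataset-band mean power (the threshold rule used before re-testing the
#' phase contrasts on high-power trials only). With right-skewed power
#' distributions this retains well under half the trials.
#'
#' @param powers numeric vector of per-trial band powers.
#' @return integer indices of retained trials.
#' @export
meanPowerThreshold <- function(powers) {
    stopifnot(length(powers) >= 1L)
    which(powers > mean(powers))
}
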