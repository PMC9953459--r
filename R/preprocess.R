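# Deterministic single-channel epoch conditioning.

#' Excise a time span and bridge it by linear interpolation
#'
#' Replaces every sample strictly inside `span` by the straight line joining
#' the last sample at or before the span start and the first sample at or
#' after the span end (the boundary samples themselves are retained). This is
#' the standard treatment of the stimulus-artifact segment. Idempotent.
#'
#' @param es an [EpochSet-class].
#' @param span ms pair, default the -2..20 ms artifact span.
#' @return the modified [EpochSet-class].
#' @export
exciseInterpolate <- function(es, span = c(-2, 20)) {
    t <- epochTimes(es)
    inside <- which(.windowMask(t, span, open = TRUE))
    if (length(inside) == 0L) return(es)
    before <- which(t <= span[1] + 1e-9)
    after <- which(t >= span[2] - 1e-9)
    if (length(before) == 0L || length(after) == 0L)
        stop("span touches the epoch edge: no anchor sample")
    ia <- max(before)
    ib <- min(after)
    if (ia >= min(inside) || ib <= max(inside))
        stop("span touches the epoch edge: no anchor sample")
    sig <- epochSignal(es)
    w <- (t[inside] - t[ia]) / (t[ib] - t[ia])
    sig[inside, ] <- outer(1 - w, sig[ia, ]) + outer(w, sig[ib, ])
    SummarizedExperiment::assay(es, "signal") <- sig
    es
}

#' Baseline-correct each trial
#'
#' Subtracts, per trial, the mean of the samples inside `span` (inclusive)
#' from the whole trial.
#'
#' @param es an [EpochSet-class].
#' @param span ms pair, default -500..-200 ms.
#' @return the corrected [EpochSet-class].
#' @export
baselineCorrect <- function(es, span = c(-500, -200)) {
    t <- epochTimes(es)
    sel <- .windowMask(t, span)
    if (!any(sel)) stop("baseline span contains no samples")
    sig <- epochSignal(es)
    sig <- sweep(sig, 2, colMeans(sig[sel, , drop = FALSE]))
    SummarizedExperiment::assay(es, "signal") <- sig
    es
}

#' Down-sample an EpochSet by an integer factor
#'
#' Anti-alias filters (zero-phase FIR low-pass at 80% of the target Nyquist)
#' and decimates. The original rate must be an integer multiple of
#' `target_fs`; equal rates return the input unchanged.
#'
#' @param es an [EpochSet-class].
#' @param target_fs target sampling rate, Hz (default 1000).
#' @return the down-sampled [EpochSet-class] (signal assay only; truth
#'   annotations are kept, clean traces dropped).
#' @export
downsampleEpochs <- function(es, target_fs = 1000) {
    fs <- samplingRate(es)
    if (abs(fs - target_fs) < 1e-9) return(es)
    q <- fs / target_fs
    if (abs(q - round(q)) > 1e-9)
        stop("fs must be an integer multiple of target_fs")
    q <- as.integer(round(q))
    t <- epochTimes(es)
    sig <- epochSignal(es)
    b <- as.numeric(signal::fir1(64, 0.8 / q))
    b <- b / sum(b)                  # unit DC gain
    filt <- apply(sig, 2, function(x)
        signal::filtfilt(as.numeric(b), 1, x))
    keep <- seq(1L, nrow(sig), by = q)
    nkeep <- floor(nrow(sig) * target_fs / fs)
    keep <- keep[seq_len(min(nkeep, length(keep)))]
    truth <- if (isTRUE(S4Vectors::metadata(es)$has_truth))
        trialTruth(es) else NULL
    EpochSet(filt[keep, , drop = FALSE], t[keep], fs = target_fs,
             truth = truth)
}

#' Standard epoch conditioning
#'
#' Artifact excision with linear interpolation, then baseline correction,
#' then optional down-sampling, in that fixed order.
#'
#' @param es an [EpochSet-class].
#' @param artifact_span,baseline_span ms pairs.
#' @param target_fs target rate in Hz, `NULL` to skip down-sampling.
#' @return the conditioned [EpochSet-class].
#' @export
preprocessEpochs <- function(es, artifact_span = c(-2, 20),
                             baseline_span = c(-500, -200),
                             target_fs = NULL) {
    es <- exciseInterpolate(es, artifact_span)
    es <- baselineCorrect(es, baseline_span)
    if (!is.null(target_fs)) es <- downsampleEpochs(es, target_fs)
    es
}
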