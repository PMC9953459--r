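# Single-trial response quantification and phase-bin assignment.

#' Rectified area under the curve of a trial window
#'
#' Trapezoidal integral of the absolute signal over a time window, in
#' uV*ms. The stimulated-condition window is 25--80 ms after the pulse; the
#' control window is the matched 55 ms span returned by
#' [controlWindowFor()].
#'
#' @param x numeric vector or samples x trials matrix.
#' @param window_ms ms pair (inclusive), default `c(25, 80)`.
#' @param times time axis in ms for the rows of `x`.
#' @return numeric vector of AUC values in uV*ms, one per trial.
#' @export
computeAUC <- function(x, window_ms = c(25, 80), times) {
    x <- as.matrix(x)
    if (window_ms[1] < times[1] - 1e-9 ||
        window_ms[2] > times[length(times)] + 1e-9)
        stop("AUC window outside the epoch")
    sel <- which(.windowMask(times, window_ms))
    if (length(sel) < 2L) stop("AUC window contains fewer than two samples")
    a <- abs(x[sel, , drop = FALSE])
    dt <- mean(diff(times[sel]))
    (colSums(a) - (a[1, ] + a[nrow(a), ]) / 2) * dt
}

#' Assign a pre-stimulus phase to its 60-degree category
#'
#' Categories (boundaries inclusive): positive peak 0 +/- 30 deg
#' (\[330, 360) and \[0, 30\]), 90 +/- 30 deg (\[60, 120\]), negative peak
#' 180 +/- 30 deg (\[150, 210\]), 270 +/- 30 deg (\[240, 300\]); phases in
#' the gaps map to `"none"`. The "random" category of the analysis is the
#' full trial set, not a bin label.
#'
#' @param phase_deg numeric vector of phases in degrees, each in \[0, 360).
#' @return character vector of labels: `"positive_peak"`, `"deg90"`,
#'   `"negative_peak"`, `"deg270"`, or `"none"` (`NA` in, `NA` out).
#' @export
assignPhaseBin <- function(phase_deg) {
    ok <- is.na(phase_deg) | (phase_deg >= 0 & phase_deg < 360)
    if (!all(ok)) stop("phases must lie in [0, 360)")
    out <- rep("none", length(phase_deg))
    out[phase_deg >= 330 | phase_deg <= 30] <- "positive_peak"
    out[phase_deg >= 60 & phase_deg <= 120] <- "deg90"
    out[phase_deg >= 150 & phase_deg <= 210] <- "negative_peak"
    out[phase_deg >= 240 & phase_deg <= 300] <- "deg270"
    out[is.na(phase_deg)] <- NA_character_
    out
}

#' Control-condition AUC window for a phase anchor
#'
#' For a control phase anchor at `phase_target_ms` the response window
#' starts 29 ms later and spans the same 55 ms as the 25--80 ms
#' stimulated-condition window: the default anchor of -1000 ms gives
#' (-971, -916) ms.
#'
#' @param phase_target_ms control phase-anchor time, ms (default -1000).
#' @param offset_ms start of the window relative to the anchor (default 29).
#' @param length_ms window length (default 55).
#' @return ms pair `c(start, end)`.
#' @export
controlWindowFor <- function(phase_target_ms = -1000, offset_ms = 29,
                             length_ms = 55) {
    c(phase_target_ms + offset_ms, phase_target_ms + offset_ms + length_ms)
}
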