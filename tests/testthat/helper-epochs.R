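# Shared fixture builders (all generated in code).

# EpochSet holding arbitrary per-trial signals on a ms time axis
makeEpochs <- function(..., times = seq(-1000, 1000), fs = 1000) {
    trials <- list(...)
    EpochSet(do.call(cbind, trials), times, fs = fs)
}

# EpochSet whose clean oscillator assay for `band` is a pure cosine with
# phase `phase0_deg` at t = 0 (signal assay = the same trace)
makeOscEpochs <- function(freq, phase0_deg = 0, band = "alpha",
                          times = seq(-1000, 1000), fs = 1000) {
    u <- cos(2 * pi * freq * times / 1000 + phase0_deg * pi / 180)
    EpochSet(matrix(u), times, fs = fs,
             truth = data.frame(amp = 1),
             clean = stats::setNames(list(matrix(u)), band))
}

# sinusoidal analysis window of `n_ms` samples ending at t_end (1 kHz),
# with oscillation phase `phase_at_target` (deg) at target_ms
sineWindow <- function(freq, n_ms, t_end = -4, target_ms = 0,
                       phase_at_target = 0, snr = Inf) {
    tt <- seq(t_end - n_ms + 1, t_end)
    x <- cos(2 * pi * freq * (tt - target_ms) / 1000 +
                 phase_at_target * pi / 180)
    if (is.finite(snr)) x <- snr * x + rnorm(length(tt))
    x
}

pipelineConfig <- function(...) {
    genConfig(epoch_span = c(-2100, 200), store_clean = FALSE, ...)
}
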