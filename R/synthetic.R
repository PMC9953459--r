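# Synthetic epoched EEG with known oscillatory ground truth.
#
# Each trial is: sum over bands of A_i * u_i(t) (u_i a unit-RMS narrowband
# Gaussian trace, A_i a per-epoch log-normal amplitude) + 1/f background
# + evoked kernel at t >= 0 + stimulus artifact. Keeping A_i constant within
# an epoch realizes the temporal-correlation premise: pre-stimulus band power
# predicts post-stimulus amplitude.

# analytic signal (FFT construction) of each column of a real matrix
.analyticMatrix <- function(x) {
    x <- as.matrix(x)
    n <- nrow(x)
    h <- numeric(n)
    if (n %% 2L == 0L) {
        h[c(1L, n / 2L + 1L)] <- 1
        h[2:(n / 2L)] <- 2
    } else {
        h[1L] <- 1
        h[2:((n + 1L) / 2L)] <- 2
    }
    mvfft(mvfft(x) * h, inverse = TRUE) / n
}

.analyticVector <- function(x) as.vector(.analyticMatrix(matrix(x)))

# smooth frequency-domain band mask with raised-cosine transitions
.bandMask <- function(n, fs, lo, hi, trans = NULL) {
    if (is.null(trans)) trans <- max(0.5, 0.15 * (hi - lo))
    k <- 0:(n - 1)
    f <- pmin(k, n - k) * fs / n            # two-sided (Hermitian) frequencies
    m <- numeric(n)
    up <- f >= lo - trans & f < lo
    dn <- f > hi & f <= hi + trans
    m[f >= lo & f <= hi] <- 1
    m[up] <- 0.5 * (1 + cos(pi * (lo - f[up]) / trans))
    m[dn] <- 0.5 * (1 + cos(pi * (f[dn] - hi) / trans))
    m
}

# unit-RMS narrowband Gaussian traces, one column per trial; the FFT is done
# at a highly composite padded length and the result truncated
.bandNoise <- function(n, n_trials, fs, lo, hi) {
    np <- stats::nextn(n, c(2, 3))
    w <- matrix(rnorm(np * n_trials), np, n_trials)
    m <- .bandMask(np, fs, lo, hi)
    x <- Re(mvfft(mvfft(w) * m, inverse = TRUE))[seq_len(n), , drop = FALSE] / np
    rms <- sqrt(colMeans(x^2))
    sweep(x, 2, rms, "/")
}

# 1/f^alpha background, each column scaled to the requested RMS
.pinkNoise <- function(n, n_trials, fs, exponent, scale) {
    if (scale == 0) return(matrix(0, n, n_trials))
    np <- stats::nextn(n, c(2, 3))
    w <- matrix(rnorm(np * n_trials), np, n_trials)
    k <- 0:(np - 1)
    f <- pmax(pmin(k, np - k) * fs / np, 1)   # flatten below 1 Hz
    g <- f^(-exponent / 2)
    g[1] <- 0                                 # remove DC
    x <- Re(mvfft(mvfft(w) * g, inverse = TRUE))[seq_len(n), , drop = FALSE] / np
    rms <- sqrt(colMeans(x^2))
    sweep(x, 2, scale / rms, "*")
}

#' Default evoked-response kernel
#'
#' Sum of two Gaussian-windowed damped sinusoids (periods about 40 ms and
#' 15 ms), zero for t < 0, peaking inside the 25--80 ms response window and
#' decayed to nothing by about 150 ms. The returned waveform has unit peak
#' absolute amplitude.
#'
#' @param times_ms time axis in ms.
#' @return numeric waveform, same length as `times_ms`.
#' @export
evokedKernel <- function(times_ms) {
    t <- times_ms
    k <- exp(-(t - 45)^2 / (2 * 18^2)) * cos(2 * pi * (t - 45) / 40) +
        0.4 * exp(-(t - 40)^2 / (2 * 12^2)) * cos(2 * pi * (t - 40) / 15)
    k[t < 0] <- 0
    k / max(abs(k))
}

# rank standardization to (-1, 1): 2*(rank - 0.5)/n - 1
.rankZ <- function(x) {
    n <- length(x)
    2 * (rank(x, ties.method = "average") - 0.5) / n - 1
}

#' Generate one synthetic dataset of epoched EEG trials
#'
#' Draws `cfg@nTrials` epochs of single-channel EEG per the generative model
#' described in [GenConfig-class]. The evoked response amplitude on trial i
#' is `evokedPeakUv * (1 + gamma * z_i + kappa * cos(phi_i))`, with `z_i` the
#' rank-standardized interaction-band amplitude and `phi_i` the
#' interaction-band oscillator phase at t = 0. Samples strictly inside
#' `artifactSpan` are overwritten with a decaying-exponential stimulus
#' artifact. Reproducible: the same `cfg` and `dataset_index` always give a
#' bit-identical result; different `dataset_index` values give independent
#' streams.
#'
#' @param cfg a [GenConfig-class].
#' @param dataset_index 1-based dataset number within the cohort.
#' @return an [EpochSet-class] with ground truth in `colData`
#'   (`amp_<band>` uV, `phase0_<band>` degrees at t = 0, `evoked_gain` uV)
#'   and, if `cfg@storeClean`, clean unit-amplitude oscillator traces as
#'   assays.
#' @export
generateDataset <- function(cfg, dataset_index = 1L) {
    validObject(cfg)
    set.seed((as.integer(cfg@seed) + 97003L * as.integer(dataset_index)) %%
                 .Machine$integer.max)
    fs <- cfg@fs
    times <- seq(cfg@epochSpan[1], cfg@epochSpan[2], by = 1000 / fs)
    n <- length(times)
    nt <- as.integer(cfg@nTrials)
    bands <- defaultBands()[names(cfg@bandAmplitudes)]

    sig <- .pinkNoise(n, nt, fs, cfg@noiseExponent, cfg@noiseScale)
    clean <- list()
    truth <- data.frame(row.names = seq_len(nt))
    i0 <- .timeIndex(times, 0)
    s <- cfg@ampSdlog
    # oscillator phases at t = 0 are part of the truth record, but their
    # analytic-signal transform is costly; compute them only when kept
    # (storeClean) or needed for the phase interaction (kappa != 0)
    want_phase <- cfg@storeClean || cfg@kappa != 0
    for (bn in names(bands)) {
        b <- bands[[bn]]
        u <- .bandNoise(n, nt, fs, b@lo, b@hi)
        amps <- cfg@bandAmplitudes[[bn]] *
            rlnorm(nt, meanlog = -s^2 / 2, sdlog = s)
        sig <- sig + sweep(u, 2, amps, "*")
        truth[[paste0("amp_", bn)]] <- amps
        truth[[paste0("phase0_", bn)]] <- if (want_phase)
            (Arg(.analyticMatrix(u)[i0, ]) * 180 / pi) %% 360
        else NA_real_
        if (cfg@storeClean) clean[[bn]] <- u
    }

    # evoked response with optional power/phase interaction
    gains <- numeric(nt)
    if (cfg@evokedPeakUv > 0) {
        z <- .rankZ(truth[[paste0("amp_", cfg@interactionBand)]])
        fac <- 1 + cfg@gamma * z
        if (cfg@kappa != 0) {
            phi <- truth[[paste0("phase0_", cfg@interactionBand)]] * pi / 180
            fac <- fac + cfg@kappa * cos(phi)
        }
        if (any(fac < 0))
            stop("gamma/kappa make the evoked amplitude negative on ",
                 sum(fac < 0), " trial(s); ill-posed configuration")
        gains <- cfg@evokedPeakUv * fac
        sig <- sig + outer(evokedKernel(times), gains)
    }
    truth$evoked_gain <- gains

    # stimulus artifact: overwrite samples strictly inside artifactSpan
    art <- .windowMask(times, cfg@artifactSpan, open = TRUE)
    sig[art, ] <- cfg@artifactPeakUv *
        exp(-(times[art] - cfg@artifactSpan[1]) / 5)

    if (!cfg@storeClean) clean <- NULL
    EpochSet(sig, times, fs = fs, truth = truth, clean = clean)
}

#' Ground-truth oscillator phase of a synthetic EpochSet
#'
#' Reads the stored clean oscillator trace of `band` and returns the
#' analytic-signal phase at `t_ms` per trial, in degrees wrapped to
#' \[0, 360) under the cosine convention (0 deg = positive peak, phase
#' increasing in time).
#'
#' @param es synthetic [EpochSet-class] generated with `store_clean = TRUE`.
#' @param band a [BandSpec-class] or band name.
#' @param t_ms time in ms at which the phase is read.
#' @return numeric vector of angles in degrees, one per trial.
#' @export
truthPhase <- function(es, band, t_ms = 0) {
    bn <- if (is(band, "BandSpec")) band@name else band
    an <- paste0("clean_", bn)
    if (!(an %in% SummarizedExperiment::assayNames(es)))
        stop("EpochSet carries no clean oscillator trace for band '", bn,
             "' (generate with store_clean = TRUE)")
    u <- SummarizedExperiment::assay(es, an)
    i <- .timeIndex(epochTimes(es), t_ms)
    unname((Arg(.analyticMatrix(u)[i, ]) * 180 / pi) %% 360)
}

#' Generate a cohort of synthetic datasets
#'
#' @param cfg a [GenConfig-class]; `cfg@nDatasets` datasets are produced.
#' @return list of [EpochSet-class] objects.
#' @export
generateCohort <- function(cfg) {
    lapply(seq_len(as.integer(cfg@nDatasets)),
           function(i) generateDataset(cfg, i))
}
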