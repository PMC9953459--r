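#' @import methods
#' @importFrom stats ar approx median pt rlnorm rnorm sd t.test var mvfft fft
#' @importFrom utils read.csv write.csv write.table head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' Frequency band specification
#'
#' A named frequency band together with the band-specific length of the
#' pre-stimulus window used for Welch power estimation. The three canonical
#' bands are theta (4--7 Hz, 1000 ms power window), alpha (8--13 Hz, 500 ms)
#' and beta (14--30 Hz, 250 ms); see [defaultBands()].
#'
#' @slot name band label, e.g. `"alpha"`.
#' @slot lo,hi band edges in Hz, `0 < lo < hi`.
#' @slot powerWindowMs length in ms of the pre-stimulus window over which
#'   band power is computed.
#' @export
setClass("BandSpec", representation(
    name = "character", lo = "numeric", hi = "numeric",
    powerWindowMs = "numeric"
))

setValidity("BandSpec", function(object) {
    if (length(object@lo) != 1L || length(object@hi) != 1L)
        return("lo and hi must be scalars")
    if (!(object@lo > 0 && object@hi > object@lo))
        return("band edges must satisfy 0 < lo < hi")
    if (object@powerWindowMs <= 0)
        return("powerWindowMs must be positive")
    TRUE
})

#' @param name,lo,hi,power_window_ms see slots.
#' @rdname BandSpec-class
#' @export
bandSpec <- function(name, lo, hi, power_window_ms) {
    new("BandSpec", name = name, lo = as.numeric(lo), hi = as.numeric(hi),
        powerWindowMs = as.numeric(power_window_ms))
}

#' Canonical EEG band definitions
#'
#' Theta 4--7 Hz (1000 ms power window), alpha 8--13 Hz (500 ms),
#' beta 14--30 Hz (250 ms).
#'
#' @return named list of [BandSpec-class] objects.
#' @export
defaultBands <- function() {
    list(theta = bandSpec("theta", 4, 7, 1000),
         alpha = bandSpec("alpha", 8, 13, 500),
         beta  = bandSpec("beta", 14, 30, 250))
}

#' Parameters of the autoregressive phase estimator
#'
#' Tunable parameters of the PHASTIMATE-style estimator: the order (taps) of
#' the zero-phase forward--backward FIR band-pass, the analysis window length,
#' the filtered-edge trim, the Yule--Walker autoregressive model order, and
#' the number of samples entering the analytic-signal (Hilbert) transform.
#' Band-specific defaults are provided by [defaultPhastimateParams()].
#'
#' @slot filterOrder FIR order of the band-pass applied forward and backward.
#' @slot windowMs analysis window length, ms.
#' @slot edgeMs trim removed from each end of the filtered window, ms.
#' @slot arOrder Yule--Walker autoregressive order.
#' @slot hilbertWindow number of samples entering the analytic-signal
#'   transform.
#' @export
setClass("PhastimateParams", representation(
    filterOrder = "numeric", windowMs = "numeric", edgeMs = "numeric",
    arOrder = "numeric", hilbertWindow = "numeric"
))

setValidity("PhastimateParams", function(object) {
    v <- c(object@filterOrder, object@windowMs, object@edgeMs,
           object@arOrder, object@hilbertWindow)
    if (any(!is.finite(v)) || any(v <= 0))
        return("all parameters must be positive and finite")
    if (object@windowMs <= 2 * object@edgeMs)
        return("windowMs must exceed 2 * edgeMs")
    TRUE
})

#' @param filter_order,window_ms,edge_ms,ar_order,hilbert_window see slots.
#' @rdname PhastimateParams-class
#' @export
phastimateParams <- function(filter_order, window_ms, edge_ms, ar_order,
                             hilbert_window) {
    new("PhastimateParams", filterOrder = as.numeric(filter_order),
        windowMs = as.numeric(window_ms), edgeMs = as.numeric(edge_ms),
        arOrder = as.numeric(ar_order),
        hilbertWindow = as.numeric(hilbert_window))
}

#' Band-specific default estimator parameters
#'
#' Defaults used throughout: theta 320/1000/140/30/256,
#' alpha 192/718/65/25/128, beta 100/500/30/15/64
#' (filter order / window ms / edge ms / AR order / Hilbert window).
#'
#' @param band band name, one of `"theta"`, `"alpha"`, `"beta"`.
#' @return a [PhastimateParams-class] object.
#' @export
defaultPhastimateParams <- function(band = c("theta", "alpha", "beta")) {
    band <- match.arg(band)
    switch(band,
        theta = phastimateParams(320, 1000, 140, 30, 256),
        alpha = phastimateParams(192, 718, 65, 25, 128),
        beta  = phastimateParams(100, 500, 30, 15, 64))
}

#' Synthetic-EEG generator configuration
#'
#' Configuration for [generateDataset()]. The generator produces epoched
#' single-channel EEG: a sum of band-limited stochastic oscillators whose
#' amplitude is drawn once per epoch from a log-normal distribution (so
#' pre-stimulus power predicts post-stimulus amplitude -- the continuation
#' property of real EEG), a 1/f background, a large decaying stimulus
#' artifact, and an optional evoked response whose amplitude may depend on
#' pre-stimulus power (`gamma`) and/or phase (`kappa`) of the interaction
#' band.
#'
#' @slot nDatasets number of datasets in a cohort.
#' @slot nTrials trials per dataset.
#' @slot fs sampling rate, Hz.
#' @slot epochSpan epoch limits in ms relative to the stimulus.
#' @slot bandAmplitudes named per-band oscillator RMS amplitude, uV.
#' @slot ampSdlog log-normal sigma of the per-epoch amplitude draw.
#' @slot noiseExponent 1/f background spectral slope.
#' @slot noiseScale broadband background RMS, uV.
#' @slot evokedPeakUv peak amplitude of the evoked kernel, uV (0 = none).
#' @slot artifactSpan ms span overwritten by the stimulus artifact (open
#'   interval).
#' @slot artifactPeakUv artifact peak amplitude, uV.
#' @slot gamma dimensionless gain of the power interaction: evoked amplitude
#'   is scaled by `1 + gamma * z + kappa * cos(phi)` where `z` is the trial's
#'   rank-standardized pre-stimulus interaction-band power in (-1, 1) and
#'   `phi` the interaction-band oscillator phase at t = 0.
#' @slot kappa dimensionless gain of the phase interaction.
#' @slot interactionBand band driving the evoked-response interaction.
#' @slot storeClean whether to keep the clean per-band oscillator traces as
#'   extra assays (needed by [truthPhase()]).
#' @slot seed integer RNG seed; dataset `i` uses an independent substream.
#' @export
setClass("GenConfig", representation(
    nDatasets = "numeric", nTrials = "numeric", fs = "numeric",
    epochSpan = "numeric", bandAmplitudes = "numeric", ampSdlog = "numeric",
    noiseExponent = "numeric", noiseScale = "numeric",
    evokedPeakUv = "numeric", artifactSpan = "numeric",
    artifactPeakUv = "numeric", gamma = "numeric", kappa = "numeric",
    interactionBand = "character", storeClean = "logical", seed = "numeric"
))

setValidity("GenConfig", function(object) {
    if (object@nTrials < 1) return("nTrials must be >= 1")
    if (object@nDatasets < 1) return("nDatasets must be >= 1")
    if (object@fs <= 0) return("fs must be positive")
    if (length(object@epochSpan) != 2L ||
        diff(object@epochSpan) <= 0) return("epochSpan must be increasing")
    if (any(object@bandAmplitudes < 0) || object@noiseScale < 0 ||
        object@evokedPeakUv < 0 || object@artifactPeakUv < 0)
        return("amplitude/scale fields must be >= 0")
    if (is.null(names(object@bandAmplitudes)))
        return("bandAmplitudes must be named by band")
    if (!(object@interactionBand %in% names(object@bandAmplitudes)))
        return("interactionBand must name an entry of bandAmplitudes")
    if (length(object@artifactSpan) != 2L ||
        diff(object@artifactSpan) <= 0)
        return("artifactSpan must be increasing")
    if (object@artifactSpan[1] < object@epochSpan[1] ||
        object@artifactSpan[2] > object@epochSpan[2])
        return("epochSpan must strictly contain artifactSpan")
    if (object@epochSpan[1] > 25 || object@epochSpan[2] < 80)
        return("epochSpan must contain the 25-80 ms response window")
    TRUE
})

#' @param n_datasets,n_trials,fs,epoch_span,band_amplitudes,amp_sdlog see
#'   slots.
#' @param noise_exponent,noise_scale,evoked_peak_uv,artifact_span see slots.
#' @param artifact_peak_uv,gamma,kappa,interaction_band,store_clean,seed see
#'   slots.
#' @rdname GenConfig-class
#' @export
genConfig <- function(n_datasets = 16, n_trials = 100, fs = 1000,
                      epoch_span = c(-1000, 1000),
                      band_amplitudes = c(theta = 6, alpha = 7, beta = 7),
                      amp_sdlog = 0.9, noise_exponent = 1, noise_scale = 5,
                      evoked_peak_uv = 10, artifact_span = c(-2, 20),
                      artifact_peak_uv = 500, gamma = 0, kappa = 0,
                      interaction_band = "theta", store_clean = TRUE,
                      seed = 1L) {
    new("GenConfig", nDatasets = n_datasets, nTrials = n_trials, fs = fs,
        epochSpan = as.numeric(epoch_span),
        bandAmplitudes = band_amplitudes, ampSdlog = amp_sdlog,
        noiseExponent = noise_exponent, noiseScale = noise_scale,
        evokedPeakUv = evoked_peak_uv,
        artifactSpan = as.numeric(artifact_span),
        artifactPeakUv = artifact_peak_uv, gamma = gamma, kappa = kappa,
        interactionBand = interaction_band, storeClean = store_clean,
        seed = seed)
}

#' Epoched single-channel EEG trials
#'
#' An `EpochSet` holds one dataset's trials as a time x trial matrix (assay
#' `"signal"`, uV) inside a [SummarizedExperiment::SummarizedExperiment].
#' Rows are samples; `rowData(es)$time_ms` is the uniform time axis in ms
#' relative to the stimulus and `metadata(es)$fs` the sampling rate in Hz.
#' Synthetic sets carry per-trial ground truth in `colData` (per-band
#' oscillator amplitude and phase at t = 0, evoked gain) and, when
#' `store_clean = TRUE`, the clean oscillator traces as assays
#' `"clean_<band>"`.
#'
#' @export
setClass("EpochSet", contains = "SummarizedExperiment")

setValidity("EpochSet", function(object) {
    t <- epochTimes(object)
    if (length(t) < 2L) return("EpochSet needs at least two samples")
    if (is.null(t)) return("rowData must contain a time_ms column")
    dt <- diff(t)
    if (any(dt <= 0)) return("times must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * mean(dt))
        return("times must be uniformly spaced")
    fs <- S4Vectors::metadata(object)$fs
    if (is.null(fs)) return("metadata must contain fs")
    if (abs(mean(dt) - 1000 / fs) > 1e-6 * (1000 / fs))
        return("time spacing must equal 1000/fs ms")
    if (!("signal" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'signal' is required")
    TRUE
})

#' @param data time x trial numeric matrix, uV.
#' @param times time axis in ms (length `nrow(data)`), uniform spacing.
#' @param fs sampling rate in Hz; must equal `1000/diff(times)`.
#' @param truth optional per-trial data.frame of ground-truth annotations.
#' @param clean optional named list of clean oscillator matrices (same
#'   dimension as `data`), one per band.
#' @rdname EpochSet-class
#' @export
EpochSet <- function(data, times, fs = 1000 / diff(times[1:2]),
                     truth = NULL, clean = NULL) {
    data <- as.matrix(data)
    assays <- list(signal = data)
    if (!is.null(clean)) {
        names(clean) <- paste0("clean_", names(clean))
        assays <- c(assays, clean)
    }
    cd <- if (is.null(truth)) {
        S4Vectors::DataFrame(row.names = sprintf("trial%03d",
                                                 seq_len(ncol(data))))
    } else {
        S4Vectors::DataFrame(truth,
                             row.names = sprintf("trial%03d",
                                                 seq_len(ncol(data))))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays,
        rowData = S4Vectors::DataFrame(time_ms = as.numeric(times)),
        colData = cd,
        metadata = list(fs = fs, has_truth = !is.null(truth)))
    new("EpochSet", se)
}
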