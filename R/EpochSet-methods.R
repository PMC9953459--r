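#' @describeIn EpochSet-class the time x trial signal matrix (uV).
#' @param es,object an `EpochSet`.
#' @export
epochSignal <- function(es) SummarizedExperiment::assay(es, "signal")

#' @describeIn EpochSet-class time axis in ms relative to the stimulus.
#' @export
epochTimes <- function(es)
    SummarizedExperiment::rowData(es)$time_ms

#' @describeIn EpochSet-class sampling rate in Hz.
#' @export
samplingRate <- function(es) S4Vectors::metadata(es)$fs

#' @describeIn EpochSet-class per-trial ground-truth annotations
#'   (`data.frame`), or error if the set is not synthetic.
#' @export
trialTruth <- function(es) {
    if (!isTRUE(S4Vectors::metadata(es)$has_truth))
        stop("this EpochSet carries no ground-truth annotations")
    as.data.frame(SummarizedExperiment::colData(es))
}

#' @describeIn EpochSet-class number of trials.
#' @export
nTrials <- function(es) ncol(es)

setMethod("show", "EpochSet", function(object) {
    t <- epochTimes(object)
    cat("EpochSet:", ncol(object), "trials x", nrow(object), "samples\n")
    cat(sprintf("  time %g..%g ms at %g Hz\n", t[1], t[length(t)],
                samplingRate(object)))
    cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                           collapse = ", "), "\n")
    if (isTRUE(S4Vectors::metadata(object)$has_truth))
        cat("  ground truth: ",
            paste(colnames(SummarizedExperiment::colData(object)),
                  collapse = ", "), "\n", sep = "")
})

# index of the sample nearest to t_ms (error when outside the axis)
.timeIndex <- function(times, t_ms) {
    if (t_ms < times[1] - 1e-9 || t_ms > times[length(times)] + 1e-9)
        stop(sprintf("time %g ms outside epoch (%g..%g ms)", t_ms,
                     times[1], times[length(times)]))
    which.min(abs(times - t_ms))
}

# logical sample mask for a closed ms window
.windowMask <- function(times, span, open = FALSE) {
    if (open) times > span[1] & times < span[2]
    else times >= span[1] - 1e-9 & times <= span[2] + 1e-9
}

#' Write an EpochSet to plain-text files
#'
#' The signal matrix is written as a tab-delimited table (`<stem>_signal.tsv`,
#' one column per trial), metadata (fs, time span, trial count) as a JSON
#' sidecar (`<stem>_meta.json`), and ground truth, when present, as
#' `<stem>_truth.csv`.
#'
#' @param es an [EpochSet-class].
#' @param stem path prefix for the three files.
#' @return invisibly, the paths written.
#' @export
writeEpochSet <- function(es, stem) {
    sig <- epochSignal(es)
    t <- epochTimes(es)
    paths <- paste0(stem, c("_signal.tsv", "_meta.json", "_truth.csv"))
    write.table(format(sig, digits = 10, trim = TRUE), paths[1],
                sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    meta <- list(fs = samplingRate(es), t_start_ms = t[1],
                 t_end_ms = t[length(t)], n_samples = nrow(sig),
                 n_trials = ncol(sig),
                 has_truth = isTRUE(S4Vectors::metadata(es)$has_truth))
    jsonlite::write_json(meta, paths[2], auto_unbox = TRUE, digits = NA)
    if (meta$has_truth)
        write.csv(trialTruth(es), paths[3], row.names = FALSE)
    invisible(paths)
}

#' Read an EpochSet written by [writeEpochSet()]
#'
#' @param stem path prefix used when writing.
#' @return an [EpochSet-class] (clean oscillator assays are not round-tripped).
#' @export
readEpochSet <- function(stem) {
    meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                                simplifyVector = TRUE)
    sig <- as.matrix(read.table(paste0(stem, "_signal.tsv"), sep = "\t"))
    dimnames(sig) <- NULL
    times <- seq(meta$t_start_ms, meta$t_end_ms, length.out = meta$n_samples)
    truth <- NULL
    if (isTRUE(meta$has_truth))
        truth <- read.csv(paste0(stem, "_truth.csv"))
    EpochSet(sig, times, fs = meta$fs, truth = truth)
}
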