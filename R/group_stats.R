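# Per-dataset aggregation and across-dataset statistics: normalized AUC by
# phase category, low/high power contrasts, the corrected_effect measure,
# paired and one-sample t tests with Bonferroni-adjusted levels.

.BINS <- c("positive_peak", "deg90", "negative_peak", "deg270")

#' Per-trial feature table for one dataset
#'
#' Computes, per trial and band: pre-stimulus and pre-control Welch band
#' power, their median-split labels and mean-threshold retention flags,
#' rectified AUC over the stimulated (25--80 ms) and control windows, and --
#' optionally -- the forecast pre-stimulus phase and its 60-degree bin for
#' both conditions.
#'
#' @param es a preprocessed [EpochSet-class].
#' @param dataset_id identifier copied into the table.
#' @param bands list of [BandSpec-class] (default [defaultBands()]).
#' @param compute_phase whether to run the phase forecaster (the power
#'   analysis does not need it).
#' @param params named list of [PhastimateParams-class] per band (defaults
#'   to [defaultPhastimateParams()]).
#' @param ctrl_anchor_ms control-condition phase anchor, ms.
#' @param phase_margin_ms gap between the last usable sample and the phase
#'   target (default 4 ms).
#' @return data.frame, one row per trial x band.
#' @export
trialFeatures <- function(es, dataset_id = 1L, bands = defaultBands(),
                          compute_phase = TRUE, params = NULL,
                          ctrl_anchor_ms = -1000, phase_margin_ms = 4) {
    t <- epochTimes(es)
    fs <- samplingRate(es)
    sig <- epochSignal(es)
    nt <- ncol(sig)
    ctrl_win <- controlWindowFor(ctrl_anchor_ms)
    auc_tms <- computeAUC(sig, c(25, 80), t)
    auc_ctrl <- computeAUC(sig, ctrl_win, t)
    out <- vector("list", length(bands))
    for (k in seq_along(bands)) {
        b <- bands[[k]]
        p_tms <- prestimPower(es, b, 0)
        p_ctrl <- prestimPower(es, b, ctrl_anchor_ms)
        row <- data.frame(
            dataset = dataset_id, trial = seq_len(nt), band = b@name,
            power_tms = p_tms, power_ctrl = p_ctrl,
            power_label_tms = medianSplit(p_tms),
            power_label_ctrl = medianSplit(p_ctrl),
            retained_tms = seq_len(nt) %in% meanPowerThreshold(p_tms),
            retained_ctrl = seq_len(nt) %in% meanPowerThreshold(p_ctrl),
            auc_tms = auc_tms, auc_ctrl = auc_ctrl)
        if (compute_phase) {
            pp <- if (is.null(params)) defaultPhastimateParams(b@name)
                  else params[[b@name]]
            i_tms <- max(which(t <= -phase_margin_ms + 1e-9))
            i_ctl <- max(which(t <= ctrl_anchor_ms - phase_margin_ms + 1e-9))
            nw <- round(pp@windowMs * fs / 1000)
            row$phase_tms <- phastimatePhase(
                sig[(i_tms - nw + 1):i_tms, , drop = FALSE], pp, b, fs,
                t_end_ms = t[i_tms], target_time_ms = 0)
            row$phase_ctrl <- phastimatePhase(
                sig[(i_ctl - nw + 1):i_ctl, , drop = FALSE], pp, b, fs,
                t_end_ms = t[i_ctl], target_time_ms = ctrl_anchor_ms)
            row$bin_tms <- assignPhaseBin(row$phase_tms)
            row$bin_ctrl <- assignPhaseBin(row$phase_ctrl)
        }
        out[[k]] <- row
    }
    do.call(rbind, out)
}

#' Per-dataset condition means
#'
#' Aggregates a per-trial feature table ([trialFeatures()], possibly
#' concatenated over datasets) into one row per dataset x band: mean AUC per
#' phase bin, mean over all trials ("random"), low/high power means for both
#' conditions, and trial counts. Cells with no trials are `NA`.
#'
#' @param features data.frame from [trialFeatures()].
#' @return data.frame, one row per dataset x band.
#' @export
summarizeDatasets <- function(features) {
    has_phase <- "bin_tms" %in% names(features)
    keys <- unique(features[c("dataset", "band")])
    rows <- lapply(seq_len(nrow(keys)), function(r) {
        f <- features[features$dataset == keys$dataset[r] &
                      features$band == keys$band[r], ]
        cellMean <- function(v, sel)
            if (any(sel, na.rm = TRUE)) mean(v[which(sel)]) else NA_real_
        row <- data.frame(
            dataset = keys$dataset[r], band = keys$band[r],
            n_trials = nrow(f),
            auc_random_tms = mean(f$auc_tms),
            auc_random_ctrl = mean(f$auc_ctrl),
            auc_low_tms = cellMean(f$auc_tms, f$power_label_tms == "low"),
            auc_high_tms = cellMean(f$auc_tms, f$power_label_tms == "high"),
            auc_low_ctrl = cellMean(f$auc_ctrl,
                                    f$power_label_ctrl == "low"),
            auc_high_ctrl = cellMean(f$auc_ctrl,
                                     f$power_label_ctrl == "high"))
        if (has_phase) {
            for (bin in .BINS) {
                row[[paste0("auc_", bin, "_tms")]] <-
                    cellMean(f$auc_tms, f$bin_tms == bin)
                row[[paste0("auc_", bin, "_ctrl")]] <-
                    cellMean(f$auc_ctrl, f$bin_ctrl == bin)
                row[[paste0("n_", bin, "_tms")]] <-
                    sum(f$bin_tms == bin, na.rm = TRUE)
                row[[paste0("n_", bin, "_tms_thr")]] <-
                    sum(f$bin_tms == bin & f$retained_tms, na.rm = TRUE)
            }
            row$n_random_thr <- sum(f$retained_tms)
        }
        row
    })
    do.call(rbind, rows)
}

#' Normalized AUC per phase category
#'
#' For each labelled bin with at least one trial, the bin's mean AUC minus
#' the mean AUC over all of the dataset's trials (the "random" category).
#' Empty bins give `NA` and are excluded from the group test for that bin.
#'
#' @param summary data.frame from [summarizeDatasets()].
#' @param band band name.
#' @param condition `"tms"` or `"ctrl"`.
#' @return data.frame: dataset plus one column per bin of normalized AUC
#'   (uV*ms).
#' @export
normalizedAUC <- function(summary, band, condition = c("tms", "ctrl")) {
    condition <- match.arg(condition)
    s <- summary[summary$band == band, ]
    out <- data.frame(dataset = s$dataset)
    rnd <- s[[paste0("auc_random_", condition)]]
    for (bin in .BINS)
        out[[bin]] <- s[[paste0("auc_", bin, "_", condition)]] - rnd
    out
}

#' The corrected_effect measure
#'
#' Per dataset:
#' `(auc_high_tms - auc_low_tms) - (auc_high_ctrl - auc_low_ctrl)`,
#' in uV*ms -- the high-minus-low power difference of the stimulated
#' response with the matching difference of the no-stimulus control
#' subtracted, isolating the stimulus-dependent part of the power effect
#' from mere continuation of ongoing dynamics. Datasets with any empty cell
#' give `NA`.
#'
#' @param summary data.frame from [summarizeDatasets()].
#' @param band band name.
#' @return data.frame with columns `dataset`, `band`, `value` (uV*ms).
#' @export
correctedEffect <- function(summary, band) {
    s <- summary[summary$band == band, ]
    data.frame(dataset = s$dataset, band = band,
               value = (s$auc_high_tms - s$auc_low_tms) -
                       (s$auc_high_ctrl - s$auc_low_ctrl))
}

.tResult <- function(contrast, d, mu0 = 0) {
    d <- d[is.finite(d)]
    n <- length(d)
    if (n < 2L) stop("need at least two paired values")
    if (sd(d) < 1e-12) {
        t <- if (mean(d) == mu0) 0 else sign(mean(d) - mu0) * Inf
        return(data.frame(contrast = contrast, n = n, mean = mean(d),
                          sd = sd(d), t = t, df = n - 1,
                          p = if (is.infinite(t)) 0 else 1,
                          degenerate = TRUE))
    }
    tt <- t.test(d, mu = mu0)
    data.frame(contrast = contrast, n = n, mean = mean(d), sd = sd(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, degenerate = FALSE)
}

#' Two-sided paired t test
#'
#' Classical paired t statistic on the per-dataset differences, df = n - 1.
#' Pairs with a missing member are dropped (pairwise deletion). Differences
#' with zero variance are flagged `degenerate` with `t = +/-Inf`, `p = 0`
#' (or `t = 0`, `p = 1` for identical vectors).
#'
#' @param a,b equal-length paired value vectors.
#' @param contrast label for the result row.
#' @return one-row data.frame: contrast, n, mean and sd of the differences,
#'   t, df, p, degenerate flag.
#' @export
pairedT <- function(a, b, contrast = "paired") {
    stopifnot(length(a) == length(b))
    .tResult(contrast, a - b)
}

#' Two-sided one-sample t test
#'
#' `t = (mean - mu0) / (sd / sqrt(n))`, df = n - 1; `NA` values dropped;
#' zero variance flagged as degenerate.
#'
#' @param values numeric vector.
#' @param mu0 null value (default 0).
#' @param contrast label for the result row.
#' @return one-row data.frame as in [pairedT()].
#' @export
oneSampleT <- function(values, mu0 = 0, contrast = "one-sample") {
    .tResult(contrast, values, mu0 = mu0)
}

#' Bonferroni-adjusted significance level
#'
#' `family_alpha / m`, rounded to the conventional three decimals:
#' 0.05/12 = 0.004, 0.05/3 = 0.017, 0.05/6 = 0.008.
#'
#' @param family_alpha family-wise level.
#' @param m number of comparisons.
#' @param digits rounding (default 3; `NA` for the exact value).
#' @return adjusted per-comparison threshold.
#' @export
adjustAlpha <- function(family_alpha, m, digits = 3) {
    stopifnot(m >= 1)
    a <- family_alpha / m
    if (is.na(digits)) a else round(a, digits)
}
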