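test_that("generation is deterministic in seed and independent across datasets", {
    cfg <- genConfig(n_trials = 8, seed = 11)
    a <- generateDataset(cfg, 1)
    b <- generateDataset(cfg, 1)
    expect_identical(epochSignal(a), epochSignal(b))
    expect_identical(trialTruth(a), trialTruth(b))
    c <- generateDataset(cfg, 2)
    expect_false(isTRUE(all.equal(epochSignal(a), epochSignal(c))))
})

test_that("epoch structure satisfies its invariants", {
    cfg <- genConfig(n_trials = 5, seed = 3)
    es <- generateDataset(cfg, 1)
    t <- epochTimes(es)
    expect_equal(diff(range(diff(t))), 0)
    expect_equal(t[1], -1000)
    expect_equal(t[length(t)], 1000)
    expect_true(all(is.finite(epochSignal(es))))
    expect_true(validObject(es))
})

test_that("evoked kernel is injected additively with the configured gains", {
    base <- list(n_trials = 64, seed = 21, gamma = 0.4, kappa = 0.2)
    with_k <- generateDataset(do.call(genConfig,
                                      c(base, evoked_peak_uv = 10)), 1)
    without <- generateDataset(do.call(genConfig,
                                       c(base, evoked_peak_uv = 0)), 1)
    t <- epochTimes(with_k)
    gains <- trialTruth(with_k)$evoked_gain
    expect_true(all(gains > 0))
    d <- epochSignal(with_k) - epochSignal(without)
    keep <- t <= -2 | t >= 20          # outside the overwritten artifact
    expect_equal(d[keep, ], outer(evokedKernel(t), gains)[keep, ],
                 tolerance = 1e-10, ignore_attr = TRUE)
    # kernel support: silent before the stimulus, gone by 150 ms
    k <- evokedKernel(t)
    expect_true(all(k[t < 0] == 0))
    expect_lt(max(abs(k[t > 150])), 0.01)
    expect_equal(max(abs(k)), 1)
    peak_t <- t[which.max(abs(k))]
    expect_true(peak_t >= 25 && peak_t <= 80)
})

test_that("interactions that could flip the evoked sign are rejected", {
    cfg <- genConfig(n_trials = 30, gamma = 1.6, seed = 2)
    expect_error(generateDataset(cfg, 1), "negative")
    expect_error(genConfig(n_trials = 0), "nTrials")
    expect_error(genConfig(noise_scale = -1), "amplitude")
    expect_error(genConfig(epoch_span = c(0, 1000)), "artifact")
})

test_that("truthPhase follows the cosine convention", {
    es <- makeOscEpochs(10, phase0_deg = 0)
    expect_lt(abs(truthPhase(es, "alpha", 0)), 1)
    # quarter period after a peak: 25 ms at 10 Hz
    expect_equal(truthPhase(es, "alpha", 25), 90, tolerance = 1)
    es90 <- makeOscEpochs(10, phase0_deg = 90)
    expect_equal(truthPhase(es90, "alpha", 0), 90, tolerance = 1)
    # agreement with the analytic signal of the stored clean trace
    u <- SummarizedExperiment::assay(es, "clean_alpha")[, 1]
    ref <- (Arg(prestim:::.analyticVector(u)) * 180 / pi) %% 360
    i0 <- which(epochTimes(es) == 0)
    expect_equal(truthPhase(es, "alpha", 0), ref[i0], tolerance = 1e-9)
    expect_error(truthPhase(generateDataset(
        genConfig(n_trials = 2, store_clean = FALSE), 1), "alpha"),
        "clean oscillator")
})

test_that("pre-stimulus power predicts post-window band amplitude (continuation)", {
    cfg <- pipelineConfig(n_trials = 400, evoked_peak_uv = 0, seed = 1)
    es <- preprocessEpochs(generateDataset(cfg, 1))
    t <- epochTimes(es)
    fs <- samplingRate(es)
    sig <- epochSignal(es)
    n <- nrow(sig)
    fftband <- function(x, lo, hi) {     # ideal zero-phase band selection
        f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
        m <- as.numeric(f >= lo & f <= hi)
        Re(mvfft(mvfft(x) * m, inverse = TRUE)) / n
    }
    for (b in defaultBands()) {
        pre <- prestimPower(es, b, 0)
        post <- colMeans(fftband(sig, b@lo, b@hi)[t >= 25 & t <= 80, ]^2)
        expect_gt(cor(log(pre), log(post)), 0.5)
    }
})
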