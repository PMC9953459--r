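test_that("excision bridges the artifact span with the anchor line", {
    t <- seq(-100, 100)
    # constant signal: line through equal anchors changes nothing
    es <- makeEpochs(rep(5, length(t)), times = t)
    expect_equal(epochSignal(exciseInterpolate(es)), epochSignal(es))
    # a linear ramp is reproduced exactly by linear interpolation
    es <- makeEpochs(as.numeric(t), times = t)
    expect_equal(epochSignal(exciseInterpolate(es)), epochSignal(es))
    # arbitrary junk strictly inside (-2, 20) is replaced by the line
    # through the anchors (-2, 0) and (20, 22): value = t + 2
    x <- as.numeric(t) + 2
    x[t > -2 & t < 20] <- rnorm(sum(t > -2 & t < 20), sd = 100)
    es <- exciseInterpolate(makeEpochs(x, times = t))
    inside <- t > -2 & t < 20
    expect_equal(epochSignal(es)[inside, 1], t[inside] + 2)
    # samples outside the span are untouched
    expect_equal(epochSignal(es)[!inside, 1], x[!inside])
    # idempotence
    expect_equal(epochSignal(exciseInterpolate(es)), epochSignal(es))
})

test_that("excision without an anchor sample errors", {
    es <- makeEpochs(rnorm(21), times = seq(0, 20))
    expect_error(exciseInterpolate(es, c(-2, 20)), "anchor")
})

test_that("baseline correction subtracts the per-trial baseline mean", {
    t <- seq(-600, 100)
    es <- makeEpochs(rep(7, length(t)), times = t)
    expect_true(all(epochSignal(baselineCorrect(es)) == 0))
    # baseline samples {1,2,3} repeated: mean 2 subtracted everywhere
    x <- rep(c(1, 2, 3), length.out = length(t))
    idx <- which(t >= -500 & t <= -200)
    x[idx] <- rep(c(1, 2, 3), length.out = length(idx))
    es <- makeEpochs(x, times = t)
    m <- mean(x[idx])
    expect_equal(epochSignal(baselineCorrect(es))[, 1], x - m)
    # idempotence and invariance of inter-sample differences
    bc <- baselineCorrect(es)
    expect_equal(epochSignal(baselineCorrect(bc)), epochSignal(bc))
    expect_equal(diff(epochSignal(bc)[, 1]), diff(x))
    expect_error(baselineCorrect(es, c(500, 600)), "no samples")
})

test_that("down-sampling preserves DC and in-band amplitude", {
    t2 <- seq(-500, 500, by = 0.5)          # 2 kHz
    es <- makeEpochs(rep(3, length(t2)), times = t2, fs = 2000)
    expect_identical(downsampleEpochs(es, 2000), es)   # identity
    ds <- downsampleEpochs(es, 1000)
    expect_equal(samplingRate(ds), 1000)
    expect_equal(mean(diff(epochTimes(ds))), 1)
    expect_equal(unname(epochSignal(ds)[50:100, 1]), rep(3, 51),
                 tolerance = 1e-6)
    # 10 Hz sinusoid: amplitude preserved within 1% away from the edges
    x <- sin(2 * pi * 10 * t2 / 1000)
    ds <- downsampleEpochs(makeEpochs(x, times = t2, fs = 2000), 1000)
    td <- epochTimes(ds)
    mid <- td > -400 & td < 400
    expect_equal(max(abs(epochSignal(ds)[mid, 1])), 1, tolerance = 0.01)
    expect_error(downsampleEpochs(es, 1500), "integer multiple")
})
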