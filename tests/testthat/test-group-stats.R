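test_that("normalized AUC subtracts the all-trials mean per bin", {
    s <- data.frame(dataset = 1, band = "alpha",
                    auc_random_tms = 10,
                    auc_positive_peak_tms = 12, auc_deg90_tms = 10,
                    auc_negative_peak_tms = 8, auc_deg270_tms = NA)
    out <- normalizedAUC(s, "alpha", "tms")
    expect_equal(out$positive_peak, 2)
    expect_equal(out$deg90, 0)
    expect_equal(out$negative_peak, -2)
    expect_true(is.na(out$deg270))           # empty bin stays missing
})

test_that("corrected effect is the difference of power differences", {
    s <- data.frame(dataset = 1:2, band = "theta",
                    auc_high_tms = c(22.5, 5), auc_low_tms = c(18.7, 5),
                    auc_high_ctrl = c(11.2, 5), auc_low_ctrl = c(9.7, 5))
    ce <- correctedEffect(s, "theta")
    expect_equal(ce$value, c(2.3, 0), tolerance = 1e-9)
})

test_that("paired t handles regular and degenerate differences", {
    v <- c(3, 1, 4, 1, 5)
    r <- pairedT(v, v)
    expect_equal(r$t, 0)
    expect_equal(r$p, 1)
    r <- pairedT(c(2, 3, 4, 5), c(1, 2, 3, 4))   # differences all 1
    expect_true(r$degenerate)
    expect_identical(r$t, Inf)
    expect_equal(r$p, 0)
    # differences {1,2,3}: t = 2 / (1/sqrt(3)) = 2 sqrt(3)
    r <- pairedT(c(2, 4, 6), c(1, 2, 3))
    expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
    expect_equal(r$df, 2)
    expect_equal(r$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)
})

test_that("one-sample t reproduces the published group statistics", {
    # mean 2.3, sd 6.2, n 64 -> t = 2.97 on 63 df (printed as 2.9, p < .01)
    z <- rnorm(64)
    v <- 2.3 + 6.2 * (z - mean(z)) / sd(z)
    r <- oneSampleT(v)
    expect_equal(r$t, 2.3 / (6.2 / 8), tolerance = 1e-9)
    expect_equal(r$t, 2.97, tolerance = 0.005)
    expect_equal(r$df, 63)
    expect_lt(r$p, 0.01)
    # mean 1.3, sd 5.9, n 64 -> t = 1.76, p = 0.083 (printed 0.085)
    v <- 1.3 + 5.9 * (z - mean(z)) / sd(z)
    r <- oneSampleT(v)
    expect_equal(r$t, 1.3 / (5.9 / 8), tolerance = 1e-9)
    expect_equal(r$p, 2 * pt(-1.3 / (5.9 / 8), 63), tolerance = 1e-9)
    expect_equal(r$p, 0.083, tolerance = 0.005)
    # symmetric values: t = 0
    expect_equal(oneSampleT(c(-2, -1, 1, 2))$t, 0)
    expect_true(oneSampleT(rep(4, 5))$degenerate)
})

test_that("Bonferroni thresholds follow the three-decimal convention", {
    expect_equal(adjustAlpha(0.05, 12), 0.004)
    expect_equal(adjustAlpha(0.05, 3), 0.017)
    expect_equal(adjustAlpha(0.05, 6), 0.008)
    expect_equal(adjustAlpha(0.05, 1), 0.05)
    expect_equal(adjustAlpha(0.05, 3, digits = NA), 0.05 / 3)
})
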