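test_that("forecast phase matches the construction on noiseless sinusoids", {
    b <- defaultBands()$alpha
    p <- defaultPhastimateParams("alpha")
    # peak exactly at the target: 0 degrees
    x <- sineWindow(10, p@windowMs, phase_at_target = 0)
    d0 <- phastimatePhase(matrix(x), p, b, 1000, -4, 0)
    expect_lt(min(d0, 360 - d0), 10)
    # half a period later: 180 degrees
    x <- sineWindow(10, p@windowMs, phase_at_target = 180)
    d180 <- phastimatePhase(matrix(x), p, b, 1000, -4, 0)
    expect_lt(abs(d180 - 180), 10)
    expect_error(phastimatePhase(matrix(x[1:100]), p, b, 1000, -4, 0),
                 "window")
})

test_that("forecast and oracle share the phase convention", {
    b <- defaultBands()$alpha
    p <- defaultPhastimateParams("alpha")
    t <- seq(-2000, 500)
    set.seed(42)
    ph0 <- runif(100, 0, 360)
    x <- sapply(ph0, function(u) cos(2 * pi * 10 * t / 1000 + u * pi / 180))
    oracle <- hilbertOraclePhase(x, b, 1000, t, 0)
    i_end <- max(which(t <= -4))
    nw <- round(p@windowMs)
    est <- phastimatePhase(x[(i_end - nw + 1):i_end, ], p, b, 1000,
                           t[i_end], 0)
    expect_lt(circularErrorSD(est, oracle) * 180 / pi, 10)
    expect_true(all(est >= 0 & est < 360))
})

test_that("oracle phase follows the analytic-signal convention", {
    b <- defaultBands()$alpha
    t <- seq(-2000, 500)
    x <- cos(2 * pi * 10 * t / 1000)       # peak at t = 0
    v <- hilbertOraclePhase(matrix(x), b, 1000, t, 0)
    expect_lt(min(v, 360 - v), 2)
    expect_equal(hilbertOraclePhase(matrix(x), b, 1000, t, 25), 90,
                 tolerance = 2)
    # a chirp's unwrapped phase advances monotonically
    f_inst <- seq(8, 13, length.out = length(t))
    xc <- cos(cumsum(2 * pi * f_inst / 1000))
    angs <- sapply(seq(-300, 100, by = 25),
                   function(tt) hilbertOraclePhase(matrix(xc), b, 1000,
                                                   t, tt))
    unwrapped <- angs + 360 * cumsum(c(0, diff(angs) < 0))
    expect_true(all(diff(unwrapped) > 0))
    expect_error(hilbertOraclePhase(matrix(x), b, 1000, t, -1999), "edge")
})

test_that("noise raises the circular forecasting error", {
    b <- defaultBands()$alpha
    p <- defaultPhastimateParams("alpha")
    set.seed(7)
    n <- 60
    run <- function(snr) {
        ph0 <- runif(n, 0, 360)
        est <- vapply(ph0, function(u)
            phastimatePhase(matrix(sineWindow(10, p@windowMs,
                                              phase_at_target = u,
                                              snr = snr)),
                            p, b, 1000, -4, 0), numeric(1))
        circularErrorSD(est, ph0)
    }
    expect_gt(run(0.05), run(10))   # near-pure noise vs clean oscillation
})

test_that("circular error statistic matches its closed forms", {
    expect_equal(circularErrorSD(c(10, 250, 380 %% 360), c(10, 250, 20)), 0)
    # differences {0, 90}: Rbar = |(1 + i)/2| = sqrt(2)/2
    expect_equal(circularErrorSD(c(0, 90), c(0, 0)),
                 sqrt(-2 * log(sqrt(2) / 2)), tolerance = 1e-12)
    expect_equal(circularErrorSD(c(0, 90), c(0, 0)), 0.8326, tolerance = 1e-4)
    # four equally spaced differences: vanishing resultant
    expect_warning(v <- circularErrorSD(c(0, 90, 180, 270), rep(0, 4)),
                   "undefined")
    expect_identical(v, Inf)
})

test_that("parameter search returns the best row deterministically", {
    b <- defaultBands()$alpha
    t <- seq(-2500, 0)
    set.seed(9)
    ph0 <- runif(40, 0, 360)
    x <- sapply(ph0, function(u)
        cos(2 * pi * 10 * t / 1000 + u * pi / 180) + 0.2 * rnorm(length(t)))
    table_row <- data.frame(filter_order = 192, window_ms = 718,
                            edge_ms = 65, ar_order = 25,
                            hilbert_window = 128)
    # singleton grid: that row
    got <- optimizePhastimate(x, t, b, table_row, 1000)
    expect_equal(got@arOrder, 25)
    # degenerate AR order loses to the sensible row
    grid <- rbind(table_row,
                  transform(table_row, ar_order = 1))
    got <- optimizePhastimate(x, t, b, grid, 1000)
    expect_equal(got@arOrder, 25)
    err <- attr(got, "grid")$error_rad
    expect_lt(err[1], err[2])
    # repeated runs select identically
    again <- optimizePhastimate(x, t, b, grid, 1000)
    expect_equal(attr(again, "grid")$error_rad, err)
    expect_error(optimizePhastimate(x, t, b, grid[0, ], 1000), "empty")
})
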