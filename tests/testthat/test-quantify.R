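test_that("ratio computation follows the fura-2 convention and guards f380", {
    expect_equal(computeRatio(c(1, 2, 3), f380 = c(1, 2, 3)), rep(1, 3))
    expect_equal(computeRatio(c(2, 4), f380 = c(1, 2)), c(2, 2))
    expect_error(computeRatio(c(1, 2), f380 = c(1, 0)), "sample 2")
    # TasteTraceSet method adds the assay and passes ratio through
    tts <- TasteTraceSet(f340 = matrix(2, 10, 1), f380 = matrix(1, 10, 1),
        time = 0:9)
    expect_equal(unname(SummarizedExperiment::assay(computeRatio(tts),
        "ratio")[1, 1]), 2)
})

test_that("baseline statistics use the pre-stimulus window with n-1 SD", {
    b <- estimateBaseline(0:59, rep(1.3, 60), epochStart = 40,
        windowS = 30)
    expect_equal(b$mean, 1.3)
    expect_equal(b$sd, 0)
    expect_equal(b$n, 30)
    # hand-computed two-sample case
    y <- c(rep(0, 8), 1.0, 1.2, rep(9, 10))
    b2 <- estimateBaseline(0:19, y, epochStart = 10, windowS = 2,
        minSamples = 2)
    expect_equal(b2$mean, 1.1)
    expect_equal(b2$sd, sqrt(0.02), tolerance = 1e-6)
    # bounds and sample-count guards
    expect_error(estimateBaseline(0:59, rnorm(60), epochStart = 20,
        windowS = 30), "before the trace start")
    expect_error(estimateBaseline(0:59, rnorm(60), epochStart = 4,
        windowS = 4), "need >= 5")
})

test_that("the 2-SD rule requires a sustained supra-threshold run", {
    tm <- 0:99
    base <- fixedBaseline(1, 0.01)
    flat <- rep(1, 100)
    expect_false(detectResponse(tm, flat, c(40, 70), base)$responsive)
    # sustained step of +3 SD is detected at its first sample
    step <- flat; step[51:60] <- 1.03
    det <- detectResponse(tm, step, c(40, 70), base)
    expect_true(det$responsive)
    expect_equal(det$crossingIndex, 51L)
    # a single +5 SD spike is rejected by min_run = 3
    spike <- flat; spike[55] <- 1.05
    expect_false(detectResponse(tm, spike, c(40, 70), base)$responsive)
    # brute-force oracle: no 3-sample window is entirely above threshold
    thr <- 1 + 2 * 0.01
    runs <- vapply(seq_len(98), function(i) all(spike[i:(i + 2)] > thr),
        logical(1))
    expect_false(any(runs))
})

test_that("onset/offset localisation handles pulses and no-return traces", {
    sq <- squarePulseTrace(n = 60, from = 20, to = 29)
    base <- fixedBaseline(1, 0.01)
    det <- detectResponse(sq$time, sq$ratio, c(18, 32), base)
    loc <- locateResponseWindow(sq$time, sq$ratio, base,
        det$crossingIndex)
    expect_equal(loc$onset_s, 19)   # last at-baseline sample before the run
    expect_equal(loc$offset_s, 30)  # first settled sample after the pulse
    expect_false(loc$noReturn)
    # monotone rising trace never returns
    rise <- list(time = 0:59, ratio = 1 + c(rep(0, 20), seq(0, 2,
        length.out = 40)))
    det2 <- detectResponse(rise$time, rise$ratio, c(18, 32), base)
    loc2 <- locateResponseWindow(rise$time, rise$ratio, base,
        det2$crossingIndex)
    expect_true(loc2$noReturn)
    expect_true(is.na(loc2$offset_s))
})

test_that("amplitude is the percent increase of the window peak over baseline", {
    tm <- 0:9
    base <- fixedBaseline(1, 0.01)
    y <- c(1, 1, 1.742, 1.3, 1, 1, 1, 1, 1, 1)
    amp <- quantifyAmplitude(tm, y, base, 1, 6)
    expect_equal(amp$amplitude_pct, 74.2)
    expect_equal(quantifyAmplitude(tm, rep(1, 10), base, 1,
        6)$amplitude_pct, 0)
    b2 <- fixedBaseline(2, 0.01)
    expect_equal(quantifyAmplitude(tm, c(2, 2, 3, 2, 2, 2, 2, 2, 2, 2),
        b2, 1, 6)$amplitude_pct, 50)
    expect_error(quantifyAmplitude(tm, y, fixedBaseline(0, 0.01), 1, 6),
        "baseline mean")
})

test_that("AUC is the clamped trapezoidal integral over the located window", {
    sq <- squarePulseTrace(n = 60, from = 20, to = 29, height = 0.5)
    base <- fixedBaseline(1, 0.01)
    # onset at 19 s, offset at 30 s (indices 20/31): the plateau
    # contributes 4.5 and the two boundary trapezoids 0.25 each
    expect_equal(integrateResponse(sq$time, sq$ratio, base, 20, 31), 5.0)
    expect_equal(integrateResponse(sq$time, rep(1, 60), base, 20, 31), 0)
    # excursions below baseline contribute nothing
    dip <- rep(1, 60); dip[22:24] <- 0.4
    expect_equal(integrateResponse(sq$time, dip, base, 20, 31), 0)
    expect_error(integrateResponse(sq$time, sq$ratio, base, 30, 30),
        "offset after onset")
})

test_that("AUC scales linearly with amplitude for fixed kinetics", {
    mk <- function(amp) {
        p <- TraceGenParams(amplitudePct = amp, noiseSd = 1e-12,
            decayTau = 10)
        as.numeric(SummarizedExperiment::assay(simulateTrace(p, 1),
            "ratio"))
    }
    tm <- TasteCa:::.traceGrid(TraceGenParams())
    base <- fixedBaseline(1, 1e-12)
    a1 <- integrateResponse(tm, mk(20), base, 63, 140)
    a2 <- integrateResponse(tm, mk(40), base, 63, 140)
    expect_gt(a1, 0)
    expect_equal(a2 / a1, 2, tolerance = 1e-6)
})

test_that("duration of a calibrated transient round-trips through the locator", {
    # decay calibrated so the clean transient re-enters the band 46 s
    # after the peak; located duration must match within one sample
    noise <- 0.005
    tau <- calibrateDecay(50, 1, noise, targetDuration = 46 + 10,
        returnBandK = 2)
    p <- TraceGenParams(amplitudePct = 50, noiseSd = 1e-9,
        decayTau = tau)
    tm <- TasteCa:::.traceGrid(p)
    y <- 1 + TasteCa:::.transientDelta(tm, 62, 0.5, 2, tau)
    base <- fixedBaseline(1, noise)  # band matches the calibration
    det <- detectResponse(tm, y, c(60, 90), base)
    loc <- locateResponseWindow(tm, y, base, det$crossingIndex)
    expect_false(loc$noReturn)
    expect_lt(abs((loc$offset_s - loc$onset_s) - 56), 1 + 1e-9)
})

test_that("per-cell quantification is independent across epochs", {
    # two epochs; transient only in the second
    tm <- 0:479
    tau <- 10
    y <- 1 + TasteCa:::.transientDelta(tm, 302, 0.5, 2, tau)
    set.seed(99)
    y <- y + rnorm(length(y), 0, 0.005)
    ep <- data.frame(stimulus = c("SAC", "Den"),
        concentration_mM = c(2, 5), start_s = c(60, 300),
        end_s = c(90, 330))
    calls <- quantifyCell(tm, y, ep)
    expect_equal(calls$responsive, c(FALSE, TRUE))
    expect_true(all(is.na(calls[1, c("peak", "amplitude_pct", "auc",
        "duration_s")])))
    expect_equal(calls$amplitude_pct[2], 50, tolerance = 0.05)
    expect_error(quantifyCell(tm, y, data.frame(stimulus = c("a", "b"),
        concentration_mM = 1, start_s = c(60, 80), end_s = c(100, 120))),
        "overlap")
})

test_that("preset cohort traces are recovered as responsive with preset-scale amplitude", {
    calls <- quantifyPresetCohort("ctl_SAC", nCells = 30, seed = 8,
        amplitudeCv = 0)
    expect_true(all(calls$responsive))
    expect_equal(mean(calls$amplitude_pct), 74.2, tolerance = 0.05)
})

test_that("no-return responses are flagged and excluded from AUC and duration", {
    # slow huge transient that cannot settle before the trace ends
    p <- TraceGenParams(amplitudePct = 100, decayTau = 500,
        durationTotal = 240)
    tr <- simulateTrace(p, seed = 13)
    calls <- as.data.frame(quantifyCells(tr))
    expect_true(calls$responsive)
    expect_true(calls$excluded_no_return)
    expect_true(is.na(calls$auc) && is.na(calls$duration_s))
    expect_false(is.na(calls$amplitude_pct))
})
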