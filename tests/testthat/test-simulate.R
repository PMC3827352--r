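test_that("simulated traces have the configured length and are reproducible", {
    p <- TraceGenParams(amplitudePct = 40, durationTotal = 200,
        samplingInterval = 0.5)
    a <- simulateTrace(p, seed = 11)
    b <- simulateTrace(p, seed = 11)
    expect_equal(nrow(a), 400)
    expect_identical(SummarizedExperiment::assay(a, "ratio"),
        SummarizedExperiment::assay(b, "ratio"))
    c <- simulateTrace(p, seed = 12)
    expect_false(identical(SummarizedExperiment::assay(a, "ratio"),
        SummarizedExperiment::assay(c, "ratio")))
})

test_that("non-responder traces are baseline plus noise", {
    p <- TraceGenParams(responder = FALSE, baselineMean = 1.2,
        noiseSd = 0.01, durationTotal = 400)
    y <- SummarizedExperiment::assay(simulateTrace(p, seed = 3), "ratio")
    expect_lt(abs(mean(y) - 1.2), 3 * 0.01 / sqrt(length(y)))
    # zero-amplitude responder is indistinguishable from a non-responder
    pz <- TraceGenParams(responder = TRUE, amplitudePct = 0,
        baselineMean = 1.2, noiseSd = 0.01, durationTotal = 400)
    yz <- SummarizedExperiment::assay(simulateTrace(pz, seed = 3), "ratio")
    expect_identical(as.numeric(y), as.numeric(yz))
})

test_that("a noise-free responder attains exactly the configured peak", {
    p <- tracePreset("ctl_SAC")
    p@noiseSd <- 1e-12
    y <- SummarizedExperiment::assay(simulateTrace(p, seed = 1), "ratio")
    expect_equal(max(y), 1.742, tolerance = 1e-9)
    # amplitude scale: peak elevation is amplitudePct% of baseline
    p2 <- TraceGenParams(amplitudePct = 19.1, baselineMean = 2,
        noiseSd = 1e-12)
    y2 <- SummarizedExperiment::assay(simulateTrace(p2, seed = 1), "ratio")
    expect_equal(max(y2), 2 * 1.191, tolerance = 1e-9)
})

test_that("invalid generator parameters are rejected naming the field", {
    expect_error(TraceGenParams(noiseSd = 0), "noiseSd")
    expect_error(TraceGenParams(amplitudePct = -1), "amplitudePct")
    expect_error(TraceGenParams(riseTau = -2), "riseTau")
    expect_error(TraceGenParams(durationTotal = 100,
        epoch = StimulusEpoch("SAC", 2, 60, 120)), "epoch")
    expect_error(StimulusEpoch("SAC", 2, 90, 60), "start")
})

test_that("calibrateDecay matches its closed form and rejects infeasible targets", {
    # peak elevation 0.5 re-entering a 0.05 band 46.05 s after the peak
    expect_equal(
        calibrateDecay(50, 1, 0.025, targetDuration = 46.05 + 10,
            returnBandK = 2, riseTau = 2),
        20, tolerance = 1e-3)
    # target equal to the rise time is infeasible
    expect_error(calibrateDecay(50, 1, 0.01, targetDuration = 10,
        riseTau = 2), "infeasible")
    # peak below the band is infeasible
    expect_error(calibrateDecay(1, 1, 0.01, targetDuration = 50,
        returnBandK = 2), "infeasible")
})

test_that("widening the return band increases the implied decay constant", {
    grid <- expand.grid(amp = c(20, 59.8, 74.2), dur = c(40, 65.5, 90),
        k = c(1, 2, 3))
    for (i in seq_len(nrow(grid))) {
        g <- grid[i, ]
        expect_gt(
            calibrateDecay(g$amp, 1, 0.005, g$dur, returnBandK = 2 * g$k),
            calibrateDecay(g$amp, 1, 0.005, g$dur, returnBandK = g$k))
    }
})

test_that("calibrated decay round-trips through band re-entry on a clean trace", {
    noise <- 1e-6
    for (target in c(50.5, 65.5)) {
        tau <- calibrateDecay(59.8, 1, noise, targetDuration = target,
            returnBandK = 2)
        p <- TraceGenParams(amplitudePct = 59.8, noiseSd = noise,
            decayTau = tau, epoch = StimulusEpoch("Den", 5, 60, 90))
        tm <- traceTimes(simulateTrace(p, seed = 1))
        y <- TasteCa:::.transientDelta(tm, 62, 0.598, 2, tau) + 1
        # first time the noise-free transient is back inside the band
        reentry <- tm[which(tm > 72 & abs(y - 1) <= 2 * noise)[1]]
        expect_lt(abs((reentry - 62) - target), 1 + 1e-9)
    }
})

test_that("cohort ground-truth labels match the configured fractions", {
    p <- tracePreset("ctl_MPG")
    mk <- function(frac, n) cohortConfig("g", list(MPG = p),
        responderFraction = c(MPG = frac), nCells = n)
    all1 <- simulateCohort(mk(1, 50), seed = 5)
    expect_true(all(SummarizedExperiment::colData(all1)$true_responder_MPG))
    none <- simulateCohort(mk(0, 50), seed = 5)
    expect_false(any(SummarizedExperiment::colData(none)$true_responder_MPG))
    big <- simulateCohort(mk(0.3, 10000), seed = 7)
    expect_lt(
        abs(mean(SummarizedExperiment::colData(big)$true_responder_MPG) - 0.3),
        0.02)
})

test_that("per-cell substreams are stable under cohort-size changes", {
    p <- tracePreset("ctl_SAC")
    cfg5 <- cohortConfig("g", list(SAC = p), nCells = 5)
    cfg9 <- cohortConfig("g", list(SAC = p), nCells = 9)
    a <- SummarizedExperiment::assay(simulateCohort(cfg5, seed = 21), "ratio")
    b <- SummarizedExperiment::assay(simulateCohort(cfg9, seed = 21), "ratio")
    expect_identical(a, b[, 1:5])
})

test_that("intake generator hits the configured preference", {
    # indifference and full preference, noise off
    r1 <- simulatePreferenceRecords(IntakeGenParams(truePreference = 1,
        betaPrecision = Inf, nAnimals = 3, concentrations = c(1, 2)),
        seed = 1)
    expect_true(all(r1$water_intake == 0))
    expect_equal(preferenceTable(r1)$ratio, rep(1, 6))
    # sampling-error bound at n = 200
    r2 <- simulatePreferenceRecords(IntakeGenParams(truePreference = 0.8,
        nAnimals = 200, concentrations = 2), seed = 2)
    expect_lt(abs(mean(preferenceTable(r2)$ratio) - 0.8), 0.03)
    # sides alternate between periods for each animal x concentration
    byCell <- split(r2$test_side, paste(r2$animal_id, r2$concentration_mM))
    expect_true(all(vapply(byCell, function(s)
        length(unique(s)) == 2L, logical(1))))
})
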