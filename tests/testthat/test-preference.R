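oneCell <- function(test, water, periods = seq_along(test)) {
    data.frame(animal_id = "a1", group = "ctl", stimulus = "SAC",
        concentration_mM = 2, period = periods, test_intake = test,
        water_intake = water)
}

test_that("preference ratios pool volumes over the two periods", {
    expect_equal(preferenceRatio(oneCell(c(5, 5), c(5, 5))), 0.5)
    expect_equal(preferenceRatio(oneCell(c(0, 0), c(4, 6))), 0)
    # side-swap cancellation: (8,2) then (2,8) pools to 10/20
    expect_equal(preferenceRatio(oneCell(c(8, 2), c(2, 8))), 0.5)
    # order of the periods is irrelevant
    rec <- oneCell(c(8, 2), c(2, 8))
    expect_equal(preferenceRatio(rec[2:1, ]), preferenceRatio(rec))
    expect_error(preferenceRatio(oneCell(5, 5, periods = 1)),
        "missing 24 h period")
    expect_error(preferenceRatio(oneCell(c(0, 0), c(0, 0))),
        "zero total intake")
})

test_that("relabelling test and water maps the ratio to its complement", {
    set.seed(41)
    rec <- simulatePreferenceRecords(IntakeGenParams(
        truePreference = 0.7, nAnimals = 10), seed = 41)
    swapped <- rec
    swapped$test_intake <- rec$water_intake
    swapped$water_intake <- rec$test_intake
    expect_equal(preferenceTable(swapped)$ratio,
        1 - preferenceTable(rec)$ratio)
    expect_true(all(preferenceTable(rec)$ratio >= 0 &
        preferenceTable(rec)$ratio <= 1))
})

test_that("48 h pooling cancels a pure side preference", {
    rec <- simulatePreferenceRecords(IntakeGenParams(
        truePreference = 0.5, sideBias = 0.2, nAnimals = 100,
        concentrations = 2), seed = 77)
    # per-animal ratio SD ~0.075 (beta noise + intake imbalance);
    # bound the cohort mean at 3 standard errors
    expect_lt(abs(mean(preferenceTable(rec)$ratio) - 0.5), 0.023)
})

test_that("the repeated-measures ANOVA rejects incomplete series", {
    rec <- simulatePreferenceRecords(IntakeGenParams(truePreference = 0.6,
        nAnimals = 4), seed = 5)
    pref <- preferenceTable(rec)
    pref$group <- rep(c("ctl", "ob"), each = nrow(pref) / 2)
    drop <- pref[-1, ]
    expect_error(rmTwoWayAnova(drop), "incomplete")
    fit <- rmTwoWayAnova(pref)
    expect_setequal(fit$effects$effect, c("group", "conc", "group:conc"))
    expect_true(all(fit$contrasts$p.adj >= fit$contrasts$p.raw))
})

test_that("group effect holds its nominal type-I level under the null", {
    nRej <- 0L
    nSim <- 300L
    for (i in seq_len(nSim)) {
        rec <- rbind(
            simulatePreferenceRecords(IntakeGenParams(0.5, nAnimals = 5,
                group = "ctl"), seed = 2 * i),
            simulatePreferenceRecords(IntakeGenParams(0.5, nAnimals = 5,
                group = "ob"), seed = 2 * i + 1))
        fit <- rmTwoWayAnova(preferenceTable(rec))
        if (fit$effects$p[fit$effects$effect == "group"] < 0.05)
            nRej <- nRej + 1L
    }
    expect_gt(nRej / nSim, 0.02)
    expect_lt(nRej / nSim, 0.10)
})

test_that("a top-concentration difference is found by interaction and contrast", {
    hits <- vapply(seq_len(60), function(i) {
        rec <- rbind(
            simulatePreferenceRecords(IntakeGenParams(
                c(0.5, 0.5, 0.5, 0.9), nAnimals = 25, group = "ctl"),
                seed = 1000 + 2 * i),
            simulatePreferenceRecords(IntakeGenParams(
                c(0.5, 0.5, 0.5, 0.5), nAnimals = 25, group = "ob"),
                seed = 1001 + 2 * i))
        fit <- rmTwoWayAnova(preferenceTable(rec))
        top <- fit$contrasts[fit$contrasts$concentration_mM == 20, ]
        c(fit$effects$p[fit$effects$effect == "group:conc"] < 0.05,
          top$p.adj < 0.05)
    }, logical(2))
    expect_gte(mean(hits[1, ]), 0.9)
    expect_gte(mean(hits[2, ]), 0.9)
})

test_that("per-concentration t-tests return one row per concentration", {
    rec <- rbind(
        simulatePreferenceRecords(IntakeGenParams(0.9, nAnimals = 5,
            group = "ctl"), seed = 8),
        simulatePreferenceRecords(IntakeGenParams(0.5, nAnimals = 5,
            group = "ob"), seed = 9))
    pref <- preferenceTable(rec)
    tt <- perConcentrationTests(pref)
    expect_equal(nrow(tt), 4)
    expect_true(all(tt$p < 0.05))  # 0.4 gap at n = 5 is decisive
    one <- perConcentrationTests(pref[pref$concentration_mM == 2, ])
    expect_equal(nrow(one), 1)
    # dose-curve summary shape
    ds <- doseCurveSummary(pref)
    expect_equal(nrow(ds), 8)
    expect_true(all(c("mean_ratio", "sd_ratio", "n") %in% colnames(ds)))
})
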