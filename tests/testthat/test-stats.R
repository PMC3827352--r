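test_that("responder tables count responsive cells per cohort", {
    calls <- data.frame(cell_id = paste0("c", 1:10), stimulus = "SAC",
        responsive = rep(c(TRUE, FALSE), c(4, 6)), group = "ctl")
    tab <- buildResponderTable(calls, "SAC")
    expect_equal(unname(tab["ctl", ]), c(4L, 6L))
    # a cell present in the table but untested for the stimulus errors
    extra <- rbind(calls, data.frame(cell_id = "c11", stimulus = "Den",
        responsive = TRUE, group = "ctl"))
    expect_error(buildResponderTable(extra, "SAC"), "untested")
    expect_error(buildResponderTable(calls, "SAC",
        cohorts = c("ctl", "ob")), "empty")
})

test_that("chi-square matches hand-computed values and guards marginals", {
    h <- chiSquareIndependence(rbind(c(20, 20), c(10, 10)))
    expect_equal(h$statistic, 0)
    expect_equal(h$p.value, 1)
    # expected counts 22.5/17.5 by hand: 2*56.25/22.5 + 2*56.25/17.5
    h2 <- chiSquareIndependence(rbind(c(30, 10), c(15, 25)))
    expect_equal(h2$statistic, 11.4286, tolerance = 1e-4)
    expect_equal(h2$df, 1)
    expect_error(chiSquareIndependence(rbind(c(0, 0), c(5, 5))),
        "marginal")
    expect_error(chiSquareIndependence(matrix(1:3, 1)), "2 x 2")
})

test_that("chi-square equals the from-scratch expected-counts oracle", {
    set.seed(515)
    for (i in seq_len(100)) {
        tab <- matrix(rpois(4, lambda = sample(3:40, 1)) + 1, 2)
        expect_equal(chiSquareIndependence(tab)$statistic,
            chisqOracle(tab), tolerance = 1e-10)
    }
})

test_that("one-way ANOVA with Bonferroni post-hoc behaves at the extremes", {
    set.seed(7)
    base <- rnorm(30)
    # identical duplicated groups: no between-group variance
    same <- oneWayAnovaBonferroni(c(base, base),
        rep(c("a", "b"), each = 30))
    expect_lt(same$F, 1e-10)
    # means separated by 5 pooled SDs: essentially always significant
    far <- oneWayAnovaBonferroni(c(base, base + 5, base + 10),
        rep(c("a", "b", "c"), each = 30))
    expect_lt(far$p.value, 1e-6)
    expect_true(all(far$pairwise$p.adj < 0.05))
    # Bonferroni invariants
    expect_true(all(far$pairwise$p.adj >= far$pairwise$p.raw))
    expect_true(all(far$pairwise$p.adj <= 1))
    expect_error(oneWayAnovaBonferroni(c(1, 2, 3), c("a", "a", "b")),
        "'b'")
})

test_that("Student's t-test handles identity, hand cases and degeneracy", {
    x <- c(1.2, 3.4, 2.2, 5.1)
    same <- twoSampleT(x, x)
    expect_equal(same$statistic, 0)
    expect_equal(same$p.value, 1)
    expect_equal(twoSampleT(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
    expect_warning(deg <- twoSampleT(c(2, 2), c(2, 2)), "degenerate")
    expect_equal(deg$p.value, 1)
    # pooled vs Welch differ under unequal variances
    set.seed(9)
    a <- rnorm(10, sd = 0.1); b <- rnorm(40, sd = 3)
    expect_false(isTRUE(all.equal(twoSampleT(a, b)$df,
        twoSampleT(a, b, welch = TRUE)$df)))
})

test_that("the duration contrast between denatonium presets is well powered", {
    obese <- quantifyPresetCohort("ob_DEN", nCells = 200, seed = 61)
    ctl <- quantifyPresetCohort("ctl_DEN", nCells = 200, seed = 62)
    dObese <- obese$duration_s[!is.na(obese$duration_s)]
    dCtl <- ctl$duration_s[!is.na(ctl$duration_s)]
    set.seed(63)
    hits <- vapply(seq_len(200), function(i) {
        twoSampleT(sample(dObese, 50), sample(dCtl, 50))$p.value < 0.05
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})
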