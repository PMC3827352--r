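# Cohort-level statistics: responder-frequency chi-square, one-way ANOVA
# with Bonferroni pairwise post-hoc comparisons, and Student's t-tests.
# Significance is declared at p < 0.05 throughout, with stars at
# p < 0.05 / 0.01 / 0.001.

#' Significance stars
#' @param p numeric p-values.
#' @return character: \code{"***"} p < 0.001, \code{"**"} p < 0.01,
#'   \code{"*"} p < 0.05, \code{""} otherwise.
#' @export
significanceStars <- function(p) {
    ifelse(is.na(p), "", ifelse(p < 0.001, "***",
        ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Responder-frequency contingency table
#'
#' Counts responsive and non-responsive cells per cohort for one
#' stimulus. For MPG, pass calls pre-filtered with
#' [selectUmamiResponses()]. Every cell in the table must have been
#' tested for the stimulus.
#'
#' @param calls a response-call table (rows for the chosen stimulus are
#'   used; other rows only assert that their cells were tested).
#' @param stimulus stimulus to tabulate.
#' @param cohorts optional cohort labels defining row order; defaults to
#'   the groups present.
#' @return an integer matrix (cohorts x \code{responsive} /
#'   \code{non_responsive}) with attribute \code{stimulus}.
#' @examples
#' calls <- S4Vectors::DataFrame(cell_id = paste0("c", 1:10),
#'     stimulus = "SAC", responsive = rep(c(TRUE, FALSE), c(4, 6)),
#'     group = rep("ctl", 10))
#' buildResponderTable(calls, "SAC")
#' @export
buildResponderTable <- function(calls, stimulus, cohorts = NULL) {
    df <- as.data.frame(calls)
    sub <- df[df$stimulus == stimulus, , drop = FALSE]
    untested <- setdiff(unique(df$cell_id), sub$cell_id)
    if (length(untested))
        stop(sprintf("%d cell(s) untested for stimulus '%s' (e.g. %s)",
            length(untested), stimulus, untested[1]))
    if (!nrow(sub))
        stop(sprintf("no calls for stimulus '%s'", stimulus))
    if (is.null(cohorts)) cohorts <- unique(sub$group)
    counts <- t(vapply(cohorts, function(g) {
        r <- sub$responsive[sub$group == g]
        if (!length(r))
            stop(sprintf("cohort '%s' is empty for stimulus '%s'", g,
                stimulus))
        c(responsive = sum(r), non_responsive = sum(!r))
    }, integer(2)))
    structure(counts, stimulus = stimulus)
}

#' Pearson chi-square test of independence
#'
#' Responder-frequency comparison across cohorts; Pearson chi-square on
#' a cohorts-by-outcome contingency table, without Yates continuity
#' correction by default (matching the online calculator convention for
#' frequency comparisons; set \code{correct = TRUE} for sensitivity
#' analysis).
#'
#' @param table integer matrix of counts (e.g. from
#'   [buildResponderTable()]); at least 2 x 2.
#' @param correct logical, Yates continuity correction.
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{expected}.
#' @examples
#' chiSquareIndependence(rbind(c(30, 10), c(15, 25)))
#' @export
chiSquareIndependence <- function(table, correct = FALSE) {
    table <- as.matrix(table)
    if (nrow(table) < 2L || ncol(table) < 2L)
        stop("need at least a 2 x 2 table")
    if (any(table < 0) || any(table != round(table)))
        stop("counts must be non-negative integers")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        stop("zero marginal: every row and column needs at least one count")
    ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
        p.value = ht$p.value, expected = ht$expected)
}

#' One-way ANOVA with Bonferroni pairwise post-hoc tests
#'
#' Classic one-way fixed-effects ANOVA across cohorts, followed by all
#' pairwise two-sample t-tests (pooled variance by default) whose raw
#' p-values are Bonferroni-multiplied by the number of pairs. Supply
#' evoked responses only (null responses are excluded from response
#' summaries by design); \code{NA} measurements are dropped with their
#' count reported.
#'
#' @param values numeric measurements (amplitude, AUC, or duration).
#' @param groups cohort label per measurement.
#' @param measure,stimulus optional labels stored in the result.
#' @param welch use Welch (unpooled) pairwise t-tests.
#' @return a list of class \code{"GroupComparison"}: \code{F},
#'   \code{df}, \code{p.value}, \code{n} (per group), and a
#'   \code{pairwise} data.frame with raw and Bonferroni-adjusted
#'   p-values and significance stars.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(10), rnorm(10, 3))
#' g <- rep(c("ctl", "ob"), each = 10)
#' oneWayAnovaBonferroni(x, g)
#' @export
oneWayAnovaBonferroni <- function(values, groups, measure = NA_character_,
        stimulus = NA_character_, welch = FALSE) {
    keep <- !is.na(values)
    values <- values[keep]
    groups <- as.character(groups)[keep]
    n <- table(groups)
    if (length(n) < 2L)
        stop("need at least 2 groups")
    small <- names(n)[n < 2]
    if (length(small))
        stop(sprintf("group '%s' has fewer than 2 observations", small[1]))
    fit <- stats::aov(values ~ factor(groups))
    tab <- summary(fit)[[1]]
    pairs <- utils::combn(names(n), 2)
    npairs <- ncol(pairs)
    pw <- do.call(rbind, lapply(seq_len(npairs), function(k) {
        a <- values[groups == pairs[1, k]]
        b <- values[groups == pairs[2, k]]
        tt <- twoSampleT(a, b, welch = welch)
        data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
            t = tt$statistic, p.raw = tt$p.value,
            p.adj = min(1, tt$p.value * npairs),
            stringsAsFactors = FALSE)
    }))
    pw$stars <- significanceStars(pw$p.adj)
    structure(list(measure = measure, stimulus = stimulus,
        F = tab[["F value"]][1], df = tab[["Df"]],
        p.value = tab[["Pr(>F)"]][1], n = as.integer(n),
        groups = names(n), pairwise = pw), class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
    cat(sprintf("One-way ANOVA%s%s: F(%d, %d) = %.3f, p = %.4g %s\n",
        if (is.na(x$measure)) "" else paste0(" of ", x$measure),
        if (is.na(x$stimulus)) "" else paste0(" (", x$stimulus, ")"),
        x$df[1], x$df[2], x$F, x$p.value,
        significanceStars(x$p.value)))
    cat("  n:", paste(sprintf("%s=%d", x$groups, x$n), collapse = ", "),
        "\n")
    cat("  Bonferroni pairwise comparisons:\n")
    print(x$pairwise, row.names = FALSE)
    invisible(x)
}

#' Two-sample Student's t-test
#'
#' Two-sided t-test, pooled variance by default (\code{welch = TRUE}
#' for the unpooled variant). When both groups have zero variance and
#' equal means the test is degenerate; by convention \code{t = 0},
#' \code{p = 1} is returned with a warning.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param welch use the Welch test.
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @examples
#' twoSampleT(c(1, 2, 3), c(2, 3, 4))
#' @export
twoSampleT <- function(a, b, welch = FALSE) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
        stop("need at least 2 observations per group")
    if (stats::var(a) == 0 && stats::var(b) == 0) {
        if (mean(a) == mean(b)) {
            warning("degenerate t-test (both groups constant and equal); returning p = 1")
            return(list(statistic = 0, df = length(a) + length(b) - 2L,
                p.value = 1))
        }
        warning("degenerate t-test (both groups constant, unequal); returning p = 0")
        return(list(statistic = sign(mean(a) - mean(b)) * Inf,
            df = length(a) + length(b) - 2L, p.value = 0))
    }
    ht <- stats::t.test(a, b, var.equal = !welch)
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
        p.value = ht$p.value)
}
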