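fakeResults <- function(p_adj, ids = sprintf("s%02d", seq_along(p_adj))) {
    S4Vectors::DataFrame(series_id = ids, p_raw = p_adj / 2, p_adj = p_adj,
        q_bh = bhAdjust(p_adj), best_period_h = 24,
        best_phase_h = rep(0, length(p_adj)),
        mesor_est = 10, amplitude_est = 2, fold_change_est = 1.5,
        r_squared = 0.8)
}

test_that("hit calls use a strict threshold", {
    res <- fakeResults(c(0.049, 0.05, 0.051, 1))
    h <- classifyHits(res, 0.05, "p_adj")
    expect_identical(unname(h), c(TRUE, FALSE, FALSE, FALSE))
    expect_identical(sum(classifyHits(fakeResults(rep(1, 5)))), 0L)
    expect_error(classifyHits(res, 0.05, "p_bonferroni"))
    expect_error(classifyHits(res, 0), "threshold")
})

test_that("confusion metrics tally counts and guard empty denominators", {
    truth <- S4Vectors::DataFrame(series_id = sprintf("s%04d", 1:1000),
        is_rhythmic = rep(FALSE, 1000))
    hits <- stats::setNames(rep(FALSE, 1000), truth$series_id)
    hits[1:12] <- TRUE
    cm <- confusionMetrics(hits, truth)
    expect_equal(cm$fpr, 0.012)
    expect_identical(cm$fp, 12L)
    expect_equal(cm$fdr_observed, 1)
    expect_true(is.na(cm$tpr))

    none <- stats::setNames(rep(FALSE, 1000), truth$series_id)
    cm0 <- confusionMetrics(none, truth)
    expect_equal(cm0$fpr, 0)
    expect_true(is.na(cm0$fdr_observed))

    truth2 <- S4Vectors::DataFrame(series_id = c("a", "b", "c", "d"),
        is_rhythmic = c(TRUE, TRUE, FALSE, FALSE))
    perfect <- stats::setNames(c(TRUE, TRUE, FALSE, FALSE), truth2$series_id)
    cm2 <- confusionMetrics(perfect, truth2)
    expect_equal(cm2$tpr, 1)
    expect_equal(cm2$fpr, 0)
    expect_equal(cm2$fdr_observed, 0)
    expect_error(confusionMetrics(perfect[1:3], truth2), "ids")
})

test_that("confusion counts partition the truth classes", {
    d <- synthesizeDataset(smallConfig(frac_rhythmic = 0.5, amp_min = 2,
        amp_max = 4))
    res <- jtkTest(d)
    cm <- confusionMetrics(classifyHits(res), groundTruth(d))
    expect_identical(cm$tp + cm$fn, cm$n_true_rhythmic)
    expect_identical(cm$fp + cm$tn, cm$n_true_arrhythmic)
})

test_that("fold change over baseline guards division by zero", {
    expect_equal(foldChangeFPR(0.10, 0.0125), 8)
    expect_equal(foldChangeFPR(0.3, 0.3), 1)
    expect_true(is.na(foldChangeFPR(0.3, 0)))
    expect_error(foldChangeFPR(1.3, 0.5))
})

test_that("circular phase error wraps around the cycle", {
    expect_equal(circularPhaseError(23, 1, 24), 2)
    expect_equal(circularPhaseError(6, 6, 24), 0)
    expect_equal(circularPhaseError(20, 6, 24), 10)
})

test_that("parameter recovery summarises detected rhythmic series only", {
    truth <- S4Vectors::DataFrame(series_id = c("s01", "s02", "s03"),
        is_rhythmic = c(TRUE, TRUE, FALSE),
        true_period_h = c(24, 24, NA), true_phase_h = c(1, 6, NA),
        true_amplitude = c(2, 2, NA))
    res <- fakeResults(c(0.001, 0.2, 0.001), ids = truth$series_id)
    res$best_phase_h <- c(23, 5, 0)
    rec <- parameterRecovery(res, truth)
    expect_identical(rec$n, 1L)                    # s02 not a hit, s03 arrhythmic
    expect_equal(rec$phase_error_median_h, 2)      # wrap-around 23 vs 1
    expect_equal(rec$period_error_median_h, 0)
    expect_equal(rec$amp_rel_error_median, 0)

    rec0 <- parameterRecovery(fakeResults(rep(1, 3), truth$series_id), truth)
    expect_identical(rec0$n, 0L)
    expect_true(is.na(rec0$phase_error_median_h))
})

test_that("negative drawn amplitudes are scored against the effective peak", {
    truth <- S4Vectors::DataFrame(series_id = "s01", is_rhythmic = TRUE,
        true_period_h = 24, true_phase_h = 2, true_amplitude = -3)
    res <- fakeResults(0.001, "s01")
    res$best_phase_h <- 14                      # the actual peak of -3*cos
    res$amplitude_est <- 3
    rec <- parameterRecovery(res, truth)
    expect_equal(rec$phase_error_median_h, 0)
    expect_equal(rec$amp_rel_error_median, 0)
})

test_that("the headline summary takes the minimum over nonzero baselines", {
    tab <- data.frame(
        design_label = rep(c("A", "B", "C"), each = 2),
        concat_level = rep(c(0, 1), 3),
        fold_change = c(NA, 9, NA, 8.2, NA, NA))
    mf <- minFoldChangeByLevel(tab)
    expect_equal(mf$min_fold_change, 8.2)
})
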