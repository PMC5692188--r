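test_that("time grids follow the half-open convention", {
    g <- buildTimeGrid(48, 2, 1)
    expect_length(g@times_h, 24)
    expect_length(g@column_labels, 24)
    expect_equal(buildTimeGrid(24, 4)@times_h, c(0, 4, 8, 12, 16, 20))
    expect_length(buildTimeGrid(48, 4, 3)@column_labels, 36)
    expect_equal(g@column_labels[1:2], c("T00_r1", "T02_r1"))
})

test_that("non-divisible duration/interval is rejected naming both values", {
    err <- expect_error(buildTimeGrid(48, 7))
    expect_match(conditionMessage(err), "48")
    expect_match(conditionMessage(err), "7")
    expect_error(buildTimeGrid(-48, 2), "positive")
})

test_that("config invariants are enforced", {
    expect_error(simulationConfig(frac_rhythmic = 1.2), "frac_rhythmic")
    expect_error(simulationConfig(amp_min = 3, amp_max = 1), "amp_min")
    expect_error(simulationConfig(period_min_h = 0), "period")
    expect_error(simulationConfig(noise_sd = -1), "noise_sd")
})

test_that("rhythmic-flag count is exact, never stochastic", {
    for (seed in 1:3) {
        set.seed(seed)
        tr <- sampleGroundTruth(simulationConfig(n_series = 1000,
            frac_rhythmic = 0.5))
        expect_identical(sum(tr$is_rhythmic), 500L)
    }
    set.seed(1)
    tr0 <- sampleGroundTruth(simulationConfig(n_series = 100,
        frac_rhythmic = 0))
    expect_identical(sum(tr0$is_rhythmic), 0L)
    expect_true(all(is.na(tr0$true_period_h)))
})

test_that("truth parameters respect their ranges; degenerate uniform collapses", {
    set.seed(2)
    cfg <- simulationConfig(n_series = 500, frac_rhythmic = 1,
        period_min_h = 20, period_max_h = 28, amp_min = 1, amp_max = 5)
    tr <- sampleGroundTruth(cfg)
    expect_true(all(tr$true_period_h >= 20 & tr$true_period_h <= 28))
    expect_true(all(tr$true_amplitude >= 1 & tr$true_amplitude <= 5))
    expect_true(all(tr$true_phase_h >= 0 & tr$true_phase_h < tr$true_period_h))
    set.seed(3)
    deg <- sampleGroundTruth(simulationConfig(n_series = 10000,
        frac_rhythmic = 1))
    expect_true(all(deg$true_period_h == 24))
})

test_that("identical config and seed reproduce the dataset bit-identically", {
    cfg <- simulationConfig(n_series = 30, seed = 7, outliers_enabled = TRUE)
    d1 <- synthesizeDataset(cfg)
    d2 <- synthesizeDataset(cfg)
    expect_identical(datasetValues(d1), datasetValues(d2))
    expect_identical(as.data.frame(groundTruth(d1)),
        as.data.frame(groundTruth(d2)))
})

test_that("noiseless rhythmic rows equal their closed-form cosine", {
    cfg <- simulationConfig(n_series = 25, frac_rhythmic = 1, noise_sd = 0,
        period_min_h = 20, period_max_h = 28, seed = 11)
    d <- synthesizeDataset(cfg)
    tr <- groundTruth(d)
    t <- rep(sampleTimes(d), each = nReplicates(d))
    for (i in seq_len(nrow(d))) {
        expected <- 10 + tr$true_amplitude[i] *
            cos(2 * pi * (t - tr$true_phase_h[i]) / tr$true_period_h[i])
        expect_equal(unname(datasetValues(d)[i, ]), expected,
            tolerance = 1e-12)
    }
})

test_that("zero noise and zero rhythmic fraction give the bare mesor", {
    d <- synthesizeDataset(simulationConfig(n_series = 10, frac_rhythmic = 0,
        noise_sd = 0, seed = 1))
    expect_true(all(datasetValues(d) == 10))
})

test_that("grand mean of pure noise stays within the CLT bound of the mesor", {
    d <- synthesizeDataset(simulationConfig(n_series = 1000,
        frac_rhythmic = 0, noise_sd = 1, seed = 5))
    n_cells <- length(datasetValues(d))
    expect_lt(abs(mean(datasetValues(d)) - 10), 3 / sqrt(n_cells))
})

test_that("phases are uniform over the cycle (chi-squared at alpha = 0.001)", {
    set.seed(13)
    tr <- sampleGroundTruth(simulationConfig(n_series = 10000,
        frac_rhythmic = 1, period_min_h = 20, period_max_h = 28))
    frac <- tr$true_phase_h / tr$true_period_h
    ct <- table(cut(frac, seq(0, 1, by = 0.1)))
    expect_gt(stats::chisq.test(ct)$p.value, 0.001)
})

test_that("outlier injection is controlled and audited", {
    d <- synthesizeDataset(simulationConfig(n_series = 40, seed = 9))
    set.seed(1)
    expect_identical(datasetValues(injectOutliers(d, 0, 5)),
        datasetValues(d))
    set.seed(1)
    expect_equal(datasetValues(injectOutliers(d, 1, 0)), datasetValues(d))
    expect_error(injectOutliers(d, 0.01, -2), "outlier_magnitude")

    big <- synthesizeDataset(simulationConfig(n_series = 1000, seed = 15))
    set.seed(2)
    out <- injectOutliers(big, 0.01, 5)
    n_alt <- as.integer(sub(".*altered (\\d+) of.*", "\\1",
        utils::tail(provenance(out), 1)))
    n_cells <- length(datasetValues(big))
    expect_lt(abs(n_alt - 0.01 * n_cells),
        3 * sqrt(n_cells * 0.01 * 0.99))
    changed <- datasetValues(out) != datasetValues(big)
    expect_identical(sum(changed), n_alt)
    delta <- (datasetValues(out) - datasetValues(big))[changed]
    expect_true(all(abs(abs(delta) - 5) < 1e-12))
})
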