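mkDataset <- function(...) synthesizeDataset(smallConfig(...))

test_that("a single copy is the identity; tiling duplicates columns exactly", {
    d <- mkDataset()
    expect_identical(datasetValues(duplicateConcatenate(d, 1)),
        datasetValues(d))
    d2 <- duplicateConcatenate(d, 2)
    expect_identical(ncol(d2), 48L)
    expect_identical(datasetValues(d2)[, 1:24], datasetValues(d))
    expect_identical(unname(datasetValues(d2)[, 25:48]),
        unname(datasetValues(d)))
    expect_equal(sampleTimes(d2), seq(0, 94, by = 2))
    expect_match(utils::tail(provenance(d2), 1), "MALPRACTICE")
    expect_error(duplicateConcatenate(d, 0), "total_copies")
})

test_that("duplication adds no information: ground truth is untouched", {
    d <- mkDataset(frac_rhythmic = 0.5)
    d2 <- duplicateConcatenate(d, 3)
    expect_identical(as.data.frame(groundTruth(d2)),
        as.data.frame(groundTruth(d)))
    # the multiset of values per original timepoint is exactly replicated
    expect_identical(unname(datasetValues(d2)[, rep(1:24, 3) == 1]),
        unname(datasetValues(d)[, 1, drop = FALSE][, c(1, 1, 1)]))
})

test_that("down-sampling halves the grid as in the derivation chain", {
    d <- mkDataset()                       # 48 h @ 2 h
    b <- downsampleDataset(d, 2)           # 48 h @ 4 h
    expect_identical(length(sampleTimes(b)), 12L)
    expect_equal(samplingInterval(b), 4)
    expect_equal(gridDuration(b), 48)
    expect_identical(datasetValues(b),
        datasetValues(d)[, seq(1, 24, 2)])
    expect_identical(datasetValues(downsampleDataset(d, 1)),
        datasetValues(d))
    expect_error(downsampleDataset(d, 25), "exceeds")
})

test_that("down-sampling composes: every 2nd twice equals every 4th once", {
    d <- mkDataset()
    a <- downsampleDataset(downsampleDataset(d, 2), 2)
    b <- downsampleDataset(d, 4)
    expect_identical(datasetValues(a), datasetValues(b))
    expect_equal(sampleTimes(a), sampleTimes(b))
})

test_that("truncation keeps the first half-open window", {
    d <- mkDataset()
    b <- downsampleDataset(d, 2)
    cc <- truncateDataset(b, 24)
    expect_identical(length(sampleTimes(cc)), 6L)
    expect_equal(gridDuration(cc), 24)
    expect_identical(datasetValues(truncateDataset(d, 48)),
        datasetValues(d))
    comp <- truncateDataset(downsampleDataset(d, 2), 24)
    expect_identical(ncol(comp), 6L)
    expect_error(truncateDataset(b, 26), "multiple")
    expect_error(truncateDataset(b, 72), "exceeds")
})

test_that("manipulations preserve truth, series count and replicates", {
    d <- synthesizeDataset(smallConfig(replicates = 2, frac_rhythmic = 0.5))
    for (m in list(function(x) duplicateConcatenate(x, 2),
                   function(x) downsampleDataset(x, 2),
                   function(x) truncateDataset(x, 24))) {
        y <- m(d)
        expect_identical(nrow(y), nrow(d))
        expect_identical(as.data.frame(groundTruth(y)),
            as.data.frame(groundTruth(d)))
        expect_identical(nReplicates(y), 2L)
        expect_gt(length(provenance(y)), length(provenance(d)))
    }
})
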