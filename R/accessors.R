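#' Extract the sampling grid of a dataset
#'
#' @param x a \linkS4class{RhythmDataset}.
#' @return a \linkS4class{TimeGrid}.
#' @examples
#' d <- synthesizeDataset(simulationConfig(n_series = 5, seed = 1))
#' timeGrid(d)
#' @export
#' @rdname timeGrid
setMethod("timeGrid", "RhythmDataset", function(x) {
    cd <- SummarizedExperiment::colData(x)
    new("TimeGrid", times_h = unique(cd$time_h),
        replicates = as.integer(max(cd$replicate)),
        column_labels = colnames(x))
})

#' Per-series ground truth of a dataset
#'
#' @param x a \linkS4class{RhythmDataset}.
#' @return a \code{DataFrame} with columns \code{series_id},
#'   \code{is_rhythmic}, \code{true_period_h}, \code{true_phase_h},
#'   \code{true_amplitude}; zero rows when the dataset was imported without
#'   truth columns.
#' @export
#' @rdname groundTruth
setMethod("groundTruth", "RhythmDataset", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"is_rhythmic" %in% colnames(rd))
        return(S4Vectors::DataFrame())
    S4Vectors::DataFrame(series_id = rownames(x), rd)
})

#' Provenance log of a dataset
#'
#' Append-only history of the generator call and of every manipulation
#' applied afterwards.
#'
#' @param x a \linkS4class{RhythmDataset}.
#' @return a character vector, one entry per recorded operation.
#' @export
#' @rdname provenance
setMethod("provenance", "RhythmDataset", function(x)
    S4Vectors::metadata(x)$provenance)

.appendProvenance <- function(x, entry) {
    S4Vectors::metadata(x)$provenance <-
        c(S4Vectors::metadata(x)$provenance, entry)
    x
}

#' Sampling times, interval, duration and replicate count
#'
#' Convenience accessors for the sampling design of a
#' \linkS4class{RhythmDataset} or \linkS4class{TimeGrid}. Durations follow
#' the half-open convention: the duration of a grid sampled at times
#' 0, 2, ..., 46 is 48 h.
#'
#' @param x a \code{RhythmDataset} or \code{TimeGrid}.
#' @return \code{sampleTimes}: the unique timepoints in hours;
#'   \code{samplingInterval}: the spacing in hours; \code{gridDuration}: the
#'   half-open duration in hours; \code{nReplicates}: replicates per
#'   timepoint.
#' @export
sampleTimes <- function(x) {
    if (is(x, "RhythmDataset")) x <- timeGrid(x)
    x@times_h
}

#' @rdname sampleTimes
#' @export
samplingInterval <- function(x) {
    t <- sampleTimes(x)
    if (length(t) < 2L) stop("grid has a single timepoint; interval undefined")
    t[2] - t[1]
}

#' @rdname sampleTimes
#' @export
gridDuration <- function(x) {
    t <- sampleTimes(x)
    if (length(t) < 2L) return(t[1])
    max(t) + (t[2] - t[1]) - min(t)
}

#' @rdname sampleTimes
#' @export
nReplicates <- function(x) {
    if (is(x, "RhythmDataset")) x <- timeGrid(x)
    x@replicates
}

#' Expression value matrix of a dataset
#'
#' @param x a \linkS4class{RhythmDataset}.
#' @return the numeric matrix of the \code{"values"} assay
#'   (series x columns).
#' @export
datasetValues <- function(x) SummarizedExperiment::assay(x, "values")
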