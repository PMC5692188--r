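#' Duplicate-and-concatenate a dataset (malpractice simulation)
#'
#' Tiles the value matrix along the time axis so copy c spans
#' \code{[c*duration, (c+1)*duration)}. This fakes a longer experiment while
#' adding no information: the duplicated samples are not independent, which
#' inflates the significance of rank tests. Provided so the benchmark can
#' quantify exactly how badly. Ground truth and series count are unchanged;
#' the operation is loudly recorded in the provenance log ("the first
#' concatenation" = 2 total copies).
#'
#' @param x a \linkS4class{RhythmDataset}.
#' @param total_copies total number of copies in the output (>= 1; 1 is the
#'   identity).
#' @return the tiled dataset.
#' @examples
#' d <- synthesizeDataset(simulationConfig(n_series = 5, seed = 1))
#' ncol(duplicateConcatenate(d, 2)) == 2 * ncol(d)
#' @rdname duplicateConcatenate
#' @export
setMethod("duplicateConcatenate", "RhythmDataset", function(x, total_copies) {
    total_copies <- as.integer(total_copies)
    if (is.na(total_copies) || total_copies < 1L)
        stop("total_copies must be >= 1")
    if (total_copies == 1L) return(x)
    g <- timeGrid(x)
    dur <- gridDuration(g)
    times <- as.vector(vapply(0:(total_copies - 1L),
        function(cc) g@times_h + cc * dur, numeric(length(g@times_h))))
    newgrid <- new("TimeGrid", times_h = times, replicates = g@replicates,
        column_labels = .columnLabels(times, g@replicates))
    vals <- datasetValues(x)[, rep(seq_len(ncol(x)), total_copies),
        drop = FALSE]
    out <- RhythmDataset(vals, newgrid, .truthOrNull(x),
        provenance = provenance(x),
        noise_sd = S4Vectors::metadata(x)$noise_sd)
    .appendProvenance(out, sprintf(
        "MALPRACTICE SIMULATION duplicate_concatenate: %d total copies (%d columns); samples are no longer independent",
        total_copies, ncol(out)))
})

.truthOrNull <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (ncol(rd) == 0L) NULL else rd
}

#' Down-sample a dataset to a coarser interval
#'
#' Keeps every \code{keep_every}-th timepoint starting at the first, so
#' 48 h @ 2 h with \code{keep_every = 2} becomes 48 h @ 4 h. Replicate
#' structure and ground truth are preserved.
#'
#' @param x a \linkS4class{RhythmDataset}.
#' @param keep_every keep one timepoint in this many (>= 1; 1 is the
#'   identity).
#' @return the down-sampled dataset.
#' @rdname downsampleDataset
#' @export
setMethod("downsampleDataset", "RhythmDataset", function(x, keep_every) {
    keep_every <- as.integer(keep_every)
    if (is.na(keep_every) || keep_every < 1L)
        stop("keep_every must be >= 1")
    g <- timeGrid(x)
    if (keep_every > length(g@times_h))
        stop(sprintf("keep_every (%d) exceeds the %d available timepoints",
            keep_every, length(g@times_h)))
    if (keep_every == 1L) return(x)
    keep_t <- seq(1L, length(g@times_h), by = keep_every)
    keep_cols <- as.vector(vapply(keep_t, function(tt)
        (tt - 1L) * g@replicates + seq_len(g@replicates),
        integer(g@replicates)))
    times <- g@times_h[keep_t]
    newgrid <- new("TimeGrid", times_h = times, replicates = g@replicates,
        column_labels = .columnLabels(times, g@replicates))
    out <- RhythmDataset(datasetValues(x)[, keep_cols, drop = FALSE],
        newgrid, .truthOrNull(x), provenance = provenance(x),
        noise_sd = S4Vectors::metadata(x)$noise_sd)
    .appendProvenance(out, sprintf(
        "downsample: kept every %d-th timepoint; interval %g h -> %g h",
        keep_every, samplingInterval(g), samplingInterval(newgrid)))
})

#' Truncate a dataset to a shorter duration
#'
#' Keeps columns with time < \code{new_duration_h}. Collecting fewer than
#' two complete cycles makes detection sensitive to outliers and inflates
#' false negatives; this operation exists so the benchmark can measure that
#' power loss.
#'
#' @param x a \linkS4class{RhythmDataset}.
#' @param new_duration_h new half-open duration in hours; must be a multiple
#'   of the sampling interval and at most the current duration.
#' @return the truncated dataset.
#' @rdname truncateDataset
#' @export
setMethod("truncateDataset", "RhythmDataset", function(x, new_duration_h) {
    g <- timeGrid(x)
    dur <- gridDuration(g)
    iv <- samplingInterval(g)
    if (new_duration_h > dur + 1e-9)
        stop(sprintf("new duration (%g h) exceeds the current %g h",
            new_duration_h, dur))
    k <- new_duration_h / iv
    if (abs(k - round(k)) > 1e-8)
        stop(sprintf(
            "new duration (%g h) is not a multiple of the %g h interval",
            new_duration_h, iv))
    keep_t <- which(g@times_h < new_duration_h - 1e-9)
    if (!length(keep_t)) stop("truncation would leave no timepoints")
    if (length(keep_t) == length(g@times_h)) return(x)
    keep_cols <- as.vector(vapply(keep_t, function(tt)
        (tt - 1L) * g@replicates + seq_len(g@replicates),
        integer(g@replicates)))
    times <- g@times_h[keep_t]
    newgrid <- new("TimeGrid", times_h = times, replicates = g@replicates,
        column_labels = .columnLabels(times, g@replicates))
    out <- RhythmDataset(datasetValues(x)[, keep_cols, drop = FALSE],
        newgrid, .truthOrNull(x), provenance = provenance(x),
        noise_sd = S4Vectors::metadata(x)$noise_sd)
    .appendProvenance(out, sprintf("truncate: duration %g h -> %g h",
        dur, new_duration_h))
})
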