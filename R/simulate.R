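#' Build an evenly spaced sampling grid
#'
#' Times follow the half-open convention \code{[0, duration_h)}, so a 48 h
#' experiment sampled every 2 h yields 24 timepoints. This makes "every other
#' point of 48 h @ 2 h" exactly 48 h @ 4 h (12 points) and "the first half"
#' exactly 24 h @ 4 h (6 points).
#'
#' @param duration_h total duration in hours (integer multiple of
#'   \code{interval_h}).
#' @param interval_h sampling interval in hours.
#' @param replicates replicates per timepoint.
#' @return a \linkS4class{TimeGrid} with columns labelled
#'   \code{"T<HH>_r<k>"}.
#' @examples
#' buildTimeGrid(48, 2)           # 24 timepoints
#' buildTimeGrid(48, 4, 3)        # 12 timepoints x 3 replicates
#' @export
buildTimeGrid <- function(duration_h, interval_h, replicates = 1) {
    if (duration_h <= 0 || interval_h <= 0)
        stop("duration_h and interval_h must be positive")
    k <- duration_h / interval_h
    if (abs(k - round(k)) > 1e-8)
        stop(sprintf(
            "duration_h (%g) is not an integer multiple of interval_h (%g)",
            duration_h, interval_h))
    times <- seq(0, duration_h - interval_h, by = interval_h)
    new("TimeGrid", times_h = times, replicates = as.integer(replicates),
        column_labels = .columnLabels(times, replicates))
}

.columnLabels <- function(times, replicates) {
    tl <- ifelse(abs(times - round(times)) < 1e-9,
        sprintf("%02d", as.integer(round(times))),
        formatC(times, format = "g"))
    as.vector(t(outer(tl, seq_len(replicates),
        function(a, b) sprintf("T%s_r%d", a, b))))
}

#' Construct a rhythm dataset from its parts
#'
#' Used by the simulator and the CSV reader; end users normally call
#' \code{\link{synthesizeDataset}} or \code{\link{readDatasetCSV}} instead.
#'
#' @param values numeric matrix, series x (timepoints x replicates).
#' @param grid a \linkS4class{TimeGrid} matching the columns of
#'   \code{values}.
#' @param truth \code{NULL}, or a data.frame/DataFrame with columns
#'   \code{is_rhythmic}, \code{true_period_h}, \code{true_phase_h},
#'   \code{true_amplitude} (one row per series).
#' @param provenance character log carried over into the new object.
#' @param noise_sd noise level used for outlier scaling (NA when unknown).
#' @return a \linkS4class{RhythmDataset}.
#' @export
RhythmDataset <- function(values, grid, truth = NULL,
        provenance = character(), noise_sd = NA_real_) {
    values <- as.matrix(values)
    if (ncol(values) != length(grid@column_labels))
        stop(sprintf("value matrix has %d columns but the grid defines %d",
            ncol(values), length(grid@column_labels)))
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("series_%04d", seq_len(nrow(values)))
    colnames(values) <- grid@column_labels
    cd <- S4Vectors::DataFrame(
        time_h = rep(grid@times_h, each = grid@replicates),
        replicate = rep(seq_len(grid@replicates), length(grid@times_h)),
        row.names = grid@column_labels)
    rd <- if (is.null(truth)) S4Vectors::DataFrame(row.names = rownames(values))
        else S4Vectors::DataFrame(truth, row.names = rownames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = values), colData = cd, rowData = rd,
        metadata = list(provenance = provenance, noise_sd = noise_sd))
    new("RhythmDataset", se)
}

#' Draw per-series ground truth
#'
#' Exactly \code{round(frac_rhythmic * n_series)} series are flagged
#' rhythmic (the count is deterministic, never binomial). Each rhythmic
#' series draws period ~ U[period_min_h, period_max_h], amplitude ~
#' U[amp_min, amp_max] (signed) and phase ~ U[0, period). Arrhythmic series
#' carry NA parameters. Consumes the current RNG stream; seed via
#' \code{set.seed} or through \code{\link{synthesizeDataset}}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \code{DataFrame} with one row per series.
#' @examples
#' set.seed(1)
#' sampleGroundTruth(simulationConfig(n_series = 4, frac_rhythmic = 0.5))
#' @export
sampleGroundTruth <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    n <- config@n_series
    n_r <- as.integer(round(config@frac_rhythmic * n))
    is_r <- c(rep(TRUE, n_r), rep(FALSE, n - n_r))
    period <- phase <- amp <- rep(NA_real_, n)
    if (n_r > 0) {
        period[seq_len(n_r)] <- stats::runif(n_r, config@period_min_h,
            config@period_max_h)
        amp[seq_len(n_r)] <- stats::runif(n_r, config@amp_min, config@amp_max)
        phase[seq_len(n_r)] <- stats::runif(n_r, 0, period[seq_len(n_r)])
    }
    S4Vectors::DataFrame(is_rhythmic = is_r, true_period_h = period,
        true_phase_h = phase, true_amplitude = amp,
        row.names = sprintf("series_%04d", seq_len(n)))
}

.withSeed <- function(seed, expr) {
    if (is.na(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Generate a synthetic rhythm dataset
#'
#' Rhythmic series follow
#' \deqn{y(t, r) = \mathrm{mesor} + A \cos(2\pi (t - \phi)/T) + \epsilon,}
#' arrhythmic series are mesor + noise, with
#' \eqn{\epsilon \sim N(0, \mathrm{noise\_sd}^2)} drawn independently per
#' (timepoint, replicate) cell. Ground truth is drawn first, then the noise,
#' from a single seeded stream, so a given config + seed reproduces the
#' dataset bit-identically. Outlier spikes are applied afterwards when
#' enabled.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{RhythmDataset} with ground truth in
#'   \code{\link{groundTruth}} and the generator call logged in
#'   \code{\link{provenance}}.
#' @examples
#' d <- synthesizeDataset(simulationConfig(n_series = 10, seed = 1))
#' d
#' @export
synthesizeDataset <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    .withSeed(config@seed, {
        grid <- buildTimeGrid(config@duration_h, config@interval_h,
            config@replicates)
        truth <- sampleGroundTruth(config)
        tcol <- rep(grid@times_h, each = config@replicates)
        n <- config@n_series
        vals <- matrix(config@baseline, n, length(tcol))
        r_idx <- which(truth$is_rhythmic)
        if (length(r_idx)) {
            A <- truth$true_amplitude[r_idx]
            Tt <- truth$true_period_h[r_idx]
            ph <- truth$true_phase_h[r_idx]
            vals[r_idx, ] <- vals[r_idx, , drop = FALSE] +
                A * cos(outer(2 * pi / Tt, tcol) -
                        (2 * pi * ph / Tt))
        }
        if (config@noise_sd > 0)
            vals <- vals + matrix(stats::rnorm(n * length(tcol),
                sd = config@noise_sd), n)
        rownames(vals) <- rownames(truth)
        prov <- sprintf(paste0(
            "synthesize_dataset: %g h @ %g h x %d rep, n_series=%d, ",
            "frac_rhythmic=%g, period=[%g,%g], amplitude=[%g,%g], ",
            "mesor=%g, noise_sd=%g, seed=%s"),
            config@duration_h, config@interval_h, config@replicates,
            n, config@frac_rhythmic, config@period_min_h, config@period_max_h,
            config@amp_min, config@amp_max, config@baseline, config@noise_sd,
            ifelse(is.na(config@seed), "none", config@seed))
        x <- RhythmDataset(vals, grid, truth, provenance = prov,
            noise_sd = config@noise_sd)
        if (config@outliers_enabled)
            x <- injectOutliers(x, config@outlier_rate,
                config@outlier_magnitude)
        x
    })
}

#' Inject outlier spikes into a dataset
#'
#' Each cell is independently replaced, with probability
#' \code{outlier_rate}, by \code{value + s * outlier_magnitude * noise_sd}
#' with sign \code{s} equiprobably -1 or +1. The count of altered cells is
#' recorded in the provenance log. Ground truth is unchanged.
#'
#' @param x a \linkS4class{RhythmDataset}.
#' @param outlier_rate per-cell replacement probability in [0, 1].
#' @param outlier_magnitude spike size in multiples of \code{noise_sd}.
#' @param noise_sd noise scale; defaults to the value recorded by the
#'   generator.
#' @return the modified dataset.
#' @export
injectOutliers <- function(x, outlier_rate = 0.01, outlier_magnitude = 5,
        noise_sd = NULL) {
    stopifnot(is(x, "RhythmDataset"))
    if (outlier_rate < 0 || outlier_rate > 1)
        stop("outlier_rate must lie in [0, 1]")
    if (outlier_magnitude < 0)
        stop("outlier_magnitude must be >= 0")
    if (is.null(noise_sd)) noise_sd <- S4Vectors::metadata(x)$noise_sd
    if (is.null(noise_sd) || is.na(noise_sd))
        stop("noise_sd unknown for this dataset; pass it explicitly")
    v <- datasetValues(x)
    hit <- matrix(stats::runif(length(v)) < outlier_rate, nrow(v))
    sgn <- matrix(sign(stats::runif(length(v)) - 0.5), nrow(v))
    sgn[sgn == 0] <- 1
    v[hit] <- v[hit] + sgn[hit] * outlier_magnitude * noise_sd
    SummarizedExperiment::assay(x, "values") <- v
    .appendProvenance(x, sprintf(
        "inject_outliers: rate=%g, magnitude=%g x noise_sd, altered %d of %d cells",
        outlier_rate, outlier_magnitude, sum(hit), length(hit)))
}
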