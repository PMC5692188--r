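#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-` SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#'   `rowData<-`
NULL

#' Simulation configuration for synthetic rhythm datasets
#'
#' Holds every user-settable option of the synthetic time-series generator:
#' the sampling design (duration, interval, replicates), the population of
#' series (total number, fraction genuinely rhythmic), the rhythm parameter
#' ranges (signed amplitude, period in hours), the mesor (baseline) and the
#' Gaussian noise level, plus optional outlier spikes and a seed.
#'
#' Phases of rhythmic series are drawn uniformly over one full period; period
#' and amplitude are drawn uniformly within their ranges. Amplitudes may be
#' negative (a negative amplitude is equivalent to a half-period phase shift);
#' the signed draw is stored in the ground truth.
#'
#' @slot duration_h total experiment duration in hours.
#' @slot interval_h sampling interval in hours; must divide \code{duration_h}.
#' @slot n_series number of time series (features).
#' @slot replicates independent replicates per timepoint.
#' @slot frac_rhythmic fraction of series that are genuinely rhythmic.
#' @slot amp_min,amp_max signed amplitude range (arbitrary expression units).
#' @slot period_min_h,period_max_h period range in hours.
#' @slot baseline mesor, the rhythm-adjusted mean level.
#' @slot noise_sd standard deviation of the additive Gaussian noise.
#' @slot outliers_enabled whether outlier spikes are injected.
#' @slot outlier_rate per-cell probability of an outlier spike.
#' @slot outlier_magnitude spike size in multiples of \code{noise_sd}.
#' @slot seed integer seed (NA for unseeded).
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        duration_h = "numeric", interval_h = "numeric",
        n_series = "integer", replicates = "integer",
        frac_rhythmic = "numeric",
        amp_min = "numeric", amp_max = "numeric",
        period_min_h = "numeric", period_max_h = "numeric",
        baseline = "numeric", noise_sd = "numeric",
        outliers_enabled = "logical", outlier_rate = "numeric",
        outlier_magnitude = "numeric", seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@duration_h <= 0) msg <- c(msg, "duration_h must be > 0")
    if (object@interval_h <= 0) msg <- c(msg, "interval_h must be > 0")
    k <- object@duration_h / object@interval_h
    if (object@interval_h > 0 && abs(k - round(k)) > 1e-8)
        msg <- c(msg, sprintf(
            "duration_h (%g) must be an integer multiple of interval_h (%g)",
            object@duration_h, object@interval_h))
    if (object@n_series < 1L) msg <- c(msg, "n_series must be >= 1")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (object@frac_rhythmic < 0 || object@frac_rhythmic > 1)
        msg <- c(msg, "frac_rhythmic must lie in [0, 1]")
    if (object@amp_min > object@amp_max)
        msg <- c(msg, "amp_min must be <= amp_max")
    if (object@period_min_h <= 0 || object@period_min_h > object@period_max_h)
        msg <- c(msg, "need 0 < period_min_h <= period_max_h")
    if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
    if (object@outlier_rate < 0 || object@outlier_rate > 1)
        msg <- c(msg, "outlier_rate must lie in [0, 1]")
    if (object@outlier_magnitude < 0)
        msg <- c(msg, "outlier_magnitude must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param duration_h,interval_h,n_series,replicates,frac_rhythmic,amp_min,amp_max,period_min_h,period_max_h,baseline,noise_sd,outliers_enabled,outlier_rate,outlier_magnitude,seed
#'   see the corresponding slots.
#' @return \code{simulationConfig} returns a validated
#'   \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(duration_h = 48, interval_h = 2, n_series = 100)
#' cfg
#' @export
simulationConfig <- function(duration_h = 48, interval_h = 2,
        n_series = 1000, replicates = 1, frac_rhythmic = 0.5,
        amp_min = -7, amp_max = 7, period_min_h = 24, period_max_h = 24,
        baseline = 10, noise_sd = 1, outliers_enabled = FALSE,
        outlier_rate = 0.01, outlier_magnitude = 5, seed = NA) {
    new("SimulationConfig",
        duration_h = as.numeric(duration_h),
        interval_h = as.numeric(interval_h),
        n_series = as.integer(n_series),
        replicates = as.integer(replicates),
        frac_rhythmic = as.numeric(frac_rhythmic),
        amp_min = as.numeric(amp_min), amp_max = as.numeric(amp_max),
        period_min_h = as.numeric(period_min_h),
        period_max_h = as.numeric(period_max_h),
        baseline = as.numeric(baseline), noise_sd = as.numeric(noise_sd),
        outliers_enabled = isTRUE(outliers_enabled),
        outlier_rate = as.numeric(outlier_rate),
        outlier_magnitude = as.numeric(outlier_magnitude),
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  design   : %g h every %g h, %d replicate(s) -> %d columns\n",
        object@duration_h, object@interval_h, object@replicates,
        as.integer(object@duration_h / object@interval_h) * object@replicates))
    cat(sprintf("  series   : %d (%.0f%% rhythmic)\n",
        object@n_series, 100 * object@frac_rhythmic))
    cat(sprintf("  rhythm   : period [%g, %g] h, amplitude [%g, %g]\n",
        object@period_min_h, object@period_max_h,
        object@amp_min, object@amp_max))
    cat(sprintf("  noise    : mesor %g, sd %g%s\n", object@baseline,
        object@noise_sd,
        if (object@outliers_enabled)
            sprintf(", outliers rate %g x %g sd", object@outlier_rate,
                object@outlier_magnitude) else ""))
    if (!is.na(object@seed)) cat(sprintf("  seed     : %d\n", object@seed))
})

#' Evenly spaced sampling grid with replicate structure
#'
#' Sampling times follow the half-open convention \code{[0, duration)}:
#' a 48 h experiment sampled every 2 h has 24 timepoints (0, 2, ..., 46).
#' Each timepoint carries \code{replicates} columns labelled
#' \code{"T<HH>_r<k>"}.
#'
#' @slot times_h strictly increasing, evenly spaced sampling times (hours).
#' @slot replicates replicates per timepoint.
#' @slot column_labels one label per (time, replicate) column.
#' @exportClass TimeGrid
setClass("TimeGrid",
    representation(times_h = "numeric", replicates = "integer",
        column_labels = "character"))

setValidity("TimeGrid", function(object) {
    t <- object@times_h
    msg <- character()
    if (length(t) < 1L) msg <- c(msg, "at least one sampling time required")
    if (length(t) > 1L) {
        d <- diff(t)
        if (any(d <= 0)) msg <- c(msg, "times_h must be strictly increasing")
        if (max(d) - min(d) > 1e-8 * max(d))
            msg <- c(msg, "times_h must be evenly spaced")
    }
    if (length(object@column_labels) != length(t) * object@replicates)
        msg <- c(msg, "number of column labels must equal timepoints x replicates")
    if (length(msg)) msg else TRUE
})

#' Cosine reference template on a sampling grid
#'
#' The template value of column (t, r) is \code{cos(2*pi*(t - phase)/period)};
#' columns with equal template value (including all replicates of one
#' timepoint, and timepoints one period apart) form a tie group, and groups
#' are ranked by template value.
#'
#' @slot period_h,phase_h template period and phase (hours).
#' @slot template_values cosine value per column.
#' @slot tie_groups integer group rank per column (1 = lowest template value).
#' @slot group_sizes size of each tie group, in rank order.
#' @exportClass ReferenceTemplate
setClass("ReferenceTemplate",
    representation(period_h = "numeric", phase_h = "numeric",
        template_values = "numeric", tie_groups = "integer",
        group_sizes = "integer"))

setValidity("ReferenceTemplate", function(object) {
    msg <- character()
    if (sum(object@group_sizes) != length(object@template_values))
        msg <- c(msg, "tie-group sizes must sum to the number of columns")
    if (!identical(as.integer(table(object@tie_groups)),
                   object@group_sizes))
        msg <- c(msg, "tie_groups inconsistent with group_sizes")
    if (length(msg)) msg else TRUE
})

#' Exact null distribution of the tie-aware Kendall S statistic
#'
#' Distribution of \eqn{S} under the null that all orderings of distinct data
#' values are equally likely, for a template with the given tie-group sizes.
#' Computed by generating-function convolution over tie groups
#' (the Jonckheere-Terpstra/Kendall construction); symmetric about 0.
#'
#' @slot support attainable values of S (decreasing).
#' @slot probabilities probability mass per support value.
#' @slot tie_signature the sorted tie-group-size multiset this null is for.
#' @exportClass NullDistribution
setClass("NullDistribution",
    representation(support = "integer", probabilities = "numeric",
        tie_signature = "integer"))

setValidity("NullDistribution", function(object) {
    msg <- character()
    if (abs(sum(object@probabilities) - 1) > 1e-12)
        msg <- c(msg, "probabilities must sum to 1 (within 1e-12)")
    if (max(abs(object@probabilities - rev(object@probabilities))) > 1e-12)
        msg <- c(msg, "distribution must be symmetric about 0")
    if (!identical(object@support, rev(-object@support)))
        msg <- c(msg, "support must be symmetric about 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "NullDistribution", function(object) {
    cat(sprintf(
        "NullDistribution: S over [%d, %d] (%d values), tie signature (%s)\n",
        min(object@support), max(object@support), length(object@support),
        paste(object@tie_signature, collapse = ",")))
})

#' Synthetic (or imported) rhythm dataset
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"values"}
#' holds one expression-like time series per row. Column data carry the
#' sampling grid (\code{time_h}, \code{replicate}); row data carry the
#' per-series ground truth (\code{is_rhythmic}, \code{true_period_h},
#' \code{true_phase_h}, \code{true_amplitude}; all-NA for arrhythmic series
#' and for imported data without truth). The append-only provenance log in
#' \code{metadata(x)$provenance} records every manipulation applied.
#'
#' @exportClass RhythmDataset
setClass("RhythmDataset", contains = "SummarizedExperiment")

setValidity("RhythmDataset", function(object) {
    msg <- character()
    cd <- colData(object)
    if (!all(c("time_h", "replicate") %in% colnames(cd)))
        return("colData must contain 'time_h' and 'replicate'")
    t <- cd$time_h
    if (is.unsorted(t)) msg <- c(msg, "columns must be ordered by time")
    rt <- table(t)
    if (length(unique(rt)) > 1L)
        msg <- c(msg, "every timepoint must carry the same number of replicates")
    rd <- rowData(object)
    if ("is_rhythmic" %in% colnames(rd)) {
        ir <- rd$is_rhythmic
        bad <- which(ir & (is.na(rd$true_period_h) | is.na(rd$true_phase_h) |
                           is.na(rd$true_amplitude)))
        if (length(bad))
            msg <- c(msg, "rhythmic series must carry period/phase/amplitude truth")
    }
    if (!is.character(metadata(object)$provenance))
        msg <- c(msg, "metadata must contain a character provenance log")
    if (length(msg)) msg else TRUE
})

setMethod("show", "RhythmDataset", function(object) {
    callNextMethod()
    g <- timeGrid(object)
    cat(sprintf("sampling: %d timepoints every %g h x %d replicate(s), span [%g, %g) h\n",
        length(g@times_h), samplingInterval(object), g@replicates,
        min(g@times_h), gridDuration(object)))
    prov <- provenance(object)
    if (length(prov))
        cat("provenance:\n", paste0("  ", prov, collapse = "\n"), "\n", sep = "")
})
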