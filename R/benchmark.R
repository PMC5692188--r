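#' Flag hits at a significance threshold
#'
#' A series is a hit when its chosen p-value is strictly below the
#' threshold (so p = 0.05 at threshold 0.05 is not a hit).
#'
#' @param results a result table from \code{\link{jtkTest}}.
#' @param threshold significance threshold in (0, 1).
#' @param which_p one of \code{"p_adj"} (the within-series adjusted p,
#'   appropriate for the false-positive benchmark), \code{"p_raw"} or
#'   \code{"q_bh"}.
#' @return named logical vector, one flag per series.
#' @export
classifyHits <- function(results, threshold = 0.05,
        which_p = c("p_adj", "p_raw", "q_bh")) {
    which_p <- match.arg(which_p)
    if (threshold <= 0 || threshold >= 1)
        stop("threshold must lie in (0, 1)")
    stats::setNames(results[[which_p]] < threshold, results$series_id)
}

#' Confusion counts and rates against ground truth
#'
#' @param hits named logical hit flags (from \code{\link{classifyHits}}).
#' @param truth ground truth (from \code{\link{groundTruth}}) with
#'   \code{series_id} and \code{is_rhythmic}.
#' @return a list with \code{n_true_rhythmic}, \code{n_true_arrhythmic},
#'   \code{tp}, \code{fp}, \code{tn}, \code{fn}, \code{fpr}, \code{tpr} and
#'   \code{fdr_observed} (NA when there are no hits); rates are NA when
#'   their denominator is 0.
#' @export
confusionMetrics <- function(hits, truth) {
    ids <- truth$series_id
    if (!setequal(names(hits), ids))
        stop("series ids of hits and truth do not match")
    hits <- hits[match(ids, names(hits))]
    rhyth <- truth$is_rhythmic
    tp <- sum(hits & rhyth); fp <- sum(hits & !rhyth)
    fn <- sum(!hits & rhyth); tn <- sum(!hits & !rhyth)
    n_r <- sum(rhyth); n_a <- sum(!rhyth)
    list(n_true_rhythmic = n_r, n_true_arrhythmic = n_a,
        tp = tp, fp = fp, tn = tn, fn = fn,
        fpr = if (n_a > 0) fp / n_a else NA_real_,
        tpr = if (n_r > 0) tp / n_r else NA_real_,
        fdr_observed = if (tp + fp > 0) fp / (tp + fp) else NA_real_)
}

#' Fold change of a false-positive rate over its baseline
#'
#' @param fpr_manipulated,fpr_baseline rates in [0, 1].
#' @return the ratio, or NA when the baseline is 0 (designs with a zero
#'   baseline are excluded from cross-design minima).
#' @export
foldChangeFPR <- function(fpr_manipulated, fpr_baseline) {
    stopifnot(all(fpr_manipulated >= 0 & fpr_manipulated <= 1),
        all(fpr_baseline >= 0 & fpr_baseline <= 1))
    ifelse(fpr_baseline > 0, fpr_manipulated / fpr_baseline, NA_real_)
}

#' Parameter-recovery statistics on detected rhythmic series
#'
#' Restricted to truly rhythmic series that were detected as hits. The
#' circular phase error is \code{min(|d|, T - |d|)} on a cycle of the true
#' period T, measured against the waveform's effective peak phase (for a
#' negative drawn amplitude the peak sits half a period from the stored
#' phase). Amplitude error is relative to |true amplitude|.
#'
#' @param results a result table from \code{\link{jtkTest}}.
#' @param truth ground truth with per-series rhythm parameters.
#' @param hits optional logical flags; default
#'   \code{classifyHits(results)}.
#' @return a list with \code{n} (series summarised) and median/mean of the
#'   circular phase error (h), absolute period error (h) and relative
#'   amplitude error; all-NA summaries when no rhythmic series was detected.
#' @export
parameterRecovery <- function(results, truth, hits = NULL) {
    if (is.null(hits)) hits <- classifyHits(results)
    ids <- truth$series_id[truth$is_rhythmic &
        hits[match(truth$series_id, names(hits))]]
    idx_r <- match(ids, results$series_id)
    idx_t <- match(ids, truth$series_id)
    if (!length(ids))
        return(list(n = 0L, phase_error_median_h = NA_real_,
            phase_error_mean_h = NA_real_, period_error_median_h = NA_real_,
            period_error_mean_h = NA_real_, amp_rel_error_median = NA_real_,
            amp_rel_error_mean = NA_real_))
    Tt <- truth$true_period_h[idx_t]
    peak <- ifelse(truth$true_amplitude[idx_t] < 0,
        (truth$true_phase_h[idx_t] + Tt / 2) %% Tt,
        truth$true_phase_h[idx_t])
    perr <- circularPhaseError(results$best_phase_h[idx_r], peak, Tt)
    terr <- abs(results$best_period_h[idx_r] - Tt)
    aerr <- abs(results$amplitude_est[idx_r] -
        abs(truth$true_amplitude[idx_t])) / abs(truth$true_amplitude[idx_t])
    list(n = length(ids),
        phase_error_median_h = stats::median(perr),
        phase_error_mean_h = mean(perr),
        period_error_median_h = stats::median(terr),
        period_error_mean_h = mean(terr),
        amp_rel_error_median = stats::median(aerr),
        amp_rel_error_mean = mean(aerr))
}

#' Circular (wrap-around) distance between phases
#'
#' @param a,b phases in hours.
#' @param period_h cycle length.
#' @return \code{min(|a - b| mod T, T - |a - b| mod T)}.
#' @examples
#' circularPhaseError(23, 1, 24)  # 2
#' @export
circularPhaseError <- function(a, b, period_h) {
    d <- abs(a - b) %% period_h
    pmin(d, period_h - d)
}

#' False-positive inflation under duplication-and-concatenation
#'
#' Simulates 1000 (by default) arrhythmic series of pure Gaussian noise on a
#' 48 h @ 2 h grid (design A), derives design B (48 h @ 4 h) by keeping
#' every other timepoint and design C (24 h @ 4 h) as the first half of B,
#' then tiles each design to 1-4 total copies (concatenation levels 0-3),
#' runs the JTK-style test with a 24 h period, and tabulates the fraction of
#' series called hits at adjusted p below the threshold. With honest,
#' un-concatenated data the hit fractions stay below 2%; every
#' concatenation level inflates them many-fold.
#'
#' @param n_series number of noise series (>= 100).
#' @param noise_sd noise standard deviation (the rank test is scale
#'   invariant, so this does not affect the rates).
#' @param seed integer seed for the simulated noise.
#' @param threshold hit threshold on the adjusted p.
#' @return a data.frame with \code{design_label}, \code{concat_level}
#'   (0 = original data), \code{n_timepoints}, \code{n_columns},
#'   \code{n_hits}, \code{fpr} and \code{fold_change} relative to the
#'   design's level-0 rate (NA at level 0 and for zero baselines).
#' @examples
#' \donttest{
#' tab <- runFig2Experiment(n_series = 200, seed = 1)
#' subset(tab, concat_level == 0)
#' }
#' @export
runFig2Experiment <- function(n_series = 1000, noise_sd = 1, seed = NA,
        threshold = 0.05) {
    if (n_series < 100) stop("n_series must be >= 100")
    cfg <- simulationConfig(duration_h = 48, interval_h = 2,
        n_series = n_series, frac_rhythmic = 0, noise_sd = noise_sd,
        seed = seed)
    designs <- list()
    designs[["48h@2h"]] <- synthesizeDataset(cfg)
    designs[["48h@4h"]] <- downsampleDataset(designs[["48h@2h"]], 2)
    designs[["24h@4h"]] <- truncateDataset(designs[["48h@4h"]], 24)
    rows <- list()
    for (lab in names(designs)) {
        base_fpr <- NA_real_
        for (L in 0:3) {
            d <- duplicateConcatenate(designs[[lab]], L + 1L)
            res <- jtkTest(d, period_set = 24)
            nh <- sum(classifyHits(res, threshold, "p_adj"))
            fpr <- nh / n_series
            if (L == 0) base_fpr <- fpr
            rows[[length(rows) + 1L]] <- data.frame(
                design_label = lab, concat_level = L,
                n_timepoints = length(sampleTimes(d)), n_columns = ncol(d),
                n_hits = nh, fpr = fpr,
                fold_change = if (L == 0) NA_real_
                    else foldChangeFPR(fpr, base_fpr))
        }
    }
    do.call(rbind, rows)
}

#' Minimum cross-design fold change at each concatenation level
#'
#' Headline summary of \code{\link{runFig2Experiment}}: for each
#' concatenation level, the smallest false-positive-rate fold change across
#' the designs whose un-concatenated baseline rate is nonzero.
#'
#' @param fig2_table output of \code{\link{runFig2Experiment}}.
#' @return a data.frame with \code{concat_level} and \code{min_fold_change}.
#' @export
minFoldChangeByLevel <- function(fig2_table) {
    lv <- sort(unique(fig2_table$concat_level))
    lv <- lv[lv > 0]
    data.frame(concat_level = lv, min_fold_change = vapply(lv, function(L) {
        f <- fig2_table$fold_change[fig2_table$concat_level == L]
        f <- f[!is.na(f)]
        if (length(f)) min(f) else NA_real_
    }, numeric(1)))
}
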