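#' Write a dataset to CSV (truth + values dialect)
#'
#' One row per series with header columns \code{series_id, is_rhythmic,
#' true_period, true_phase, true_amplitude} followed by one value column per
#' (time, replicate) labelled \code{"T<HH>_r<k>"}; undefined truth fields
#' are written as NA. Time labels carry absolute hours, so concatenated
#' copies are visible in the file (columns continue T48, T50, ...). Values
#' keep full double precision.
#'
#' @param x a \linkS4class{RhythmDataset}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDatasetCSV <- function(x, path) {
    tr <- groundTruth(x)
    v <- datasetValues(x)
    df <- if (nrow(tr)) data.frame(
            series_id = tr$series_id,
            is_rhythmic = tr$is_rhythmic,
            true_period = tr$true_period_h,
            true_phase = tr$true_phase_h,
            true_amplitude = tr$true_amplitude,
            check.names = FALSE)
        else data.frame(series_id = rownames(x))
    df <- cbind(df, as.data.frame(format(v, digits = 15, trim = TRUE,
        scientific = FALSE)))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

.parseColumnLabel <- function(labels) {
    m <- regmatches(labels, regexec("^T([0-9]+\\.?[0-9]*)_r([0-9]+)$", labels))
    bad <- which(lengths(m) != 3L)
    if (length(bad))
        stop(sprintf("malformed time-column label(s): %s",
            paste(labels[bad], collapse = ", ")))
    data.frame(time_h = as.numeric(vapply(m, `[`, "", 2L)),
        replicate = as.integer(vapply(m, `[`, "", 3L)))
}

#' Read a dataset CSV
#'
#' Accepts the dialect written by \code{\link{writeDatasetCSV}}. Files
#' without the five truth columns (external experimental data) are accepted
#' as a dataset with empty ground truth and flagged "external" in the
#' provenance. Column labels must describe strictly increasing times with a
#' constant replicate count; violations are rejected with coordinates.
#'
#' @param path CSV file path.
#' @return a \linkS4class{RhythmDataset}.
#' @export
readDatasetCSV <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE,
        stringsAsFactors = FALSE)
    truth_cols <- c("series_id", "is_rhythmic", "true_period", "true_phase",
        "true_amplitude")
    has_truth <- all(truth_cols %in% colnames(df))
    id_col <- if ("series_id" %in% colnames(df)) "series_id"
        else colnames(df)[1L]
    meta_cols <- if (has_truth) truth_cols else id_col
    val_cols <- setdiff(colnames(df), meta_cols)
    lab <- .parseColumnLabel(val_cols)
    tp <- unique(lab$time_h)
    if (is.unsorted(tp, strictly = TRUE))
        stop("time columns are not in strictly increasing time order")
    reps <- table(lab$time_h)
    if (length(unique(as.integer(reps))) != 1L)
        stop(sprintf("unequal replicate counts across timepoints (%s)",
            paste(sprintf("t=%g:%d", as.numeric(names(reps)),
                as.integer(reps)), collapse = ", ")))
    canon <- rep(tp, each = as.integer(reps[1L]))
    if (!isTRUE(all.equal(lab$time_h, canon)))
        stop("value columns must be grouped by time with replicates adjacent")
    v <- as.matrix(df[, val_cols, drop = FALSE])
    if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(apply(df[, val_cols], 2,
            as.numeric))) & !is.na(df[, val_cols]), arr.ind = TRUE)
        stop(sprintf("non-numeric value cell(s) at row %s, column %s",
            paste(bad[, 1], collapse = ","),
            paste(val_cols[bad[, 2]], collapse = ",")))
    }
    rownames(v) <- as.character(df[[id_col]])
    grid <- new("TimeGrid", times_h = tp,
        replicates = as.integer(reps[1L]), column_labels = val_cols)
    truth <- NULL
    prov <- sprintf("read_dataset_csv: %s (%d series, %d columns)%s",
        basename(path), nrow(v), ncol(v),
        if (has_truth) "" else "; external data without ground truth")
    if (has_truth)
        truth <- S4Vectors::DataFrame(
            is_rhythmic = as.logical(df$is_rhythmic),
            true_period_h = as.numeric(df$true_period),
            true_phase_h = as.numeric(df$true_phase),
            true_amplitude = as.numeric(df$true_amplitude))
    RhythmDataset(v, grid, truth, provenance = prov)
}

#' Write a detection result table to CSV
#'
#' One row per series: \code{series_id, p_raw, p_adj, q_bh, best_period,
#' best_phase, mesor, amplitude, fold_change, r_squared}; NA marks
#' undefined estimates.
#'
#' @param results a result table from \code{\link{jtkTest}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeResultsCSV <- function(results, path) {
    df <- data.frame(series_id = results$series_id,
        p_raw = results$p_raw, p_adj = results$p_adj, q_bh = results$q_bh,
        best_period = results$best_period_h,
        best_phase = results$best_phase_h, mesor = results$mesor_est,
        amplitude = results$amplitude_est,
        fold_change = results$fold_change_est,
        r_squared = results$r_squared)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a simulation configuration file
#'
#' YAML (or flat \code{key: value}) file whose keys mirror the
#' \linkS4class{SimulationConfig} fields exactly; omitted keys keep their
#' defaults.
#'
#' @param path config file path.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(simulationConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop(sprintf("unknown config key(s): %s",
            paste(unknown, collapse = ", ")))
    do.call(simulationConfig, vals)
}

#' Run manifest for reproducible outputs
#'
#' Every file the CLI writes is paired with a JSON manifest recording the
#' configuration, seed, package version and ordered operation log, enough to
#' regenerate the output bit-identically.
#'
#' @param config a \linkS4class{SimulationConfig} or NULL.
#' @param seed the seed used.
#' @param operations ordered provenance entries.
#' @return \code{runManifest}: a list; \code{writeRunManifest}: the path,
#'   invisibly.
#' @export
runManifest <- function(config = NULL, seed = NA, operations = character()) {
    cfg <- NULL
    if (!is.null(config)) {
        sn <- slotNames(config)
        cfg <- stats::setNames(lapply(sn, function(s) slot(config, s)), sn)
    }
    list(tool = "circaBench",
        version = as.character(utils::packageVersion("circaBench")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = seed, config = cfg, operations = operations)
}

#' @rdname runManifest
#' @param manifest a list from \code{runManifest}.
#' @param path output JSON path.
#' @export
writeRunManifest <- function(manifest, path) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
        digits = NA, null = "null")
    invisible(path)
}
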