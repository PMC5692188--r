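#' Cosine reference template with tie groups
#'
#' Evaluates \code{cos(2*pi*(t - phase_h)/period_h)} at every column of the
#' grid and partitions columns into tie groups of equal template value.
#' Replicate columns of one timepoint always share a group, as do timepoints
#' whose times are symmetric about the peak or one period apart, so a 48 h
#' grid with a 24 h template ties every column with at least one other.
#' Groups are ranked by template value (rank 1 = trough).
#'
#' @param grid a \linkS4class{TimeGrid}.
#' @param period_h template period in hours (> 0).
#' @param phase_h template peak phase in hours.
#' @return a \linkS4class{ReferenceTemplate}.
#' @examples
#' g <- buildTimeGrid(24, 2)
#' referenceTemplate(g, 24, 0)
#' @export
referenceTemplate <- function(grid, period_h, phase_h = 0) {
    stopifnot(is(grid, "TimeGrid"))
    if (period_h <= 0) stop("period_h must be > 0")
    tv <- cos(2 * pi * (rep(grid@times_h, each = grid@replicates) - phase_h) /
        period_h)
    key <- round(tv, 9)  # collapse floating-point ties
    lev <- sort(unique(key))
    groups <- match(key, lev)
    new("ReferenceTemplate", period_h = period_h, phase_h = phase_h,
        template_values = tv, tie_groups = as.integer(groups),
        group_sizes = as.integer(table(groups)))
}

setMethod("show", "ReferenceTemplate", function(object) {
    cat(sprintf(
        "ReferenceTemplate: period %g h, phase %g h, %d columns in %d tie groups (%s)\n",
        object@period_h, object@phase_h, length(object@template_values),
        length(object@group_sizes),
        paste(object@group_sizes, collapse = ",")))
})
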