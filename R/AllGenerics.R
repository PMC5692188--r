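#' @rdname timeGrid
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))

#' @rdname groundTruth
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname provenance
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname jtkTest
#' @export
setGeneric("jtkTest", function(x, ...) standardGeneric("jtkTest"))

#' @rdname duplicateConcatenate
#' @export
setGeneric("duplicateConcatenate",
    function(x, total_copies) standardGeneric("duplicateConcatenate"))

#' @rdname downsampleDataset
#' @export
setGeneric("downsampleDataset",
    function(x, keep_every) standardGeneric("downsampleDataset"))

#' @rdname truncateDataset
#' @export
setGeneric("truncateDataset",
    function(x, new_duration_h) standardGeneric("truncateDataset"))
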