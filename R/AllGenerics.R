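#' @rdname PositionScan-accessors
#' @export
setGeneric("scanPosition", function(x) standardGeneric("scanPosition"))

#' @rdname PositionScan-accessors
#' @export
setGeneric("wtResidue", function(x) standardGeneric("wtResidue"))

#' @rdname PositionScan-accessors
#' @export
setGeneric("substitutions", function(x) standardGeneric("substitutions"))

#' @rdname PositionScan-accessors
#' @export
setGeneric("excludedSubstitutions",
           function(x) standardGeneric("excludedSubstitutions"))

#' @rdname PositionScan-accessors
#' @export
setGeneric("scanMeasurements",
           function(x, ...) standardGeneric("scanMeasurements"))

#' @rdname expressionFilter
#' @export
setGeneric("expressionFilter",
           function(x, threshold = 1, ...) standardGeneric("expressionFilter"))

#' @rdname correctForExpression
#' @export
setGeneric("correctForExpression",
           function(x, ...) standardGeneric("correctForExpression"))

#' @rdname scoreScan
#' @export
setGeneric("scoreScan", function(x, ...) standardGeneric("scoreScan"))

#' @rdname averageOutcomes
#' @export
setGeneric("averageOutcomes", function(x, ...) standardGeneric("averageOutcomes"))

#' @rdname RheoScaleResult-accessors
#' @export
setGeneric("rheostatScore", function(x, ...) standardGeneric("rheostatScore"))

#' @rdname RheoScaleResult-accessors
#' @export
setGeneric("neutralFraction", function(x) standardGeneric("neutralFraction"))

#' @rdname RheoScaleResult-accessors
#' @export
setGeneric("toggleFraction", function(x) standardGeneric("toggleFraction"))

#' @rdname RheoScaleResult-accessors
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname RheoScaleResult-accessors
#' @export
setGeneric("binSweepStable", function(x) standardGeneric("binSweepStable"))

#' @rdname RheoScaleResult-accessors
#' @export
setGeneric("nUsed", function(x) standardGeneric("nUsed"))
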