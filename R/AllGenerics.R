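#' @rdname RegionStats-accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))

#' @rdname RegionStats-accessors
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname RegionStats-accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname RegionStats-accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname RegionStats-accessors
#' @export
setGeneric("effectSizes", function(x) standardGeneric("effectSizes"))

#' @rdname RegionStats-accessors
#' @export
setGeneric("standardErrors", function(x) standardGeneric("standardErrors"))

#' @rdname RegionStats-accessors
#' @export
setGeneric("minorAlleleFreqs", function(x) standardGeneric("minorAlleleFreqs"))

#' @rdname RegionStats-accessors
#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))

#' @rdname RegionStats-accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))

#' @rdname FineMapFit-accessors
#' @export
setGeneric("signalAlpha", function(x) standardGeneric("signalAlpha"))

#' @rdname FineMapFit-accessors
#' @export
setGeneric("signalLbf", function(x) standardGeneric("signalLbf"))

#' @rdname FineMapFit-accessors
#' @export
setGeneric("signalMu", function(x) standardGeneric("signalMu"))

#' @rdname FineMapFit-accessors
#' @export
setGeneric("pip", function(x) standardGeneric("pip"))

#' @rdname FineMapFit-accessors
#' @export
setGeneric("credibleSets", function(x, ...) standardGeneric("credibleSets"))

#' @rdname ColocResult-accessors
#' @export
setGeneric("posteriorProbs", function(x) standardGeneric("posteriorProbs"))

#' @rdname ColocResult-accessors
#' @export
setGeneric("clppValue", function(x) standardGeneric("clppValue"))

#' @rdname ColocResult-accessors
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' @rdname MREstimate-accessors
#' @export
setGeneric("causalSlope", function(x) standardGeneric("causalSlope"))

#' @rdname MREstimate-accessors
#' @export
setGeneric("slopeInterval", function(x) standardGeneric("slopeInterval"))

#' @rdname MREstimate-accessors
#' @export
setGeneric("dispersion", function(x) standardGeneric("dispersion"))
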