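#' @rdname MethylCohort-class
#' @param x,object an object.
#' @export
setGeneric("methylation", function(x) standardGeneric("methylation"))

#' @rdname MethylCohort-class
#' @export
setGeneric("cellProportions", function(x) standardGeneric("cellProportions"))

#' @rdname MethylCohort-class
#' @export
setGeneric("bmi", function(x) standardGeneric("bmi"))

#' @rdname RegressionFit-class
#' @param x an object.
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @rdname RegressionFit-class
#' @export
setGeneric("nUsed", function(x) standardGeneric("nUsed"))

#' @rdname RegressionFit-class
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname RegressionFit-class
#' @export
setGeneric("residualDf", function(x) standardGeneric("residualDf"))

#' @rdname VifReport-class
#' @param x an object.
#' @export
setGeneric("vifTable", function(x) standardGeneric("vifTable"))

#' @rdname CorrMatrix-class
#' @param x an object.
#' @export
setGeneric("corEstimates", function(x) standardGeneric("corEstimates"))

#' @rdname CorrMatrix-class
#' @export
setGeneric("corPValues", function(x) standardGeneric("corPValues"))

#' @rdname CorrMatrix-class
#' @export
setGeneric("corCounts", function(x) standardGeneric("corCounts"))

#' @rdname PcaDecomposition-class
#' @param x an object.
#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))

#' @rdname PcaDecomposition-class
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' @rdname PcaDecomposition-class
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @rdname SignReversalResult-class
#' @param x an object.
#' @export
setGeneric("fractionPositive", function(x) standardGeneric("fractionPositive"))

#' @rdname SignReversalResult-class
#' @export
setGeneric("mcSe", function(x) standardGeneric("mcSe"))

#' @rdname SignReversalResult-class
#' @export
setGeneric("analyticProbability", function(x) standardGeneric("analyticProbability"))
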