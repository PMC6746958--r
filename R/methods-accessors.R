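#' @describeIn MethylCohort-class CpG-by-participant percent-methylation
#'   matrix (`NA` = missing).
#' @export
setMethod("methylation", "MethylCohort", function(x)
    SummarizedExperiment::assay(x, "methylation"))

#' @describeIn MethylCohort-class participant-by-cell-type proportion matrix.
#' @export
setMethod("cellProportions", "MethylCohort", function(x)
    as.matrix(SummarizedExperiment::colData(x)[, .CELL_NAMES]))

#' @describeIn MethylCohort-class raw BMI (kg/m^2) per participant.
#' @export
setMethod("bmi", "MethylCohort", function(x)
    SummarizedExperiment::colData(x)$bmi)

#' @describeIn RegressionFit-class per-term coefficient table.
#' @export
setMethod("coefTable", "RegressionFit", function(x) x@coefficients)

#' @describeIn RegressionFit-class complete-case count used by the fit.
#' @export
setMethod("nUsed", "RegressionFit", function(x) x@nUsed)

#' @describeIn RegressionFit-class coefficient of determination.
#' @export
setMethod("rSquared", "RegressionFit", function(x) x@rSquared)

#' @describeIn RegressionFit-class residual degrees of freedom.
#' @export
setMethod("residualDf", "RegressionFit", function(x) x@residualDf)

#' @describeIn VifReport-class per-predictor VIF table.
#' @export
setMethod("vifTable", "VifReport", function(x) x@table)

#' @describeIn CorrMatrix-class matrix of correlation estimates.
#' @export
setMethod("corEstimates", "CorrMatrix", function(x) x@r)

#' @describeIn CorrMatrix-class matrix of two-sided p-values.
#' @export
setMethod("corPValues", "CorrMatrix", function(x) x@p)

#' @describeIn CorrMatrix-class matrix of pairwise complete-case counts.
#' @export
setMethod("corCounts", "CorrMatrix", function(x) x@n)

#' @describeIn PcaDecomposition-class orthonormal loading matrix.
#' @export
setMethod("pcLoadings", "PcaDecomposition", function(x) x@loadings)

#' @describeIn PcaDecomposition-class participant-by-component scores.
#' @export
setMethod("pcScores", "PcaDecomposition", function(x) x@scores)

#' @describeIn PcaDecomposition-class per-component variance fractions.
#' @export
setMethod("varianceExplained", "PcaDecomposition", function(x)
    x@varianceExplained)

#' @describeIn SignReversalResult-class fraction of replicates with a
#'   positive methylation coefficient.
#' @export
setMethod("fractionPositive", "SignReversalResult", function(x)
    x@fractionPositive)

#' @describeIn SignReversalResult-class Monte-Carlo standard error.
#' @export
setMethod("mcSe", "SignReversalResult", function(x) x@mcSe)

#' @describeIn SignReversalResult-class closed-form probability for the
#'   same scenario.
#' @export
setMethod("analyticProbability", "SignReversalResult", function(x)
    x@analyticProbability)

setMethod("show", "CohortSpec", function(object) {
    cat("CohortSpec:", object@nParticipants, "participants,",
        length(object@cpgNames), "CpGs,", length(object@cellNames),
        "cell types (seed", paste0(object@seed, ")\n"))
    cat("  outcome log-scale mean/sd:", object@outcomeMean, "/",
        object@outcomeSd, "\n")
    cat("  per-CpG missingness:",
        paste(signif(object@missingnessRates, 3), collapse = " "), "\n")
})

setMethod("show", "MethylCohort", function(object) {
    callNextMethod()
    cat(sprintf("mean six-proportion sum: %.3f\n",
                mean(rowSums(cellProportions(object)))))
})

setMethod("show", "RegressionFit", function(object) {
    cat("RegressionFit [", object@label, "]  n =", object@nUsed,
        " R^2 =", signif(object@rSquared, 4), "\n")
    print(object@coefficients, digits = 4, row.names = FALSE)
})

setMethod("show", "VifReport", function(object) {
    cat("VifReport [", object@model, "]\n")
    print(object@table, digits = 4, row.names = FALSE)
    if (length(object@notes)) cat("notes:", object@notes, sep = "\n  ")
})

setMethod("show", "CorrMatrix", function(object) {
    cat("CorrMatrix (", object@method, "), ", nrow(object@r),
        " variables\n", sep = "")
    print(round(object@r, 3))
})

setMethod("show", "SignReversalResult", function(object) {
    cat(sprintf(
        "SignReversalResult [%s]: %.1f%% positive (MC se %.2f pp; analytic %.1f%%)\n",
        object@scenario, 100 * object@fractionPositive, 100 * object@mcSe,
        100 * object@analyticProbability))
})
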