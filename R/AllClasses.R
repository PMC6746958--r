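#' @import methods
#' @importFrom stats coef complete.cases cor lm.fit pnorm prcomp pt qt
#'   rbinom rnorm runif sd setNames var
#' @importFrom utils modifyList read.csv write.csv head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
NULL

## Canonical lower-case cell-type identifiers, in the order used throughout:
## CD8 T cells, CD4 T cells, NK cells, B cells, monocytes, granulocytes.
.CELL_NAMES <- c("cd8t", "cd4t", "nk", "bcell", "mono", "gran")

#' Canonical cell-type identifiers
#'
#' The six white-blood-cell subtypes estimated by reference-based (Houseman)
#' deconvolution and consumed as adjustment covariates: CD8 T cells, CD4 T
#' cells, natural killer cells, B cells, monocytes and granulocytes.
#'
#' @return Character vector of length six.
#' @examples
#' cellTypeNames()
#' @export
cellTypeNames <- function() .CELL_NAMES

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Describes a joint Gaussian model over one outcome (log BMI), a set of CpG
#' percent-methylation variables and six cell proportions, plus per-CpG
#' missingness rates and a seed. Use [cohortSpec()] to construct and
#' [defaultRaineLikeSpec()] for documented defaults.
#'
#' @slot nParticipants integer, cohort size.
#' @slot outcomeMean,outcomeSd numeric, mean and SD on the log-BMI scale.
#' @slot cpgNames character, CpG identifiers.
#' @slot cpgMeans,cpgSds numeric, percent-methylation scale.
#' @slot cellNames character(6), cell-type identifiers.
#' @slot cellMeans,cellSds numeric(6), proportion scale.
#' @slot correlationMatrix full target correlation matrix over
#'   (outcome, CpGs, cells), with dimnames.
#' @slot missingnessRates numeric, per-CpG fraction missing, in `[0, 1)`.
#' @slot seed integer seed.
#' @export
setClass("CohortSpec", representation(
    nParticipants = "integer",
    outcomeMean = "numeric", outcomeSd = "numeric",
    cpgNames = "character", cpgMeans = "numeric", cpgSds = "numeric",
    cellNames = "character", cellMeans = "numeric", cellSds = "numeric",
    correlationMatrix = "matrix",
    missingnessRates = "numeric",
    seed = "integer"))

setValidity("CohortSpec", function(object) {
    msg <- character()
    nc <- length(object@cpgNames)
    p <- 1L + nc + length(object@cellNames)
    R <- object@correlationMatrix
    if (length(object@cellNames) != 6L)
        msg <- c(msg, "exactly six cell types are required")
    if (length(object@cpgMeans) != nc || length(object@cpgSds) != nc)
        msg <- c(msg, "cpgMeans/cpgSds must match cpgNames in length")
    if (length(object@cellMeans) != 6L || length(object@cellSds) != 6L)
        msg <- c(msg, "cellMeans/cellSds must have length six")
    if (!all(dim(R) == c(p, p)))
        msg <- c(msg, sprintf("correlationMatrix must be %d x %d", p, p))
    else {
        if (max(abs(R - t(R))) > 1e-8)
            msg <- c(msg, "correlationMatrix must be symmetric")
        if (max(abs(diag(R) - 1)) > 1e-8)
            msg <- c(msg, "correlationMatrix must have unit diagonal")
        if (any(abs(R) > 1 + 1e-8))
            msg <- c(msg, "correlation entries must lie in [-1, 1]")
    }
    if (any(object@cellMeans <= 0 | object@cellMeans >= 1))
        msg <- c(msg, "cellMeans must lie in (0, 1)")
    if (any(object@missingnessRates < 0 | object@missingnessRates >= 1))
        msg <- c(msg, "missingnessRates must lie in [0, 1)")
    if (length(object@missingnessRates) != nc)
        msg <- c(msg, "missingnessRates must match cpgNames in length")
    ## enough rows to fit the largest model family (CpG + age + sex + 6 cells)
    if (object@nParticipants < 9L + 2L)
        msg <- c(msg, "nParticipants must be at least the number of model terms + 2")
    if (any(object@cpgSds <= 0) || any(object@cellSds <= 0) || object@outcomeSd <= 0)
        msg <- c(msg, "all standard deviations must be positive")
    if (length(msg)) msg else TRUE
})

#' MethylCohort: participant-level methylation cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `methylation`
#' assay (CpG-by-participant, percent scale, `NA` for missing) and column
#' data holding `age`, `sex` (0/1), `bmi` (raw kg/m^2) and the six cell
#' proportions named as in [cellTypeNames()].
#'
#' @export
setClass("MethylCohort", contains = "SummarizedExperiment")

setValidity("MethylCohort", function(object) {
    msg <- character()
    if (!"methylation" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'methylation' is required")
    cd <- SummarizedExperiment::colData(object)
    need <- c("age", "sex", "bmi", .CELL_NAMES)
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
    else {
        cells <- as.matrix(cd[, .CELL_NAMES])
        if (any(cells < -1e-9 | cells > 1 + 1e-9, na.rm = TRUE))
            msg <- c(msg, "cell proportions must lie in [0, 1]")
        m <- SummarizedExperiment::assay(object, "methylation")
        if (any(m < -1e-9 | m > 100 + 1e-9, na.rm = TRUE))
            msg <- c(msg, "methylation values must lie in [0, 100]")
    }
    if (length(msg)) msg else TRUE
})

#' RegressionFit: one fitted ordinary-least-squares model
#'
#' @slot coefficients data.frame with columns `term`, `beta`, `se`,
#'   `ciLow`, `ciHigh`, `p` (95% CI from the t distribution).
#' @slot nUsed integer, complete-case count actually fitted.
#' @slot rSquared numeric, coefficient of determination.
#' @slot residualDf integer residual degrees of freedom.
#' @slot label character model label.
#' @export
setClass("RegressionFit", representation(
    coefficients = "data.frame", nUsed = "integer",
    rSquared = "numeric", residualDf = "integer", label = "character"))

setValidity("RegressionFit", function(object) {
    cf <- object@coefficients
    msg <- character()
    if (!all(c("term", "beta", "se", "ciLow", "ciHigh", "p") %in% names(cf)))
        msg <- c(msg, "coefficient table is missing required columns")
    else {
        ok <- cf$ciLow <= cf$beta + 1e-12 & cf$beta <= cf$ciHigh + 1e-12
        if (!all(ok)) msg <- c(msg, "confidence intervals must bracket beta")
        if (any(cf$p < -1e-12 | cf$p > 1 + 1e-12))
            msg <- c(msg, "p-values must lie in [0, 1]")
    }
    if (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9)
        msg <- c(msg, "rSquared must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' VifReport: variance-inflation diagnostics for one model
#'
#' @slot table data.frame with columns `term`, `vif`, `tolerance`
#'   (= 1/vif) and `pctVarExplained` (= (1 - 1/vif) * 100).
#' @slot model character model label.
#' @slot notes character, warning records (e.g. aliased predictors).
#' @export
setClass("VifReport", representation(
    table = "data.frame", model = "character", notes = "character"))

setValidity("VifReport", function(object) {
    tb <- object@table
    msg <- character()
    if (!all(c("term", "vif", "tolerance", "pctVarExplained") %in% names(tb)))
        return("VIF table is missing required columns")
    fin <- is.finite(tb$vif)
    if (any(tb$vif[fin] < 1 - 1e-9)) msg <- c(msg, "VIFs must be >= 1")
    if (any(abs(tb$tolerance[fin] * tb$vif[fin] - 1) > 1e-9))
        msg <- c(msg, "tolerance must equal 1/vif")
    if (length(msg)) msg else TRUE
})

#' CorrMatrix: pairwise correlation estimates with p-values and counts
#'
#' @slot r symmetric matrix of correlation estimates.
#' @slot p matrix of two-sided p-values (t approximation).
#' @slot n matrix of pairwise complete-case counts.
#' @slot method "pearson" or "spearman".
#' @export
setClass("CorrMatrix", representation(
    r = "matrix", p = "matrix", n = "matrix", method = "character"))

setValidity("CorrMatrix", function(object) {
    r <- object@r
    msg <- character()
    if (max(abs(r - t(r)), na.rm = TRUE) > 1e-9)
        msg <- c(msg, "correlation matrix must be symmetric")
    if (any(abs(r) > 1 + 1e-9, na.rm = TRUE))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    if (!object@method %in% c("pearson", "spearman"))
        msg <- c(msg, "method must be 'pearson' or 'spearman'")
    if (length(msg)) msg else TRUE
})

#' ScreenReport: array-wide high-correlation screen summary
#'
#' @slot summary data.frame per cell type: `cell`, `nFlagged`, `fraction`,
#'   `nScreened`.
#' @slot top named list of data.frames (`cpg`, `r`) sorted by `|r|`
#'   descending, one per screened cell type.
#' @slot threshold numeric `|r_s|` cutoff.
#' @slot skipped character, cell types excluded (near-zero variance).
#' @export
setClass("ScreenReport", representation(
    summary = "data.frame", top = "list", threshold = "numeric",
    skipped = "character"))

#' PcaDecomposition: principal components of the cell proportions
#'
#' @slot loadings cell-type-by-component orthonormal loading matrix.
#' @slot scores participant-by-component score matrix.
#' @slot varianceExplained fraction of variance per component (sums to 1).
#' @slot center,scale logical flags used.
#' @export
setClass("PcaDecomposition", representation(
    loadings = "matrix", scores = "matrix", varianceExplained = "numeric",
    center = "logical", scale = "logical"))

setValidity("PcaDecomposition", function(object) {
    L <- object@loadings
    msg <- character()
    if (max(abs(crossprod(L) - diag(ncol(L)))) > 1e-8)
        msg <- c(msg, "loadings must be orthonormal")
    if (abs(sum(object@varianceExplained) - 1) > 1e-8)
        msg <- c(msg, "variance-explained fractions must sum to 1")
    if (length(msg)) msg else TRUE
})

#' SimulationSpec: design of the trivariate sign-reversal experiment
#'
#' Describes replicated joint Gaussian draws of (outcome, methylation,
#' granulocyte) and the regression fitted per replicate. Use
#' [simulationSpec()] to construct with study-condition defaults.
#'
#' @slot nPerReplicate integer draws per replicate.
#' @slot replicates integer number of replicates.
#' @slot means,sds numeric(3): outcome, methylation, granulocyte.
#' @slot rOutcomeMeth,rOutcomeGran,rMethGran pairwise correlations.
#' @slot includeGranulocyte logical, include granulocyte as covariate.
#' @slot seed integer.
#' @export
setClass("SimulationSpec", representation(
    nPerReplicate = "integer", replicates = "integer",
    means = "numeric", sds = "numeric",
    rOutcomeMeth = "numeric", rOutcomeGran = "numeric", rMethGran = "numeric",
    includeGranulocyte = "logical", seed = "integer"))

setValidity("SimulationSpec", function(object) {
    msg <- character()
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (length(object@means) != 3L || length(object@sds) != 3L)
        msg <- c(msg, "means and sds must have length 3")
    if (any(object@sds <= 0)) msg <- c(msg, "sds must be positive")
    R <- .simCorrelation(object)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
        msg <- c(msg, "implied 3x3 correlation matrix is not positive definite")
    if (length(msg)) msg else TRUE
})

#' SignReversalResult: outcome of one Monte-Carlo scenario
#'
#' @slot fractionPositive proportion of replicates with a positive
#'   methylation coefficient.
#' @slot replicates integer.
#' @slot mcSe Monte-Carlo standard error `sqrt(p(1-p)/replicates)`.
#' @slot betas per-replicate methylation coefficients (may be empty).
#' @slot rMethGran scenario methylation-granulocyte correlation.
#' @slot includeGranulocyte logical.
#' @slot analyticProbability closed-form large-n probability of a positive
#'   coefficient for the same scenario.
#' @slot scenario character label.
#' @export
setClass("SignReversalResult", representation(
    fractionPositive = "numeric", replicates = "integer", mcSe = "numeric",
    betas = "numeric", rMethGran = "numeric", includeGranulocyte = "logical",
    analyticProbability = "numeric", scenario = "character"))

setValidity("SignReversalResult", function(object) {
    p <- object@fractionPositive
    msg <- character()
    if (p < 0 || p > 1) msg <- c(msg, "fractionPositive must lie in [0, 1]")
    se <- sqrt(p * (1 - p) / object@replicates)
    if (abs(object@mcSe - se) > 1e-12)
        msg <- c(msg, "mcSe must equal sqrt(p(1-p)/replicates)")
    if (length(msg)) msg else TRUE
})
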