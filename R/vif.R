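#' Percent of a predictor's variance explained by the other predictors
#'
#' Converts a variance inflation factor to the percentage of that
#' predictor's variance explained by the remaining predictors,
#' `(1 - 1/VIF) * 100`. A VIF of 5, the usual rule-of-thumb ceiling,
#' corresponds to 80%.
#'
#' @param vif numeric VIF value(s), each `>= 1`.
#' @return Percentage(s) in `[0, 100)`.
#' @examples
#' pctVarianceExplained(c(1, 5, 113.71))
#' @export
pctVarianceExplained <- function(vif) {
    if (any(vif < 1 - 1e-9, na.rm = TRUE))
        stop("VIF values must be >= 1")
    (1 - 1 / pmax(vif, 1)) * 100
}

#' Variance inflation factors for a design
#'
#' For each predictor `j`, `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is the
#' coefficient of determination from regressing predictor `j` on all other
#' predictors (with intercept). Rows with any missing value are dropped
#' first. A predictor that is perfectly explained by the others receives an
#' infinite VIF together with a warning record, rather than an error.
#'
#' @param design data.frame or matrix of named predictor columns, without
#'   an intercept column (the intercept never receives a VIF).
#' @param model label stored on the report.
#' @return A [VifReport-class] with per-predictor `vif`, `tolerance`
#'   (`1/vif`) and `pctVarExplained`.
#' @examples
#' x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' vifTable(computeVif(x))
#' @export
computeVif <- function(design, model = "model") {
    X <- as.matrix(design)
    if (is.null(colnames(X)))
        colnames(X) <- paste0("x", seq_len(ncol(X)))
    X <- X[complete.cases(X), , drop = FALSE]
    k <- ncol(X)
    if (k < 2L) stop("at least two predictors are required")
    if (nrow(X) < k + 2L) stop("insufficient complete rows for a VIF")
    sds <- apply(X, 2, sd)
    if (any(sds == 0))
        stop("constant predictor(s): ", paste(colnames(X)[sds == 0],
                                              collapse = ", "))
    notes <- character()
    vif <- vapply(seq_len(k), function(j) {
        y <- X[, j]
        Z <- cbind(1, X[, -j, drop = FALSE])
        fit <- lm.fit(Z, y)
        rss <- sum(fit$residuals^2)
        tss <- sum((y - mean(y))^2)
        r2 <- 1 - rss / tss
        if (r2 >= 1 - 1e-12) Inf else max(1, 1 / (1 - r2))
    }, numeric(1))
    if (any(!is.finite(vif)))
        notes <- sprintf("perfectly collinear predictor(s): %s",
                         paste(colnames(X)[!is.finite(vif)], collapse = ", "))
    if (length(notes)) warning(notes)
    new("VifReport",
        table = data.frame(
            term = colnames(X), vif = vif, tolerance = 1 / vif,
            pctVarExplained = pctVarianceExplained(vif), row.names = NULL),
        model = model, notes = notes)
}

#' VIF report for a fitted methylation model family
#'
#' Assembles the predictor set actually entered in the model (CpG
#' methylation, age, sex and the requested cell proportions, complete-case
#' per model) and reports the VIF diagnostics for every predictor.
#'
#' @inheritParams fitMethylationModel
#' @return A [VifReport-class].
#' @examples
#' cohort <- generateCohort(defaultRaineLikeSpec())
#' vifForModel(cohort, "cpg4", "six_cell")
#' @export
vifForModel <- function(cohort, cpg,
                        adjustment = c("six_cell", "five_cell_no_gran")) {
    adjustment <- match.arg(adjustment)
    mf <- .modelFrame(cohort, cpg, .adjustmentCells(adjustment))
    computeVif(mf$design, model = sprintf("%s | %s", cpg, adjustment))
}

#' Condition indices of a design matrix
#'
#' Each column is scaled to unit Euclidean length, the singular values of
#' the scaled design are computed, and the indices are the largest singular
#' value divided by each singular value, sorted ascending. Large values
#' (conventionally above 30) flag near-linear dependence.
#'
#' @param design data.frame or matrix of named columns (include an
#'   intercept column yourself if desired).
#' @return Numeric vector of condition indices, ascending; the first is
#'   always 1.
#' @examples
#' conditionIndices(matrix(rnorm(40), 10, 4))
#' @export
conditionIndices <- function(design) {
    X <- as.matrix(design)
    X <- X[complete.cases(X), , drop = FALSE]
    if (ncol(X) < 2L) stop("at least two columns are required")
    len <- sqrt(colSums(X^2))
    if (any(len == 0)) stop("zero column(s) in design")
    d <- svd(sweep(X, 2, len, `/`), nu = 0, nv = 0)$d
    sort(max(d) / d)
}
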