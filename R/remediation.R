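#' Refit a methylation model with one cell type dropped
#'
#' Identical to [fitMethylationModel()] with the named cell type removed
#' from the six-cell adjustment set — the usual remediation after finding
#' one cell type (typically granulocytes) with an extreme VIF.
#'
#' @inheritParams fitMethylationModel
#' @param drop one of [cellTypeNames()].
#' @return A [RegressionFit-class].
#' @export
dropPredictorRefit <- function(cohort, cpg, drop = "gran") {
    if (!drop %in% .CELL_NAMES)
        stop(sprintf("unknown cell type '%s'", drop))
    mf <- .modelFrame(cohort, cpg, setdiff(.CELL_NAMES, drop))
    fitOls(mf$outcome, mf$design,
           label = sprintf("%s | six_cell minus %s", cpg, drop))
}

#' Principal components of the cell proportions
#'
#' Runs [stats::prcomp()] on the participant-by-cell-type proportion matrix
#' (complete rows only) and applies a deterministic sign convention: in each
#' component the largest-magnitude loading is positive, so results are
#' reproducible across linear-algebra backends.
#'
#' @param cohort a [MethylCohort-class].
#' @param center,scale. centering/scaling flags passed to `prcomp`
#'   (defaults: center, no scaling — the defaults of the underlying tool).
#' @return A [PcaDecomposition-class]; scores carry participant ids as row
#'   names.
#' @export
pcaCells <- function(cohort, center = TRUE, scale. = FALSE) {
    cells <- cellProportions(cohort)
    cells <- cells[complete.cases(cells), , drop = FALSE]
    if (nrow(cells) < 7L) stop("at least 7 complete rows are required")
    if (scale. && any(apply(cells, 2, sd) == 0))
        stop("constant cell column cannot be scaled")
    pc <- prcomp(cells, center = center, scale. = scale.)
    flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
        l <- pc$rotation[, j]
        sign(l[which.max(abs(l))])
    }, numeric(1))
    rot <- sweep(pc$rotation, 2, flip, `*`)
    scores <- sweep(pc$x, 2, flip, `*`)
    v <- pc$sdev^2
    new("PcaDecomposition", loadings = rot, scores = scores,
        varianceExplained = v / sum(v), center = isTRUE(center),
        scale = isTRUE(scale.))
}

#' Refit with principal components substituted for cell types
#'
#' Replaces the six cell proportions in the adjustment set by the first `k`
#' principal-component scores of those proportions (plus age and sex). With
#' `k = 6` this is an invertible linear reparameterization, so the CpG
#' coefficient equals the six-cell-model coefficient exactly.
#'
#' @inheritParams fitMethylationModel
#' @param k number of components, `1 <= k <= 6`.
#' @param center,scale. passed to [pcaCells()].
#' @return A [RegressionFit-class].
#' @export
pcSubstituteRefit <- function(cohort, cpg, k = 2L, center = TRUE,
                              scale. = FALSE) {
    if (k < 1L || k > 6L) stop("'k' must lie between 1 and 6")
    pca <- pcaCells(cohort, center = center, scale. = scale.)
    mf <- .modelFrame(cohort, cpg)
    sc <- pcScores(pca)
    idx <- match(colnames(cohort), rownames(sc))
    for (j in seq_len(k)) mf$design[[paste0("PC", j)]] <- sc[idx, j]
    fitOls(mf$outcome, mf$design,
           label = sprintf("%s | first %d cell PCs", cpg, k))
}

.residualize <- function(y, covariates) {
    keep <- complete.cases(y, covariates)
    Z <- cbind(1, as.matrix(covariates)[keep, , drop = FALSE])
    r <- rep(NA_real_, length(y))
    r[keep] <- lm.fit(Z, y[keep])$residuals
    r
}

#' Refit after residualizing methylation on cell types
#'
#' Removes cell-type variation from the methylation values by linear
#' regression and refits the outcome model on the residuals (retaining age
#' and sex). `mode = "each"` residualizes on one cell type at a time (six
#' fits); `mode = "all"` residualizes on all six jointly;
#' `mode = "all_with_covariates"` additionally removes age and sex from the
#' methylation values — with that mode the CpG coefficient reproduces the
#' six-cell-model coefficient exactly (Frisch–Waugh–Lovell identity).
#'
#' @inheritParams fitMethylationModel
#' @param mode `"each"`, `"all"` or `"all_with_covariates"`.
#' @return A named list of [RegressionFit-class] objects (one per cell type
#'   for `"each"`, otherwise length one). The residualized methylation term
#'   keeps the CpG's name.
#' @export
residualRefit <- function(cohort, cpg, mode = c("each", "all",
                                                "all_with_covariates")) {
    if (is.character(mode) && length(mode) == 1 &&
        !mode %in% c("each", "all", "all_with_covariates"))
        stop(sprintf("unknown mode '%s'", mode))
    mode <- match.arg(mode)
    mf <- .modelFrame(cohort, cpg)
    meth <- mf$design[[cpg]]
    cells <- as.data.frame(cellProportions(cohort))
    covSets <- switch(mode,
        each = lapply(setNames(.CELL_NAMES, .CELL_NAMES),
                      function(cl) cells[, cl, drop = FALSE]),
        all = list(all = cells),
        all_with_covariates = list(all_with_covariates = cbind(
            cells, age = mf$design$age, sex = mf$design$sex)))
    lapply(names(covSets), function(nm) {
        r <- .residualize(meth, covSets[[nm]])
        if (sd(r, na.rm = TRUE) < 1e-10)
            stop("residualized methylation is (numerically) constant")
        design <- if (mode == "all_with_covariates")
            setNames(data.frame(r), cpg)
        else {
            d <- data.frame(r, mf$design$age, mf$design$sex)
            names(d) <- c(cpg, "age", "sex")
            d
        }
        fitOls(mf$outcome, design,
               label = sprintf("%s | residualized on %s", cpg, nm))
    }) |> setNames(names(covSets))
}
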