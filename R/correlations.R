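## Two-sided p-value for a correlation via the t approximation
.corPValue <- function(r, n) {
    t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * pt(abs(t), n - 2, lower.tail = FALSE)
}

#' Pairwise correlation matrix with p-values and counts
#'
#' Pearson or Spearman (average ranks for ties) correlations over all
#' column pairs, using pairwise complete observations. Two-sided p-values
#' come from the t approximation `t = r sqrt((n-2)/(1-r^2))`. A constant
#' column yields `NA` correlations with a warning.
#'
#' @param table data.frame or matrix of named numeric columns.
#' @param method `"pearson"` or `"spearman"`.
#' @return A [CorrMatrix-class].
#' @examples
#' cm <- correlationMatrix(data.frame(x = 1:10, y = (1:10)^2), "spearman")
#' corEstimates(cm)
#' @export
correlationMatrix <- function(table, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    X <- as.matrix(table)
    if (is.null(colnames(X)))
        colnames(X) <- paste0("v", seq_len(ncol(X)))
    p <- ncol(X)
    obs <- !is.na(X)
    N <- crossprod(obs)
    if (any(N < 3L))
        stop("fewer than 3 pairwise complete observations for some pair")
    sds <- apply(X, 2, sd, na.rm = TRUE)
    if (any(sds == 0)) {
        warning("constant column(s), correlations undefined: ",
                paste(colnames(X)[sds == 0], collapse = ", "))
    }
    r <- suppressWarnings(
        cor(X, use = "pairwise.complete.obs", method = method))
    P <- .corPValue(r, N)
    diag(P) <- 0
    storage.mode(N) <- "integer"
    new("CorrMatrix", r = r, p = P, n = N, method = method)
}

#' CpG-by-cell correlation table for a cohort
#'
#' Correlations between each CpG's percent methylation and each estimated
#' cell proportion (pairwise complete per CpG).
#'
#' @param cohort a [MethylCohort-class].
#' @param method `"pearson"` or `"spearman"`.
#' @return A [CorrMatrix-class] over `c(cpgs, cells)`; the CpG-by-cell block
#'   is the table of interest.
#' @export
cpgCellCorrelations <- function(cohort, method = c("pearson", "spearman")) {
    df <- cbind(as.data.frame(t(methylation(cohort))),
                as.data.frame(cellProportions(cohort)))
    correlationMatrix(df, match.arg(method))
}

#' Array-wide high-correlation screen
#'
#' Computes, per cell type, the Spearman correlation between every CpG row
#' of a methylation matrix and the cell proportion, and counts CpGs with
#' `|r_s|` at or above the threshold. Processing is chunked over CpGs so
#' memory stays flat at array scale. Cell types whose sample SD is below
#' `1e-6` are skipped with a message (mirroring screens that omit
#' essentially constant cell estimates).
#'
#' @param meth CpG-by-participant matrix (column names are participant ids).
#' @param cells participant-by-cell-type matrix or data.frame (row names are
#'   participant ids).
#' @param threshold `|r_s|` cutoff in `(0, 1]`.
#' @param topK number of top CpGs to list per cell type.
#' @param chunkSize CpGs per chunk.
#' @return A [ScreenReport-class].
#' @examples
#' cells <- matrix(runif(300), 50, 6, dimnames =
#'     list(sprintf("P%02d", 1:50), cellTypeNames()))
#' meth <- matrix(runif(500, 0, 100), 10, 50,
#'     dimnames = list(paste0("cg", 1:10), rownames(cells)))
#' highCorrelationScreen(meth, cells, threshold = 0.7)
#' @export
highCorrelationScreen <- function(meth, cells, threshold = 0.700, topK = 50L,
                                  chunkSize = 10000L) {
    if (threshold <= 0 || threshold > 1)
        stop("'threshold' must lie in (0, 1]")
    cells <- as.matrix(cells)
    common <- intersect(colnames(meth), rownames(cells))
    if (length(common) == 0L)
        stop("no overlapping participant ids between 'meth' and 'cells'")
    meth <- meth[, common, drop = FALSE]
    cells <- cells[common, , drop = FALSE]
    sds <- apply(cells, 2, sd, na.rm = TRUE)
    skipped <- colnames(cells)[sds < 1e-6]
    if (length(skipped))
        message("skipping near-constant cell type(s): ",
                paste(skipped, collapse = ", "))
    use <- setdiff(colnames(cells), skipped)
    cells <- cells[, use, drop = FALSE]
    nCpg <- nrow(meth)
    R <- matrix(NA_real_, nCpg, length(use),
                dimnames = list(rownames(meth), use))
    starts <- seq(1L, nCpg, by = chunkSize)
    for (s in starts) {
        idx <- s:min(s + chunkSize - 1L, nCpg)
        R[idx, ] <- suppressWarnings(cor(
            t(meth[idx, , drop = FALSE]), cells,
            use = "pairwise.complete.obs", method = "spearman"))
    }
    summ <- data.frame(
        cell = use,
        nFlagged = colSums(abs(R) >= threshold, na.rm = TRUE),
        fraction = colMeans(abs(R) >= threshold, na.rm = TRUE),
        nScreened = colSums(!is.na(R)), row.names = NULL)
    top <- lapply(setNames(use, use), function(cl) {
        r <- R[, cl]
        ord <- order(abs(r), decreasing = TRUE, na.last = TRUE)
        ord <- head(ord, topK)
        data.frame(cpg = rownames(R)[ord], r = r[ord], row.names = NULL)
    })
    new("ScreenReport", summary = summ, top = top, threshold = threshold,
        skipped = skipped)
}
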