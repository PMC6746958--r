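## Correlated Gaussian sampling.
##
## The primary sampler factors the target correlation matrix by Cholesky
## decomposition; an alternative eigendecomposition-based factorization is
## provided so the two routes can be compared as independent checks.

.checkCorrMatrix <- function(corr) {
    if (!is.matrix(corr) || nrow(corr) != ncol(corr))
        stop("'corr' must be a square matrix")
    if (max(abs(corr - t(corr))) > 1e-8)
        stop("'corr' must be symmetric")
    if (max(abs(diag(corr) - 1)) > 1e-8)
        stop("'corr' must have a unit diagonal")
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10)
        stop(sprintf(
            "'corr' is not positive definite (smallest eigenvalue %.3e); %s",
            min(ev),
            "consider repairing it with nearestPositiveDefinite()"))
    invisible(ev)
}

#' Repair a correlation matrix to the nearest positive-definite one
#'
#' Thin wrapper around [Matrix::nearPD()] keeping the unit diagonal. The
#' Frobenius distance moved is reported via a message so repairs are never
#' silent.
#'
#' @param corr symmetric matrix with unit diagonal.
#' @return A positive-definite correlation matrix.
#' @examples
#' bad <- matrix(c(1, .9, .9, .9, 1, -.9, .9, -.9, 1), 3)
#' ok <- nearestPositiveDefinite(bad)
#' @export
nearestPositiveDefinite <- function(corr) {
    fixed <- as.matrix(Matrix::nearPD(corr, corr = TRUE, keepDiag = TRUE)$mat)
    dimnames(fixed) <- dimnames(corr)
    message(sprintf(
        "repaired correlation matrix: Frobenius distance moved %.4g",
        norm(corr - fixed, "F")))
    fixed
}

#' Draw correlated Gaussian samples
#'
#' Draws `n` joint observations from a multivariate normal distribution with
#' the given means, standard deviations and correlation matrix. Deterministic
#' for a fixed seed.
#'
#' @param n number of draws.
#' @param means,sds numeric vectors, one entry per variable.
#' @param corr target correlation matrix (symmetric, unit diagonal, positive
#'   definite).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param method `"cholesky"` (primary) or `"eigen"` (alternative
#'   factorization of the same distribution, useful as an independent
#'   cross-check).
#' @param repair if `TRUE`, a non-positive-definite `corr` is repaired with
#'   [nearestPositiveDefinite()] instead of raising an error.
#' @return An `n`-by-`length(means)` matrix; column names taken from
#'   `corr` or `names(means)`.
#' @examples
#' R <- diag(3); R[1, 2] <- R[2, 1] <- -0.783
#' x <- correlatedGaussianSample(1000, rep(0, 3), rep(1, 3), R, seed = 1)
#' cor(x)[1, 2]
#' @export
correlatedGaussianSample <- function(n, means, sds, corr, seed = NULL,
                                     method = c("cholesky", "eigen"),
                                     repair = FALSE) {
    method <- match.arg(method)
    p <- length(means)
    if (length(sds) != p || nrow(corr) != p || ncol(corr) != p)
        stop("dimensions of 'means', 'sds' and 'corr' do not agree")
    if (any(sds <= 0)) stop("'sds' must be positive")
    if (repair) {
        ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) <= 1e-10) corr <- nearestPositiveDefinite(corr)
    }
    .checkCorrMatrix(corr)
    if (!is.null(seed)) set.seed(as.integer(seed))
    Z <- matrix(rnorm(n * p), n, p)
    L <- switch(method,
        cholesky = chol(corr),                      # upper triangular: Z %*% L
        eigen = {
            e <- eigen(corr, symmetric = TRUE)
            t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors))
        })
    X <- Z %*% L
    X <- sweep(X, 2, sds, `*`)
    X <- sweep(X, 2, means, `+`)
    colnames(X) <- if (!is.null(colnames(corr))) colnames(corr) else names(means)
    X
}
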