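#' Fit an ordinary-least-squares model
#'
#' Classical OLS with complete-case handling: rows with any missing value in
#' the outcome or design are dropped, and `nUsed` reports the remainder.
#' Standard errors come from the classical covariance matrix and 95%
#' confidence intervals from the t distribution with the residual degrees of
#' freedom.
#'
#' @param outcome numeric response vector.
#' @param design data.frame or matrix of named predictor columns (no
#'   intercept column; one is added unless `intercept = FALSE`).
#' @param intercept include an intercept (default `TRUE`).
#' @param label model label stored on the fit.
#' @return A [RegressionFit-class].
#' @section Errors: exact collinearity raises an error naming the aliased
#'   columns; fewer complete rows than `ncol(design) + 2` is an error.
#' @examples
#' x <- 1:10
#' fitOls(2 * x + 1, data.frame(x = x))
#' @export
fitOls <- function(outcome, design, intercept = TRUE, label = "ols") {
    X <- as.matrix(design)
    if (is.null(colnames(X)))
        colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (length(outcome) != nrow(X))
        stop("'outcome' and 'design' must have the same number of rows")
    keep <- complete.cases(outcome, X)
    y <- outcome[keep]
    X <- X[keep, , drop = FALSE]
    if (intercept) X <- cbind(`(Intercept)` = 1, X)
    n <- length(y)
    k <- ncol(X)
    if (n < k + 2L)
        stop(sprintf("insufficient complete rows (%d) for %d coefficients",
                     n, k))
    qx <- qr(X)
    if (qx$rank < k) {
        aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):k]]
        stop("design is exactly collinear; aliased columns: ",
             paste(aliased, collapse = ", "))
    }
    beta <- qr.coef(qx, y)
    res <- y - X %*% beta
    df <- n - k
    sigma2 <- sum(res^2) / df
    XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
    se <- sqrt(sigma2 * diag(XtXinv))
    tval <- beta / se
    p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
    tq <- qt(0.975, df)
    tss <- if (intercept) sum((y - mean(y))^2) else sum(y^2)
    r2 <- if (tss > 0) 1 - sum(res^2) / tss else 0
    new("RegressionFit",
        coefficients = data.frame(
            term = colnames(X), beta = as.numeric(beta), se = se,
            ciLow = as.numeric(beta - tq * se),
            ciHigh = as.numeric(beta + tq * se),
            p = as.numeric(p), row.names = NULL),
        nUsed = n, rSquared = max(0, min(1, r2)),
        residualDf = as.integer(df), label = label)
}

.getTerm <- function(fit, term) {
    cf <- coefTable(fit)
    i <- match(term, cf$term)
    if (is.na(i))
        stop(sprintf("term '%s' not present in fit '%s'", term, fit@label))
    cf[i, ]
}

#' Flag sign reversal and significance change between two fits
#'
#' A reversal is flagged when the coefficient of `term` has strictly
#' opposite signs in the two fits (an exactly zero coefficient carries no
#' sign and never reverses). A significance change is flagged when the term
#' crosses `alpha` between the fits.
#'
#' @param fitA,fitB [RegressionFit-class] objects containing `term`.
#' @param term coefficient name to compare.
#' @param alpha significance level (default 0.05).
#' @return A list with `reversal` and `significanceChange` logical flags and
#'   the two (beta, p) pairs.
#' @examples
#' x <- rnorm(50); y <- -x + rnorm(50)
#' fa <- fitOls(y, data.frame(x = x))
#' fb <- fitOls(-y, data.frame(x = x))
#' detectSignReversal(fa, fb, "x")
#' @export
detectSignReversal <- function(fitA, fitB, term, alpha = 0.05) {
    a <- .getTerm(fitA, term)
    b <- .getTerm(fitB, term)
    list(
        reversal = sign(a$beta) != 0 && sign(b$beta) != 0 &&
            sign(a$beta) != sign(b$beta),
        significanceChange = (a$p < alpha) != (b$p < alpha),
        betaA = a$beta, betaB = b$beta, pA = a$p, pB = b$p)
}
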