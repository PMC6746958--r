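# Shared fixtures, built in code. Cohorts are cached per (n, seed) so tests
# that reuse the default study conditions do not resample.
.fixtureEnv <- new.env(parent = emptyenv())

defaultCohort <- function(n = 812L, seed = 1L) {
    key <- paste0("cohort_", n, "_", seed)
    if (is.null(.fixtureEnv[[key]]))
        .fixtureEnv[[key]] <- generateCohort(
            defaultRaineLikeSpec(nParticipants = n, seed = seed))
    .fixtureEnv[[key]]
}

# Random well-conditioned design matrix with named columns.
randomDesign <- function(n, k) {
    X <- matrix(rnorm(n * k), n, k)
    colnames(X) <- paste0("x", seq_len(k))
    X
}

# Pseudoinverse OLS oracle: coefficients, classical SEs and R^2 computed
# from first principles, independent of the package's QR path.
ginvOls <- function(y, X) {
    Xi <- cbind(1, X)
    bi <- MASS::ginv(t(Xi) %*% Xi) %*% t(Xi) %*% y
    res <- y - Xi %*% bi
    df <- length(y) - ncol(Xi)
    s2 <- sum(res^2) / df
    se <- sqrt(s2 * diag(MASS::ginv(t(Xi) %*% Xi)))
    list(beta = as.numeric(bi), se = se,
         r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Construct two columns whose *sample* correlation is exactly r.
exactlyCorrelatedPair <- function(n, r) {
    x <- rnorm(n)
    z <- rnorm(n)
    x <- (x - mean(x)) / sd(x)
    z <- residuals(lm(z ~ x))
    z <- z / sd(z)
    cbind(a = x, b = r * x + sqrt(1 - r^2) * z)
}
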