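#' Correlation implied by a regression coefficient and its standard error
#'
#' Recovers the (partial) Pearson correlation behind a reported coefficient
#' via `r = t / sqrt(t^2 + df)` with `t = beta/se` and
#' `df = n - kCovariates - 2`. Useful when a study prints beta, CI and n but
#' not the underlying correlation.
#'
#' @param beta coefficient estimate(s).
#' @param se standard error(s), positive.
#' @param n sample size(s).
#' @param kCovariates number of additional covariates in the model.
#' @return Correlation estimate(s) in `[-1, 1]`.
#' @examples
#' correlationFromT(-0.004, 0.0014, 812, 2)  # about -0.10
#' @export
correlationFromT <- function(beta, se, n, kCovariates = 0L) {
    if (any(se <= 0)) stop("'se' must be positive")
    df <- n - kCovariates - 2L
    if (any(df <= 0)) stop("invalid degrees of freedom (n too small)")
    t <- beta / se
    t / sqrt(t^2 + df)
}

.simCorrelation <- function(spec) {
    r <- diag(3)
    r[1, 2] <- r[2, 1] <- spec@rOutcomeMeth
    r[1, 3] <- r[3, 1] <- spec@rOutcomeGran
    r[2, 3] <- r[3, 2] <- spec@rMethGran
    dimnames(r) <- list(c("outcome", "meth", "gran"),
                        c("outcome", "meth", "gran"))
    r
}

#' Construct a SimulationSpec
#'
#' Defaults describe the study conditions of the sign-reversal experiment:
#' replicated cohorts of n = 812, 1,000 replicates, the published
#' methylation-granulocyte correlation (-0.783) and outcome-granulocyte
#' correlation (0.16), and an outcome-methylation correlation derived from
#' the unadjusted CpG4 association summary via [correlationFromT()]
#' (approximately -0.10). Means and SDs are placeholders on the log-BMI,
#' percent-methylation and proportion scales; they do not affect the sign
#' of any fitted coefficient.
#'
#' @param nPerReplicate draws per replicate.
#' @param replicates number of replicated regressions.
#' @param means,sds numeric(3) for (outcome, methylation, granulocyte).
#' @param rOutcomeMeth,rOutcomeGran,rMethGran pairwise correlations.
#' @param includeGranulocyte include granulocyte as a covariate.
#' @param seed integer seed.
#' @return A [SimulationSpec-class].
#' @export
simulationSpec <- function(nPerReplicate = 812L, replicates = 1000L,
                           means = c(log(22), 50, 0.55),
                           sds = c(0.15, 3.75, 0.077),
                           rOutcomeMeth = correlationFromT(
                               -0.004, seFromCi(-0.0065, -0.001, 808), 812, 2L),
                           rOutcomeGran = 0.16,
                           rMethGran = -0.783,
                           includeGranulocyte = TRUE, seed = 1L) {
    new("SimulationSpec",
        nPerReplicate = as.integer(nPerReplicate),
        replicates = as.integer(replicates),
        means = means, sds = sds,
        rOutcomeMeth = rOutcomeMeth, rOutcomeGran = rOutcomeGran,
        rMethGran = rMethGran,
        includeGranulocyte = isTRUE(includeGranulocyte),
        seed = as.integer(seed))
}

#' Closed-form probability that the methylation coefficient is positive
#'
#' Large-n normal approximation: the adjusted coefficient's sign follows the
#' partial correlation of outcome and methylation given granulocyte,
#' `rho_p = (r_ym - r_yg r_mg) / sqrt((1 - r_yg^2)(1 - r_mg^2))` (the
#' marginal `r_ym` when granulocyte is omitted), and the probability of a
#' positive fitted coefficient is
#' `Phi(rho_p sqrt(n) / sqrt(1 - rho_p^2))`. Serves as an independent
#' oracle for [runSignReversalExperiment()].
#'
#' @param spec a [SimulationSpec-class].
#' @return Probability in `[0, 1]`; exactly 0 or 1 when `|rho_p| = 1`.
#' @examples
#' analyticSignProbability(simulationSpec())
#' @export
analyticSignProbability <- function(spec) {
    stopifnot(is(spec, "SimulationSpec"))
    validObject(spec)
    rp <- if (spec@includeGranulocyte) {
        (spec@rOutcomeMeth - spec@rOutcomeGran * spec@rMethGran) /
            sqrt((1 - spec@rOutcomeGran^2) * (1 - spec@rMethGran^2))
    } else spec@rOutcomeMeth
    if (abs(rp) >= 1) return(if (rp > 0) 1 else 0)
    pnorm(rp * sqrt(spec@nPerReplicate) / sqrt(1 - rp^2))
}

#' Run the Monte-Carlo sign-reversal experiment
#'
#' Per replicate, draws `nPerReplicate` joint Gaussian observations of
#' (outcome, methylation, granulocyte) at the spec's correlations and fits
#' OLS of outcome on methylation (plus granulocyte when included, always
#' with intercept), recording the sign of the methylation coefficient.
#' Exactly zero coefficients (measure zero) count as non-positive. The
#' fraction positive is invariant to the means/SDs by construction, and the
#' whole experiment is deterministic given the seed.
#'
#' @param spec a [SimulationSpec-class].
#' @param retainBetas keep the per-replicate methylation coefficients.
#' @param scenario label stored on the result.
#' @return A [SignReversalResult-class], including the closed-form
#'   [analyticSignProbability()] for the same scenario.
#' @examples
#' res <- runSignReversalExperiment(simulationSpec(replicates = 200))
#' fractionPositive(res)
#' @export
runSignReversalExperiment <- function(spec, retainBetas = FALSE,
                                      scenario = NA_character_) {
    stopifnot(is(spec, "SimulationSpec"))
    validObject(spec)
    R <- .simCorrelation(spec)
    U <- chol(R)
    n <- spec@nPerReplicate
    set.seed(spec@seed)
    betas <- numeric(spec@replicates)
    for (b in seq_len(spec@replicates)) {
        X <- matrix(rnorm(n * 3L), n, 3L) %*% U
        X <- sweep(sweep(X, 2, spec@sds, `*`), 2, spec@means, `+`)
        y <- X[, 1] - mean(X[, 1])
        m <- X[, 2] - mean(X[, 2])
        if (spec@includeGranulocyte) {
            g <- X[, 3] - mean(X[, 3])
            smm <- sum(m^2); sgg <- sum(g^2); smg <- sum(m * g)
            sym <- sum(y * m); syg <- sum(y * g)
            betas[b] <- (sgg * sym - smg * syg) / (smm * sgg - smg^2)
        } else {
            betas[b] <- sum(y * m) / sum(m^2)
        }
    }
    p <- mean(betas > 0)
    if (is.na(scenario))
        scenario <- if (spec@includeGranulocyte)
            sprintf("r_mg=%.3g", spec@rMethGran) else "no granulocyte"
    new("SignReversalResult",
        fractionPositive = p, replicates = spec@replicates,
        mcSe = sqrt(p * (1 - p) / spec@replicates),
        betas = if (retainBetas) betas else numeric(0),
        rMethGran = spec@rMethGran,
        includeGranulocyte = spec@includeGranulocyte,
        analyticProbability = analyticSignProbability(spec),
        scenario = scenario)
}

#' Sweep the methylation-granulocyte correlation
#'
#' Re-runs the sign-reversal experiment for each requested
#' methylation-granulocyte correlation, plus one granulocyte-omitted
#' baseline. Each scenario uses an independent seeded substream derived
#' from the spec's seed by a fixed offset, so scenarios are independent but
#' the whole sweep is reproducible.
#'
#' @param spec a [SimulationSpec-class] (its `rMethGran` is ignored).
#' @param rValues methylation-granulocyte correlations to simulate.
#' @param retainBetas keep per-replicate coefficients on each result.
#' @return Named list of [SignReversalResult-class]: one per `rValues`
#'   entry, then `"no_granulocyte"`. Use [sweepSummary()] for a data.frame
#'   view.
#' @export
sweepCorrelations <- function(spec, rValues = c(-0.783, -0.5, -0.25),
                              retainBetas = FALSE) {
    stopifnot(is(spec, "SimulationSpec"))
    scen <- vector("list", length(rValues) + 1L)
    for (i in seq_along(rValues)) {
        s <- spec
        s@rMethGran <- rValues[i]
        s@includeGranulocyte <- TRUE
        s@seed <- spec@seed + i
        validObject(s)
        scen[[i]] <- runSignReversalExperiment(s, retainBetas)
    }
    s <- spec
    s@includeGranulocyte <- FALSE
    s@seed <- spec@seed + length(rValues) + 1L
    scen[[length(rValues) + 1L]] <-
        runSignReversalExperiment(s, retainBetas, scenario = "no granulocyte")
    names(scen) <- c(sprintf("r_mg=%.3g", rValues), "no_granulocyte")
    scen
}

#' Summarize a sign-reversal sweep
#'
#' @param results list of [SignReversalResult-class] as returned by
#'   [sweepCorrelations()].
#' @return data.frame with columns `scenario`, `rMethGran`,
#'   `includeGranulocyte`, `fractionPositive`, `mcSe`,
#'   `analyticProbability`.
#' @export
sweepSummary <- function(results) {
    do.call(rbind, lapply(results, function(r) data.frame(
        scenario = r@scenario,
        rMethGran = if (r@includeGranulocyte) r@rMethGran else NA_real_,
        includeGranulocyte = r@includeGranulocyte,
        fractionPositive = r@fractionPositive,
        mcSe = r@mcSe,
        analyticProbability = r@analyticProbability,
        row.names = NULL)))
}
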