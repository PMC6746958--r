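#' Construct a CohortSpec
#'
#' @param nParticipants cohort size.
#' @param outcomeMean,outcomeSd log-BMI mean and SD.
#' @param cpgNames CpG identifiers.
#' @param cpgMeans,cpgSds percent-methylation means and SDs (recycled).
#' @param cellMeans,cellSds proportion-scale means and SDs for the six cell
#'   types (order of [cellTypeNames()]).
#' @param correlationMatrix full target correlation matrix over
#'   `c("outcome", cpgNames, cellTypeNames())`, in that order. Dimnames are
#'   set if absent.
#' @param missingnessRates per-CpG fraction missing (recycled).
#' @param seed integer seed.
#' @return A [CohortSpec-class] object.
#' @seealso [defaultRaineLikeSpec()] for documented defaults,
#'   [generateCohort()] to sample from a spec.
#' @export
cohortSpec <- function(nParticipants, outcomeMean, outcomeSd,
                       cpgNames, cpgMeans, cpgSds,
                       cellMeans, cellSds, correlationMatrix,
                       missingnessRates = 0, seed = 1L) {
    nc <- length(cpgNames)
    vars <- c("outcome", cpgNames, .CELL_NAMES)
    if (is.null(dimnames(correlationMatrix)))
        dimnames(correlationMatrix) <- list(vars, vars)
    new("CohortSpec",
        nParticipants = as.integer(nParticipants),
        outcomeMean = outcomeMean, outcomeSd = outcomeSd,
        cpgNames = cpgNames,
        cpgMeans = rep_len(cpgMeans, nc), cpgSds = rep_len(cpgSds, nc),
        cellNames = .CELL_NAMES,
        cellMeans = rep_len(cellMeans, 6L), cellSds = rep_len(cellSds, 6L),
        correlationMatrix = correlationMatrix,
        missingnessRates = rep_len(missingnessRates, nc),
        seed = as.integer(seed))
}

## Published anchors for the default spec ------------------------------------
## CpG4 vs (CD8T, CD4T, NK, B, Mono, Gran) Pearson correlations.
.CPG4_CELL_COR <- c(0.611, 0.553, 0.371, 0.215, -0.402, -0.783)
## Outcome (log BMI) vs granulocyte proportion.
.OUT_GRAN_COR <- 0.16
## Unadjusted per-CpG association summaries (beta, se, n) used to derive the
## outcome-methylation correlations via r = t/sqrt(t^2 + df). The CpG4 se is
## reconstructed from its 95% CI rather than the (rounded) printed value.
.CPG_BETA <- c(0, 0.004, -0.004, -0.004, -0.003, -0.004, -0.004, -0.004, -0.004)
.CPG_SE <- c(0.001, 0.0029, 0.0019, NA, 0.001, 0.0012, 0.001, 0.0012, 0.0012)
.CPG_N <- c(780L, 758L, 723L, 812L, 790L, 778L, 740L, 801L, 760L)
## CpG vs first cell-proportion principal component, used only to scale how
## strongly each CpG loads on the shared cell-composition axis.
.CPG_PC1_COR <- c(-0.470, -0.329, -0.493, -0.671, -0.653, -0.700,
                  -0.645, -0.751, -0.727)

#' Standard error from a 95% confidence interval
#'
#' @param ciLow,ciHigh interval endpoints.
#' @param df residual degrees of freedom for the t quantile.
#' @return The implied standard error `(ciHigh - ciLow) / (2 t_{0.975, df})`.
#' @examples
#' seFromCi(-0.0065, -0.001, df = 808)
#' @export
seFromCi <- function(ciLow, ciHigh, df) {
    if (ciHigh <= ciLow) stop("'ciHigh' must exceed 'ciLow'")
    (ciHigh - ciLow) / (2 * qt(0.975, df))
}

## Assemble the default 16x16 target correlation matrix over
## (outcome, cpg1..cpg9, six cells) from a two-factor latent model:
##   M: shared cell-composition/inflammation axis. CpG4 loads g4 = 0.95, the
##      cells load r4/g4 so the CpG4-cell correlations reproduce the target
##      values exactly; other CpGs load in proportion to their (published)
##      correlation with the first cell-proportion PC, capped at CpG4's.
##   Q: cell-only factor reproducing the near-compositional degeneracy of
##      deconvolution estimates (granulocytes nearly determined by the other
##      five), which is what drives the extreme granulocyte VIF.
## Outcome correlations are pinned directly: with each CpG from the
## unadjusted association summaries, with granulocytes at 0.16, and with the
## other cells proportionally along the composition axis.
.defaultCorrelationMatrix <- function() {
    g4 <- 0.95
    h <- .CPG4_CELL_COR / g4
    kq <- c(0.65, 0.70, 0.55, 0.50, 0.45, -0.55)
    f <- pmin(.CPG_PC1_COR / .CPG_PC1_COR[4], 1)
    g <- f * g4
    se <- .CPG_SE
    se[4] <- seFromCi(-0.0065, -0.001, df = .CPG_N[4] - 4)
    rOutCpg <- correlationFromT(.CPG_BETA, se, .CPG_N, kCovariates = 2L)
    load <- c(0, g, h)
    R <- outer(load, load)
    kfull <- c(rep(0, 10), kq)
    R <- R + outer(kfull, kfull)
    diag(R) <- 1
    R[1, 2:10] <- R[2:10, 1] <- rOutCpg
    R[1, 11:16] <- R[11:16, 1] <- .OUT_GRAN_COR * (h / h[6])
    vars <- c("outcome", paste0("cpg", 1:9), .CELL_NAMES)
    dimnames(R) <- list(vars, vars)
    R
}

#' Default synthetic-cohort specification
#'
#' A documented nine-CpG, six-cell specification echoing the structure of a
#' population cohort of 812 adolescents: the CpG4-cell correlations are set
#' to the published values (0.611, 0.553, 0.371, 0.215, -0.402, -0.783 for
#' CD8 T, CD4 T, NK, B, monocytes, granulocytes), the outcome-granulocyte
#' correlation to 0.16, outcome-CpG correlations are derived from the
#' unadjusted per-CpG association summaries via [correlationFromT()], and
#' per-CpG missingness reproduces the published complete-case counts.
#'
#' Means and SDs of BMI, methylation and cell proportions are placeholders
#' (not published values): BMI is log-normal with median 22 kg/m^2, CpG
#' methylation averages 50% with SD 3.75, and cell-proportion means/SDs are
#' typical of Houseman whole-blood estimates. All downstream collinearity
#' behaviour depends only on the correlations and n, not on these
#' placeholders.
#'
#' @param nParticipants cohort size (default 812).
#' @param seed integer seed.
#' @return A [CohortSpec-class] object. Calling twice returns identical specs.
#' @examples
#' spec <- defaultRaineLikeSpec()
#' spec@correlationMatrix["cpg4", "gran"]
#' @export
defaultRaineLikeSpec <- function(nParticipants = 812L, seed = 1L) {
    cohortSpec(
        nParticipants = nParticipants,
        outcomeMean = log(22), outcomeSd = 0.15,
        cpgNames = paste0("cpg", 1:9),
        cpgMeans = 50, cpgSds = 3.75,
        cellMeans = c(0.08, 0.18, 0.05, 0.06, 0.09, 0.55),
        cellSds = c(0.025, 0.055, 0.015, 0.018, 0.025, 0.077),
        correlationMatrix = .defaultCorrelationMatrix(),
        missingnessRates = 1 - .CPG_N / 812,
        seed = seed)
}

#' Read / write a CohortSpec as JSON
#'
#' The JSON document mirrors the slot names of [CohortSpec-class]; the
#' correlation matrix is stored as a nested array with a separate
#' `variableNames` field.
#'
#' @param path file path.
#' @param spec a [CohortSpec-class] object.
#' @return `readCohortSpec` returns a [CohortSpec-class];
#'   `writeCohortSpec` returns `path` invisibly.
#' @export
readCohortSpec <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    R <- as.matrix(x$correlationMatrix)
    dimnames(R) <- list(x$variableNames, x$variableNames)
    cohortSpec(
        nParticipants = x$nParticipants,
        outcomeMean = x$outcomeMean, outcomeSd = x$outcomeSd,
        cpgNames = x$cpgNames, cpgMeans = x$cpgMeans, cpgSds = x$cpgSds,
        cellMeans = x$cellMeans, cellSds = x$cellSds,
        correlationMatrix = R,
        missingnessRates = x$missingnessRates, seed = x$seed)
}

#' @rdname readCohortSpec
#' @export
writeCohortSpec <- function(spec, path) {
    stopifnot(is(spec, "CohortSpec"))
    x <- list(
        nParticipants = spec@nParticipants,
        outcomeMean = spec@outcomeMean, outcomeSd = spec@outcomeSd,
        cpgNames = spec@cpgNames, cpgMeans = spec@cpgMeans,
        cpgSds = spec@cpgSds, cellNames = spec@cellNames,
        cellMeans = spec@cellMeans, cellSds = spec@cellSds,
        variableNames = colnames(spec@correlationMatrix),
        correlationMatrix = unname(spec@correlationMatrix),
        missingnessRates = spec@missingnessRates, seed = spec@seed)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
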