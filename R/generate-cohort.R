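#' Generate a synthetic methylation cohort
#'
#' Samples a cohort from the joint Gaussian model described by a
#' [CohortSpec-class]: one log-scale outcome (exponentiated to raw BMI), CpG
#' percent-methylation values and six cell proportions, plus independent age
#' (Normal, mean 17, SD 0.25) and sex (Bernoulli 0.5). Methylation is clipped
#' to `[0, 100]` and proportions to `[0, 1]`; at the default spec parameters
#' clipping touches well under 0.1% of draws. Per-CpG missingness is applied
#' completely at random. The same seed reproduces the identical cohort.
#'
#' @param spec a [CohortSpec-class].
#' @param repair if `TRUE`, a non-positive-definite target correlation matrix
#'   is repaired with [nearestPositiveDefinite()] instead of erroring.
#' @return A [MethylCohort-class].
#' @examples
#' cohort <- generateCohort(defaultRaineLikeSpec(nParticipants = 200))
#' cohort
#' @export
generateCohort <- function(spec, repair = FALSE) {
    stopifnot(is(spec, "CohortSpec"))
    validObject(spec)
    n <- spec@nParticipants
    means <- c(spec@outcomeMean, spec@cpgMeans, spec@cellMeans)
    sds <- c(spec@outcomeSd, spec@cpgSds, spec@cellSds)
    X <- correlatedGaussianSample(n, means, sds, spec@correlationMatrix,
                                  seed = spec@seed, repair = repair)
    nc <- length(spec@cpgNames)
    logBmi <- X[, 1]
    meth <- X[, 1 + seq_len(nc), drop = FALSE]
    cells <- X[, 1 + nc + 1:6, drop = FALSE]
    meth <- pmin(pmax(meth, 0), 100)
    cells <- pmin(pmax(cells, 0), 1)
    ## age/sex and missingness use the stream continued from the joint draw
    age <- rnorm(n, 17, 0.25)
    sex <- rbinom(n, 1L, 0.5)
    for (j in seq_len(nc)) {
        rate <- spec@missingnessRates[j]
        if (rate > 0) meth[runif(n) < rate, j] <- NA_real_
    }
    ids <- sprintf("P%04d", seq_len(n))
    assay <- t(meth)
    dimnames(assay) <- list(spec@cpgNames, ids)
    cd <- S4Vectors::DataFrame(
        age = age, sex = sex, bmi = exp(logBmi),
        as.data.frame(cells), row.names = ids)
    colnames(cd)[4:9] <- .CELL_NAMES
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(methylation = assay), colData = cd)
    new("MethylCohort", se)
}

#' Convert a MethylCohort to the flat participant table
#'
#' One row per participant with columns
#' `participant_id, age, sex, bmi, <cpgs...>, cd8t, cd4t, nk, bcell, mono,
#' gran`.
#'
#' @param cohort a [MethylCohort-class].
#' @return A `data.frame`.
#' @export
cohortToTable <- function(cohort) {
    stopifnot(is(cohort, "MethylCohort"))
    cd <- SummarizedExperiment::colData(cohort)
    data.frame(
        participant_id = colnames(cohort),
        age = cd$age, sex = cd$sex, bmi = cd$bmi,
        as.data.frame(t(methylation(cohort))),
        as.data.frame(cd[, .CELL_NAMES]),
        row.names = NULL, check.names = FALSE)
}

#' Read / write a cohort CSV
#'
#' CSV header: `participant_id,age,sex,bmi,<cpg columns...>,cd8t,cd4t,nk,
#' bcell,mono,gran`; missing methylation is an empty field.
#'
#' @param cohort a [MethylCohort-class].
#' @param path file path.
#' @return `readCohortCsv` returns a [MethylCohort-class];
#'   `writeCohortCsv` returns `path` invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
    write.csv(cohortToTable(cohort), path, row.names = FALSE, na = "")
    invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
    df <- read.csv(path, check.names = FALSE)
    need <- c("participant_id", "age", "sex", "bmi", .CELL_NAMES)
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("cohort CSV is missing columns: ", paste(miss, collapse = ", "))
    cpgs <- setdiff(names(df), need)
    assay <- t(as.matrix(df[, cpgs, drop = FALSE]))
    colnames(assay) <- df$participant_id
    cd <- S4Vectors::DataFrame(
        age = df$age, sex = df$sex, bmi = df$bmi,
        df[, .CELL_NAMES], row.names = df$participant_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(methylation = assay), colData = cd)
    new("MethylCohort", se)
}
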