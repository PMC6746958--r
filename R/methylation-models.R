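.modelFrame <- function(cohort, cpg, cells = character()) {
    m <- methylation(cohort)
    if (!cpg %in% rownames(m))
        stop(sprintf("unknown CpG '%s'", cpg))
    cd <- SummarizedExperiment::colData(cohort)
    if (any(cd$bmi <= 0, na.rm = TRUE))
        stop("BMI must be strictly positive for the log transform")
    df <- data.frame(m[cpg, ], cd$age, cd$sex, check.names = FALSE)
    names(df) <- c(cpg, "age", "sex")
    for (cl in cells) df[[cl]] <- cd[[cl]]
    list(outcome = log(cd$bmi), design = df)
}

.adjustmentCells <- function(adjustment) {
    switch(adjustment,
        none = character(),
        six_cell = .CELL_NAMES,
        five_cell_no_gran = setdiff(.CELL_NAMES, "gran"),
        stop(sprintf("unknown adjustment '%s'", adjustment)))
}

#' Fit the methylation-BMI model for one CpG
#'
#' Regresses log-transformed BMI on percent methylation at one CpG, adjusted
#' for age and sex and optionally for estimated cell proportions. Rows with
#' a missing value in any fitted variable are dropped per model, so each CpG
#' has its own complete-case count.
#'
#' @param cohort a [MethylCohort-class].
#' @param cpg CpG name (a row of the methylation assay).
#' @param adjustment `"none"` (age/sex only), `"six_cell"` (adds all six
#'   cell proportions) or `"five_cell_no_gran"` (cells without
#'   granulocytes).
#' @return A [RegressionFit-class]; the methylation coefficient is the change
#'   in log BMI per one percentage-point increase in methylation.
#' @examples
#' cohort <- generateCohort(defaultRaineLikeSpec())
#' fitMethylationModel(cohort, "cpg4", "none")
#' @export
fitMethylationModel <- function(cohort, cpg,
                                adjustment = c("none", "six_cell",
                                               "five_cell_no_gran")) {
    if (is.character(adjustment) && length(adjustment) == 1 &&
        !adjustment %in% c("none", "six_cell", "five_cell_no_gran"))
        stop(sprintf("unknown adjustment '%s'", adjustment))
    adjustment <- match.arg(adjustment)
    mf <- .modelFrame(cohort, cpg, .adjustmentCells(adjustment))
    fitOls(mf$outcome, mf$design,
           label = sprintf("%s | %s", cpg, adjustment))
}

#' Compare model families for one CpG
#'
#' Fits the unadjusted, six-cell and five-cell (granulocyte-dropped)
#' families and flags sign reversal / significance change of the
#' methylation coefficient between the unadjusted and six-cell fits.
#'
#' @inheritParams fitMethylationModel
#' @param alpha significance level for the change flag.
#' @return A list with the three fits (`none`, `six_cell`,
#'   `five_cell_no_gran`) and the comparison flags.
#' @export
compareModelFamilies <- function(cohort, cpg, alpha = 0.05) {
    fits <- lapply(c(none = "none", six_cell = "six_cell",
                     five_cell_no_gran = "five_cell_no_gran"),
                   function(a) fitMethylationModel(cohort, cpg, a))
    flags <- detectSignReversal(fits$none, fits$six_cell, cpg, alpha)
    c(fits, list(flags = flags))
}
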