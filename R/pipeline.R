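#' Assemble a pipeline configuration
#'
#' @param spec a [CohortSpec-class], or `NULL` when `cohortCsv` is given.
#' @param cohortCsv path to an existing cohort CSV (overrides `spec`).
#' @param cpgs CpG names to analyse; `NULL` means all CpGs in the cohort.
#' @param focalCpg CpG used for the VIF table (default first of `cpgs`).
#' @param stages character subset of
#'   `c("table1", "table2", "table3", "table4", "sim")`.
#' @param threshold,topK high-correlation screen options (reserved for
#'   screen-containing stage lists).
#' @param simSpec a [SimulationSpec-class] for the sign-reversal sweep.
#' @param rValues correlations swept by the simulation stage.
#' @param outDir output directory (created if missing).
#' @param seed master seed; stage seeds derive from it by fixed offsets.
#' @param alpha significance level for change flags.
#' @return A validated configuration list for [runPipeline()].
#' @export
pipelineConfig <- function(spec = defaultRaineLikeSpec(), cohortCsv = NULL,
                           cpgs = NULL, focalCpg = NULL,
                           stages = c("table1", "table2", "table3",
                                      "table4", "sim"),
                           threshold = 0.700, topK = 50L,
                           simSpec = simulationSpec(),
                           rValues = c(-0.783, -0.5, -0.25),
                           outDir = "collinear-ewas-output", seed = 1L,
                           alpha = 0.05) {
    stages <- match.arg(stages, several.ok = TRUE)
    if (!is.null(cohortCsv) && !file.exists(cohortCsv))
        stop("cohort CSV does not exist: ", cohortCsv)
    if (is.null(cohortCsv) && is.null(spec))
        stop("either 'spec' or 'cohortCsv' is required")
    if (length(stages) == 0L) stop("at least one stage must be enabled")
    list(spec = spec, cohortCsv = cohortCsv, cpgs = cpgs,
         focalCpg = focalCpg, stages = stages, threshold = threshold,
         topK = as.integer(topK), simSpec = simSpec, rValues = rValues,
         outDir = outDir, seed = as.integer(seed), alpha = alpha)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

.fitRow <- function(fit, cpg, family) {
    cf <- .getTerm(fit, cpg)
    data.frame(cpg = cpg, family = family, beta = cf$beta, se = cf$se,
               ciLow = cf$ciLow, ciHigh = cf$ciHigh, p = cf$p,
               n = nUsed(fit), rSquared = rSquared(fit), row.names = NULL)
}

#' Run the full analysis pipeline
#'
#' Orchestrates cohort generation (or loading), the regression battery
#' across model families with reversal flags, CpG-cell correlations, VIF
#' diagnostics with and without granulocytes, CpG-PC correlations, and the
#' sign-reversal sweep. Each enabled stage writes one TSV to the output
#' directory (`table1.tsv`, `table2.tsv`, `table3.tsv`, `table4.tsv`,
#' `sim.tsv`) plus a `manifest.json` recording the seed, configuration hash
#' and package version. Re-running with an identical configuration
#' reproduces byte-identical outputs.
#'
#' @param config list from [pipelineConfig()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the output file paths and the manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), quiet = FALSE) {
    say <- function(...) if (!quiet) message(...)
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    files <- list()

    cohort <- if (!is.null(config$cohortCsv)) {
        say("stage cohort: reading ", config$cohortCsv)
        readCohortCsv(config$cohortCsv)
    } else {
        spec <- config$spec
        spec@seed <- config$seed
        say("stage cohort: generating n=", spec@nParticipants)
        generateCohort(spec)
    }
    cpgs <- if (is.null(config$cpgs)) rownames(cohort) else config$cpgs
    focal <- if (is.null(config$focalCpg)) cpgs[[1]] else config$focalCpg

    if ("table1" %in% config$stages) {
        say("stage table1: model families for ", length(cpgs), " CpGs")
        rows <- lapply(cpgs, function(cpg) {
            fits <- list(
                unadjusted = fitMethylationModel(cohort, cpg, "none"),
                six_cell = fitMethylationModel(cohort, cpg, "six_cell"),
                five_cell_no_gran =
                    fitMethylationModel(cohort, cpg, "five_cell_no_gran"),
                pc_substituted = pcSubstituteRefit(cohort, cpg, k = 2L),
                residualized_all = residualRefit(cohort, cpg, "all")[[1]])
            tab <- do.call(rbind, Map(.fitRow, fits, cpg, names(fits)))
            flags <- detectSignReversal(fits$unadjusted, fits$six_cell,
                                        cpg, config$alpha)
            tab$reversalVsUnadjusted <- flags$reversal
            tab$significanceChange <- flags$significanceChange
            tab
        })
        files$table1 <- .writeTsv(do.call(rbind, rows),
                                  file.path(config$outDir, "table1.tsv"))
    }
    if ("table2" %in% config$stages) {
        say("stage table2: CpG-cell correlations")
        cm <- cpgCellCorrelations(cohort, "pearson")
        r <- corEstimates(cm)[cpgs, .CELL_NAMES, drop = FALSE]
        p <- corPValues(cm)[cpgs, .CELL_NAMES, drop = FALSE]
        n <- corCounts(cm)[cpgs, .CELL_NAMES, drop = FALSE]
        tab <- data.frame(
            cpg = rep(rownames(r), times = ncol(r)),
            cell = rep(colnames(r), each = nrow(r)),
            r = as.vector(r), p = as.vector(p), n = as.vector(n))
        files$table2 <- .writeTsv(tab, file.path(config$outDir, "table2.tsv"))
    }
    if ("table3" %in% config$stages) {
        say("stage table3: VIF diagnostics for ", focal)
        v6 <- vifTable(vifForModel(cohort, focal, "six_cell"))
        v5 <- vifTable(vifForModel(cohort, focal, "five_cell_no_gran"))
        names(v6)[-1] <- paste0(names(v6)[-1], "_sixCell")
        names(v5)[-1] <- paste0(names(v5)[-1], "_noGran")
        tab <- merge(v6, v5, by = "term", all = TRUE, sort = FALSE)
        files$table3 <- .writeTsv(tab, file.path(config$outDir, "table3.tsv"))
    }
    if ("table4" %in% config$stages) {
        say("stage table4: CpG-PC correlations")
        pca <- pcaCells(cohort)
        sc <- pcScores(pca)[match(colnames(cohort), rownames(pcScores(pca))),
                            1:2, drop = FALSE]
        df <- cbind(as.data.frame(t(methylation(cohort)[cpgs, , drop = FALSE])),
                    PC1 = sc[, 1], PC2 = sc[, 2])
        cm <- correlationMatrix(df, "pearson")
        tab <- data.frame(
            cpg = rep(cpgs, 2),
            pc = rep(c("PC1", "PC2"), each = length(cpgs)),
            r = c(corEstimates(cm)[cpgs, "PC1"], corEstimates(cm)[cpgs, "PC2"]),
            p = c(corPValues(cm)[cpgs, "PC1"], corPValues(cm)[cpgs, "PC2"]),
            n = c(corCounts(cm)[cpgs, "PC1"], corCounts(cm)[cpgs, "PC2"]))
        files$table4 <- .writeTsv(tab, file.path(config$outDir, "table4.tsv"))
    }
    if ("sim" %in% config$stages) {
        say("stage sim: sign-reversal sweep")
        s <- config$simSpec
        s@seed <- config$seed + 1000L
        files$sim <- .writeTsv(sweepSummary(sweepCorrelations(s, config$rValues)),
                               file.path(config$outDir, "sim.tsv"))
    }

    cfgJson <- jsonlite::serializeJSON(config)
    tmp <- tempfile(); writeLines(as.character(cfgJson), tmp)
    manifest <- list(
        seed = config$seed,
        stages = config$stages,
        configHash = unname(tools::md5sum(tmp)),
        package = "collinearEwas",
        packageVersion = as.character(utils::packageVersion("collinearEwas")),
        rVersion = paste(R.version$major, R.version$minor, sep = "."),
        files = lapply(files, basename))
    unlink(tmp)
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(files = files,
                   manifest = file.path(config$outDir, "manifest.json")))
}
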