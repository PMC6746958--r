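test_that("dropPredictorRefit equals a manually assembled five-cell fit", {
    cohort <- defaultCohort()
    refit <- dropPredictorRefit(cohort, "cpg4", drop = "gran")
    manual <- fitMethylationModel(cohort, "cpg4", "five_cell_no_gran")
    expect_equal(coefTable(refit)$beta, coefTable(manual)$beta)
    expect_error(dropPredictorRefit(cohort, "cpg4", "platelets"),
                 "unknown cell type")
})

test_that("dropping an orthogonalized noise cell leaves the CpG beta unchanged", {
    cohort <- defaultCohort(n = 400L, seed = 17L)
    mf <- cbind(cpg4 = methylation(cohort)["cpg4", ],
                age = SummarizedExperiment::colData(cohort)$age,
                sex = SummarizedExperiment::colData(cohort)$sex,
                cellProportions(cohort)[, setdiff(cellTypeNames(), "nk")])
    set.seed(171)
    noise <- residuals(lm(rnorm(400) ~ mf))
    SummarizedExperiment::colData(cohort)$nk <-
        0.5 + 0.01 * noise / max(abs(noise))
    with6 <- fitMethylationModel(cohort, "cpg4", "six_cell")
    without <- dropPredictorRefit(cohort, "cpg4", drop = "nk")
    b6 <- coefTable(with6)$beta[coefTable(with6)$term == "cpg4"]
    b5 <- coefTable(without)$beta[coefTable(without)$term == "cpg4"]
    expect_equal(b5, b6, tolerance = 1e-6)
})

test_that("PCA of collinear cells puts all variance on the first component", {
    cohort <- defaultCohort(n = 100L, seed = 18L)
    u <- seq(0, 1, length.out = 100)
    cells <- outer(u - 0.5, c(0.05, 0.04, 0.03, 0.02, 0.01, -0.06)) + 0.3
    cd <- SummarizedExperiment::colData(cohort)
    for (i in seq_along(cellTypeNames())) cd[[cellTypeNames()[i]]] <- cells[, i]
    SummarizedExperiment::colData(cohort) <- cd
    pca <- pcaCells(cohort)
    expect_equal(varianceExplained(pca)[1], 1, tolerance = 1e-10)
})

test_that("PCA matches an eigendecomposition oracle up to sign", {
    cohort <- defaultCohort(n = 60L, seed = 19L)
    cells <- cellProportions(cohort)
    pca <- pcaCells(cohort)
    e <- eigen(cov(cells), symmetric = TRUE)
    expect_equal(varianceExplained(pca),
                 e$values / sum(e$values), tolerance = 1e-10)
    for (j in 1:6)
        expect_equal(abs(pcLoadings(pca)[, j]), abs(e$vectors[, j]),
                     tolerance = 1e-8, ignore_attr = TRUE)
    # deterministic sign convention: dominant loading positive
    for (j in 1:6) {
        l <- pcLoadings(pca)[, j]
        expect_gt(l[which.max(abs(l))], 0)
    }
})

test_that("near-isotropic cells spread variance across components", {
    cohort <- defaultCohort(n = 5000L, seed = 20L)
    cd <- SummarizedExperiment::colData(cohort)
    set.seed(201)
    for (cl in cellTypeNames()) cd[[cl]] <- runif(5000, 0.3, 0.5)
    SummarizedExperiment::colData(cohort) <- cd
    v <- varianceExplained(pcaCells(cohort))
    expect_true(all(abs(v - 1 / 6) < 0.05))
})

test_that("substituting all six PCs reproduces the six-cell coefficient", {
    cohort <- defaultCohort()
    f6 <- fitMethylationModel(cohort, "cpg4", "six_cell")
    p6 <- pcSubstituteRefit(cohort, "cpg4", k = 6)
    b <- function(f) coefTable(f)$beta[coefTable(f)$term == "cpg4"]
    expect_equal(b(p6), b(f6), tolerance = 1e-8)
    expect_error(pcSubstituteRefit(cohort, "cpg4", k = 7), "between 1 and 6")
    expect_error(pcSubstituteRefit(cohort, "cpg4", k = 0), "between 1 and 6")
})

test_that("k = 2 substitution equals a manual design with the score columns", {
    cohort <- defaultCohort()
    p2 <- pcSubstituteRefit(cohort, "cpg4", k = 2)
    pca <- pcaCells(cohort)
    sc <- pcScores(pca)[match(colnames(cohort), rownames(pcScores(pca))), 1:2]
    design <- data.frame(cpg4 = methylation(cohort)["cpg4", ],
                         age = SummarizedExperiment::colData(cohort)$age,
                         sex = SummarizedExperiment::colData(cohort)$sex,
                         PC1 = sc[, 1], PC2 = sc[, 2])
    manual <- fitOls(log(bmi(cohort)), design)
    expect_equal(coefTable(p2)$beta, coefTable(manual)$beta, tolerance = 1e-12)
})

test_that("CpG methylation correlates strongly negatively with PC1", {
    cohort <- defaultCohort()
    pca <- pcaCells(cohort)
    sc <- pcScores(pca)[match(colnames(cohort), rownames(pcScores(pca))), 1]
    r <- cor(methylation(cohort)["cpg4", ], sc, use = "complete.obs")
    expect_lt(r, -0.3)
})

test_that("residualized methylation is orthogonal to the removed covariates", {
    cohort <- defaultCohort()
    fits <- residualRefit(cohort, "cpg4", "each")
    expect_named(fits, cellTypeNames())
    cells <- cellProportions(cohort)
    meth <- methylation(cohort)["cpg4", ]
    for (cl in cellTypeNames()) {
        keep <- !is.na(meth)
        r <- residuals(lm(meth[keep] ~ cells[keep, cl]))
        expect_lt(abs(sum(r * cells[keep, cl])),
                  1e-8 * sqrt(sum(r^2) * sum(cells[keep, cl]^2)))
    }
    allFit <- residualRefit(cohort, "cpg4", "all")
    expect_length(allFit, 1L)
    expect_error(residualRefit(cohort, "cpg4", "some"), "unknown mode")
})

test_that("Frisch-Waugh residualization reproduces the six-cell coefficient", {
    cohort <- defaultCohort()
    f6 <- fitMethylationModel(cohort, "cpg4", "six_cell")
    fw <- residualRefit(cohort, "cpg4", "all_with_covariates")[[1]]
    b <- function(f) coefTable(f)$beta[coefTable(f)$term == "cpg4"]
    expect_equal(b(fw), b(f6), tolerance = 1e-8)
})

test_that("residualizing a variable on itself is degenerate and errors", {
    cohort <- defaultCohort(n = 100L, seed = 23L)
    cd <- SummarizedExperiment::colData(cohort)
    m <- methylation(cohort)["cpg4", ]
    cd$gran <- pmin(pmax(m / 100, 0), 1)  # gran is the CpG, rescaled
    SummarizedExperiment::colData(cohort) <- cd
    expect_error(residualRefit(cohort, "cpg4", "all"), "constant")
})
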