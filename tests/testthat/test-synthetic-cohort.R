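test_that("the default spec pins the published correlation anchors", {
    spec <- defaultRaineLikeSpec()
    R <- spec@correlationMatrix
    expect_equal(unname(R["cpg4", cellTypeNames()]),
                 c(0.611, 0.553, 0.371, 0.215, -0.402, -0.783))
    expect_equal(R["outcome", "gran"], 0.16)
    expect_equal(R["outcome", "cpg4"], -0.0999, tolerance = 1e-3)
    expect_identical(defaultRaineLikeSpec(), defaultRaineLikeSpec())
    expect_true(validObject(spec))
})

test_that("generated cohorts satisfy the table invariants", {
    cohort <- defaultCohort()
    cells <- cellProportions(cohort)
    expect_true(all(cells >= 0 & cells <= 1))
    m <- methylation(cohort)
    expect_true(all(m >= 0 & m <= 100, na.rm = TRUE))
    expect_gt(mean(rowSums(cells)), 0.95)
    expect_lt(mean(rowSums(cells)), 1.10)
    expect_true(all(bmi(cohort) > 0))
})

test_that("empirical correlations recover the spec targets at large n", {
    big <- defaultCohort(n = 1e5L, seed = 3L)
    spec <- defaultRaineLikeSpec()
    cm <- cpgCellCorrelations(big, "pearson")
    got <- corEstimates(cm)["cpg4", cellTypeNames()]
    want <- spec@correlationMatrix["cpg4", cellTypeNames()]
    expect_lt(max(abs(unname(got) - unname(want))), 0.02)
    expect_lt(abs(cor(log(bmi(big)), cellProportions(big)[, "gran"]) - 0.16),
              0.02)
})

test_that("clipping leaves cell-proportion means essentially unbiased", {
    big <- defaultCohort(n = 1e5L, seed = 3L)
    spec <- defaultRaineLikeSpec()
    bias <- abs(colMeans(cellProportions(big)) - spec@cellMeans)
    expect_true(all(bias < 0.01))
})

test_that("per-CpG missingness yields the expected complete-case counts", {
    spec <- defaultRaineLikeSpec(seed = 5L)
    cohort <- generateCohort(spec)
    counts <- rowSums(!is.na(methylation(cohort)))
    expected <- spec@nParticipants * (1 - spec@missingnessRates)
    sds <- sqrt(spec@nParticipants * spec@missingnessRates *
                (1 - spec@missingnessRates))
    expect_true(all(abs(counts - expected) <= pmax(3 * sds, 1)))
    expect_equal(unname(counts["cpg4"]), 812)  # zero missingness CpG
})

test_that("the same seed reproduces a byte-identical cohort CSV", {
    spec <- defaultRaineLikeSpec(nParticipants = 150L, seed = 11L)
    f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
    writeCohortCsv(generateCohort(spec), f1)
    writeCohortCsv(generateCohort(spec), f2)
    expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
    header <- readLines(f1, n = 1)
    expect_match(header, "^\"?participant_id\"?,\"?age")
    unlink(c(f1, f2))
})

test_that("cohort CSV and spec JSON round-trip", {
    spec <- defaultRaineLikeSpec(nParticipants = 120L, seed = 2L)
    cohort <- generateCohort(spec)
    f <- tempfile(fileext = ".csv")
    writeCohortCsv(cohort, f)
    back <- readCohortCsv(f)
    expect_equal(methylation(back), methylation(cohort), tolerance = 1e-12)
    expect_equal(cellProportions(back), cellProportions(cohort),
                 tolerance = 1e-12)
    j <- tempfile(fileext = ".json")
    writeCohortSpec(spec, j)
    spec2 <- readCohortSpec(j)
    expect_equal(spec2@correlationMatrix, spec@correlationMatrix)
    expect_equal(spec2@missingnessRates, spec@missingnessRates,
                 tolerance = 1e-12)
    unlink(c(f, j))
})

test_that("a spec with an all-zero off-diagonal block keeps compositional means", {
    spec <- defaultRaineLikeSpec(nParticipants = 5000L, seed = 4L)
    p <- nrow(spec@correlationMatrix)
    spec@correlationMatrix <- diag(p)
    dimnames(spec@correlationMatrix) <-
        list(c("outcome", spec@cpgNames, cellTypeNames()),
             c("outcome", spec@cpgNames, cellTypeNames()))
    cohort <- generateCohort(spec)
    expect_gt(mean(rowSums(cellProportions(cohort))), 0.95)
    expect_lt(mean(rowSums(cellProportions(cohort))), 1.10)
})

test_that("non-completable spec matrices error with repair advice", {
    spec <- defaultRaineLikeSpec(nParticipants = 100L)
    R <- spec@correlationMatrix
    R["cpg1", "cpg2"] <- R["cpg2", "cpg1"] <- -0.99  # cpg1, cpg2 both ~ cpg4
    spec@correlationMatrix <- R
    expect_error(generateCohort(spec), "nearestPositiveDefinite")
    expect_message(cohort <- generateCohort(spec, repair = TRUE), "Frobenius")
    expect_s4_class(cohort, "MethylCohort")
})
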