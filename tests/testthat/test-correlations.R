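test_that("exact linear association gives pearson r = 1", {
    cm <- correlationMatrix(data.frame(x = c(1, 2, 3), y = c(2, 4, 6)))
    expect_equal(corEstimates(cm)["x", "y"], 1)
})

test_that("spearman is invariant under strictly monotone transforms", {
    set.seed(41)
    x <- rnorm(60); y <- x + rnorm(60)
    r1 <- corEstimates(correlationMatrix(data.frame(x, y), "spearman"))["x", "y"]
    r2 <- corEstimates(correlationMatrix(data.frame(x = exp(x), y = y^3 + y),
                                         "spearman"))["x", "y"]
    expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("estimates and p-values match direct formula evaluation on 6 points", {
    x <- c(1.2, 3.4, 2.2, 5.1, 4.0, 0.5)
    y <- c(2.0, 3.1, 2.5, 4.9, 5.2, 1.1)
    cm <- correlationMatrix(data.frame(x, y), "pearson")
    # product-moment formula from first principles
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t <- r * sqrt(4 / (1 - r^2))
    p <- 2 * pt(abs(t), 4, lower.tail = FALSE)
    expect_equal(corEstimates(cm)["x", "y"], r, tolerance = 1e-12)
    expect_equal(corPValues(cm)["x", "y"], p, tolerance = 1e-12)
    # spearman via average ranks
    cs <- correlationMatrix(data.frame(x, y), "spearman")
    rs <- cor(rank(x), rank(y))
    expect_equal(corEstimates(cs)["x", "y"], rs, tolerance = 1e-12)
})

test_that("pairwise complete-case counts track missingness", {
    x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
    x[1:3] <- NA; y[3:5] <- NA
    cm <- correlationMatrix(data.frame(x, y, z))
    expect_identical(corCounts(cm)["x", "y"], 15L)
    expect_identical(corCounts(cm)["x", "z"], 17L)
    expect_identical(corCounts(cm)["z", "z"], 20L)
    expect_error(correlationMatrix(data.frame(x = c(NA, NA, 1:2), y = 1:4)),
                 "fewer than 3")
})

test_that("a constant column warns and yields NA", {
    expect_warning(cm <- correlationMatrix(data.frame(x = rep(1, 10),
                                                      y = rnorm(10))),
                   "constant")
    expect_true(is.na(corEstimates(cm)["x", "y"]))
})

test_that("the screen flags constructed high-correlation CpGs", {
    set.seed(43)
    n <- 1000; nCpg <- 1000; nHot <- 50
    gran <- rnorm(n)
    cells <- matrix(runif(n * 6, 0.05, 0.6), n, 6,
                    dimnames = list(sprintf("P%04d", 1:n), cellTypeNames()))
    cells[, "gran"] <- pmin(pmax(0.55 + 0.077 * gran, 0), 1)
    meth <- matrix(rnorm(nCpg * n), nCpg, n,
                   dimnames = list(paste0("cg", seq_len(nCpg)),
                                   rownames(cells)))
    # population pearson 0.95 -> spearman ~ (6/pi) asin(0.95/2) ~ 0.94
    meth[1:nHot, ] <- t(0.95 * gran + sqrt(1 - 0.95^2) *
                        matrix(rnorm(n * nHot), n, nHot))
    meth <- 50 + 3 * meth
    meth <- pmin(pmax(meth, 0), 100)
    rep <- highCorrelationScreen(meth, cells, threshold = 0.700, topK = 10)
    got <- rep@summary$nFlagged[rep@summary$cell == "gran"]
    expect_lt(abs(got - nHot), 3 * sqrt(nHot * 0.05 * 0.95) + 1)
    others <- rep@summary$nFlagged[rep@summary$cell != "gran"]
    expect_true(all(others <= 2))
    top <- rep@top$gran
    expect_identical(nrow(top), 10L)
    expect_true(all(diff(abs(top$r)) <= 1e-12))
    expect_true(all(top$cpg %in% paste0("cg", 1:nHot)))
})

test_that("an all-independent matrix yields an empty screen", {
    set.seed(44)
    n <- 1000
    cells <- matrix(runif(n * 6), n, 6,
                    dimnames = list(sprintf("P%04d", 1:n), cellTypeNames()))
    meth <- matrix(runif(200 * n, 0, 100), 200, n,
                   dimnames = list(paste0("cg", 1:200), rownames(cells)))
    rep <- highCorrelationScreen(meth, cells, threshold = 0.700)
    expect_true(all(rep@summary$nFlagged == 0))
})

test_that("a monotone transform of a cell column is always flagged", {
    set.seed(45)
    n <- 200
    cells <- matrix(runif(n * 6), n, 6,
                    dimnames = list(sprintf("P%04d", 1:n), cellTypeNames()))
    meth <- rbind(cg1 = 100 / (1 + exp(-5 * (cells[, "gran"] - 0.5))),
                  cg2 = runif(n, 0, 100))
    colnames(meth) <- rownames(cells)
    rep <- highCorrelationScreen(meth, cells, threshold = 0.999)
    expect_identical(rep@top$gran$cpg[1], "cg1")
    expect_equal(rep@top$gran$r[1], 1)
})

test_that("screen counts are monotone non-increasing in the threshold", {
    set.seed(46)
    n <- 300
    cells <- matrix(runif(n * 6), n, 6,
                    dimnames = list(sprintf("P%03d", 1:n), cellTypeNames()))
    meth <- matrix(runif(100 * n, 0, 100), 100, n,
                   dimnames = list(paste0("cg", 1:100), rownames(cells)))
    meth[1:20, ] <- t(sweep(cells[, rep(1:4, 5)], 2,
                            runif(20, 50, 100), `*`))
    counts <- vapply(c(0.2, 0.4, 0.6, 0.8),
                     function(th) sum(highCorrelationScreen(
                         meth, cells, threshold = th)@summary$nFlagged),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("degenerate screen inputs are handled", {
    n <- 50
    cells <- matrix(runif(n * 6), n, 6,
                    dimnames = list(sprintf("P%02d", 1:n), cellTypeNames()))
    cells[, "nk"] <- 0.01  # essentially constant, as in low-NK cohorts
    meth <- matrix(runif(5 * n, 0, 100), 5, n,
                   dimnames = list(paste0("cg", 1:5), rownames(cells)))
    expect_message(rep <- highCorrelationScreen(meth, cells), "nk")
    expect_false("nk" %in% rep@summary$cell)
    colnames(meth) <- paste0("X", seq_len(n))
    expect_error(highCorrelationScreen(meth, cells), "overlapping")
    expect_error(highCorrelationScreen(meth, cells, threshold = 0), "0, 1")
})
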