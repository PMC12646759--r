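test_that("connectance counts realized links over possible links", {
    A <- matrix(c(1, 2, 0, 3), 2, 2, dimnames = list(c("H1", "H2"),
                                                     c("P1", "P2")))
    expect_equal(connectance(A), 0.75)
    expect_equal(connectance(matrix(1, 3, 3)), 1)
    B <- matrix(0, 3, 4); B[c(1, 5, 7, 10, 12)] <- 2
    expect_equal(connectance(B), 5 / 12)
})

test_that("weighted NODF closed cases", {
    # block-diagonal: no positive cell of the smaller row/col under a larger
    expect_equal(weightedNODF(matrix(c(5, 0, 0, 3), 2, 2, byrow = TRUE)), 0)
    # equal marginal totals: the decreasing condition fails for every pair
    eq <- matrix(c(1, 2, 2, 1), 2, 2)
    expect_equal(weightedNODF(eq), 0)
    eq3 <- matrix(c(1, 2, 3, 3, 1, 2, 2, 3, 1), 3, 3)
    expect_equal(weightedNODF(eq3), 0)
    expect_equal(weightedNODF(eq3, comparison = "fill"), 0)  # fills tie too
    # perfectly nested example, identical under both conventions
    n22 <- matrix(c(4, 3, 2, 0), 2, 2, byrow = TRUE)
    expect_equal(weightedNODF(n22), 100)
    expect_equal(weightedNODF(n22, comparison = "fill"), 100)
    # degenerate single-row network
    expect_true(is.na(weightedNODF(matrix(1:3, 1, 3))))
})

test_that("weighted NODF matches brute-force definition on random matrices", {
    set.seed(101)
    for (k in 1:200) {
        A <- randomRateMatrix(sample(2:6, 1), sample(2:6, 1))
        expect_equal(weightedNODF(A), oracleWNODF(A), tolerance = 1e-9)
        expect_equal(weightedNODF(A, comparison = "fill"),
                     oracleWNODF(A, comparison = "fill"), tolerance = 1e-9)
    }
})

test_that("fill-convention weighted NODF agrees with vegan", {
    skip_if_not_installed("vegan")
    set.seed(7)
    for (k in 1:50) {
        A <- randomRateMatrix(sample(2:6, 1), sample(2:6, 1))
        v <- unname(vegan::nestednodf(A, order = TRUE,
                                      weighted = TRUE)$statistic["NODF"])
        expect_equal(weightedNODF(A, comparison = "fill"), v,
                     tolerance = 1e-9)
    }
})

test_that("H2' closed cases and oracle equivalence", {
    # exclusive partners, equal rates -> maximal selectiveness
    D <- diag(c(2, 2, 2)); dimnames(D) <- list(letters[1:3], LETTERS[1:3])
    expect_equal(h2Prime(D), 1)
    # matrix equal to the outer product of its marginals -> 0
    O <- c(1, 2, 3) %o% c(2, 1, 1, 4)
    expect_equal(h2Prime(O), 0)
    set.seed(202)
    for (k in 1:200) {
        A <- randomRateMatrix(sample(2:6, 1), sample(2:6, 1))
        expect_equal(h2Prime(A), oracleH2(A), tolerance = 1e-9)
    }
})

test_that("Barber modularity closed forms on equal-mass block matrices", {
    for (k in 2:5) {
        A <- diag(rep(3, k))
        dimnames(A) <- list(paste0("H", 1:k), paste0("P", 1:k))
        part <- list(rows = 1:k, cols = 1:k)
        expect_equal(barberModularity(A, part), 1 - 1 / k)
        # everything in one module
        expect_equal(barberModularity(A, list(rows = rep(1L, k),
                                              cols = rep(1L, k))), 0)
        # one mislabelled row strictly lowers Q
        bad <- part; bad$rows[1] <- 2L
        expect_lt(barberModularity(A, bad), 1 - 1 / k)
    }
})

test_that("Barber modularity matches naive double-summation oracle", {
    set.seed(303)
    for (k in 1:100) {
        A <- randomRateMatrix(sample(2:6, 1), sample(2:6, 1))
        gr <- sample(1:3, nrow(A), replace = TRUE)
        gc <- sample(1:3, ncol(A), replace = TRUE)
        expect_equal(barberModularity(A, list(rows = gr, cols = gc)),
                     oracleBarberQ(A, gr, gc), tolerance = 1e-12)
    }
})

test_that("modularity optimizer recovers planted blocks", {
    A <- matrix(0, 6, 6, dimnames = list(paste0("H", 1:6), paste0("P", 1:6)))
    A[1:2, 1:2] <- 2; A[3:4, 3:4] <- 2; A[5:6, 5:6] <- 2
    part <- optimizeModularity(A, seed = 1)
    expect_equal(part@Q, 2 / 3, tolerance = 1e-12)
    labs <- moduleLabels(part)
    expect_equal(length(unique(labs$rows)), 3L)
    expect_identical(labs$rows[1], labs$rows[2])
    expect_identical(labs$rows, labs$cols)
    # 1x1 network: single module, Q = 0
    one <- matrix(2, 1, 1, dimnames = list("H1", "P1"))
    expect_equal(optimizeModularity(one, seed = 1)@Q, 0)
})

test_that("modularity optimizer is deterministic and never below Q = 0", {
    set.seed(404)
    for (k in 1:20) {
        A <- randomRateMatrix(sample(2:6, 1), sample(2:6, 1))
        p1 <- optimizeModularity(A, restarts = 5, seed = k)
        p2 <- optimizeModularity(A, restarts = 5, seed = k)
        expect_identical(moduleLabels(p1), moduleLabels(p2))
        expect_identical(p1@Q, p2@Q)
        expect_gte(p1@Q, 0)
        # reported Q matches its own partition evaluated independently
        expect_equal(p1@Q, oracleBarberQ(A, p1@rowLabels, p1@colLabels),
                     tolerance = 1e-12)
    }
})

test_that("metrics are invariant to permutation and positive rescaling", {
    set.seed(505)
    for (k in 1:20) {
        A <- randomRateMatrix(sample(3:6, 1), sample(3:6, 1))
        pr <- sample(nrow(A)); pc <- sample(ncol(A))
        B <- A[pr, pc]
        expect_equal(connectance(B), connectance(A))
        expect_equal(weightedNODF(B), weightedNODF(A), tolerance = 1e-9)
        expect_equal(h2Prime(B), h2Prime(A), tolerance = 1e-9)
        # the modularity search is stochastic; on unstructured matrices
        # permuted runs may settle in different local optima, so allow a
        # small slack here (the planted-block test checks exact recovery)
        expect_equal(optimizeModularity(B, restarts = 30, seed = 1)@Q,
                     optimizeModularity(A, restarts = 30, seed = 1)@Q,
                     tolerance = 0.05)
        s <- runif(1, 0.1, 50)
        expect_equal(connectance(A * s), connectance(A))
        expect_equal(weightedNODF(A * s), weightedNODF(A), tolerance = 1e-9)
        expect_equal(h2Prime(A * s), h2Prime(A), tolerance = 1e-9)
        expect_equal(optimizeModularity(A * s, restarts = 8, seed = 2)@Q,
                     optimizeModularity(A, restarts = 8, seed = 2)@Q,
                     tolerance = 1e-9)
    }
})
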