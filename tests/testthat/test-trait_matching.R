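# trait table covering arbitrary bird/plant name vectors
makeTraits <- function(bills, corollas) {
    TraitTable(
        data.frame(species = names(corollas), corolla_length = corollas,
                   corolla_opening = 5, corolla_curvature = 0.01),
        data.frame(species = names(bills), bill_length = bills,
                   body_mass = 5, tail_length = 50, wing_chord = 55,
                   tarsus_length = 6))
}

netFromMatrix <- function(A) new("QuantitativeNetwork", site = "s1", rates = A)

test_that("trait mismatch reproduces hand-computed values", {
    A <- matrix(c(3, 1), 1, 2, dimnames = list("H1", c("P1", "P2")))
    tr <- makeTraits(c(H1 = 10), c(P1 = 8, P2 = 14))
    # (|10-8|*3 + |10-14|*1) / 4 = 2.5
    expect_equal(traitMismatchBird(netFromMatrix(A), tr, "H1"), 2.5)

    B <- matrix(c(1, 1), 2, 1, dimnames = list(c("H1", "H2"), "P1"))
    tr2 <- makeTraits(c(H1 = 10, H2 = 18), c(P1 = 12))
    # (2 + 6) / 2 = 4
    expect_equal(traitMismatchPlant(netFromMatrix(B), tr2, "P1"), 4)

    # perfect matching -> 0
    C1 <- matrix(5, 1, 1, dimnames = list("H1", "P1"))
    expect_equal(traitMismatchBird(netFromMatrix(C1),
                                   makeTraits(c(H1 = 20), c(P1 = 20)),
                                   "H1"), 0)
    # single partner: |bill - corolla| regardless of rate
    C2 <- matrix(7.3, 1, 1, dimnames = list("H1", "P1"))
    expect_equal(traitMismatchBird(netFromMatrix(C2),
                                   makeTraits(c(H1 = 31), c(P1 = 19)),
                                   "H1"), 12)
})

test_that("trait mismatch is invariant to rate rescaling", {
    set.seed(8)
    A <- randomRateMatrix(3, 4)
    tr <- makeTraits(setNames(runif(3, 10, 40), rownames(A)),
                     setNames(runif(4, 10, 40), colnames(A)))
    for (sp in rownames(A))
        expect_equal(traitMismatchBird(netFromMatrix(A * 10), tr, sp),
                     traitMismatchBird(netFromMatrix(A), tr, sp))
})

test_that("trait mismatch matches the pairwise-sum oracle on random networks", {
    set.seed(21)
    for (k in 1:100) {
        A <- randomRateMatrix(sample(2:5, 1), sample(2:5, 1))
        bills <- setNames(runif(nrow(A), 8, 45), rownames(A))
        cors <- setNames(runif(ncol(A), 8, 45), colnames(A))
        tr <- makeTraits(bills, cors)
        net <- netFromMatrix(A)
        bsp <- sample(rownames(A), 1); psp <- sample(colnames(A), 1)
        expect_equal(traitMismatchBird(net, tr, bsp),
                     oracleTM(A, bills, cors, bsp, "bird"),
                     tolerance = 1e-12)
        expect_equal(traitMismatchPlant(net, tr, psp),
                     oracleTM(A, bills, cors, psp, "plant"),
                     tolerance = 1e-12)
    }
})

test_that("missing partner traits raise a coverage error naming the species", {
    A <- matrix(c(1, 2), 1, 2, dimnames = list("H1", c("P1", "P2")))
    tr <- makeTraits(c(H1 = 10), c(P1 = 8, P2 = 14))
    tr@plantTraits["P2", "corolla_length"] <- NA
    expect_error(traitMismatchBird(netFromMatrix(A), tr, "H1"), "P2")
})

test_that("z_TM is negative under strong matching, reproducible by seed", {
    sim <- generateCommunity(simulationConfig(sigmaMatch = 2), seed = 31)
    net <- buildNetwork(sim$table, "site1")
    # the best-matched bird (most concentrated trait kernel) is informative;
    # check the community mean over all birds instead of one species
    zs <- sapply(birdSpecies(net), function(b)
        zValue(tmZScore(sim$table, "site1", b, "bird", sim$traits,
                        nSims = 150, seed = 17)))
    expect_lt(mean(zs, na.rm = TRUE), 0)
    r1 <- tmZScore(sim$table, "site1", birdSpecies(net)[1], "bird",
                   sim$traits, nSims = 60, seed = 4)
    r2 <- tmZScore(sim$table, "site1", birdSpecies(net)[1], "bird",
                   sim$traits, nSims = 60, seed = 4)
    expect_equal(zValue(r1), zValue(r2))
})
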