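toyTree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

test_that("Faith's PD on hand-traced subtrees", {
    tree <- toyTree()
    expect_equal(faithPD(tree, c("A", "B", "C")), 5)
    expect_equal(faithPD(tree, c("A", "B")), 3)    # 1 + 1 + 1 (stem to root)
    # single taxon: root-to-tip path
    expect_equal(faithPD(tree, "C"), 2)
    expect_equal(faithPD(tree, "A"), 2)            # 1 + 1
    expect_error(faithPD(tree, c("A", "Z")), "Z")
})

test_that("Faith's PD agrees with picante and is monotone under addition", {
    skip_if_not_installed("picante")
    set.seed(12)
    for (k in 1:20) {
        tree <- ape::rtree(8, br = rexp)
        taxa <- sample(tree$tip.label, sample(2:7, 1))
        comm <- matrix(as.integer(tree$tip.label %in% taxa), 1,
                       dimnames = list("s", tree$tip.label))
        expect_equal(faithPD(tree, taxa),
                     picante::pd(comm, tree, include.root = TRUE)$PD,
                     tolerance = 1e-10)
        extra <- sample(setdiff(tree$tip.label, taxa), 1)
        expect_gte(faithPD(tree, c(taxa, extra)), faithPD(tree, taxa))
    }
})

test_that("richness counts distinct species with records", {
    tab <- toyTable()
    expect_equal(richness(tab, "s1", "bird"), 2L)   # H1, H2
    expect_equal(richness(tab, "s1", "plant"), 3L)  # P3 filmed-only counts
    onlyPlants <- MonthlyVisitTable(data.frame(
        site = "s2", month = 1L, plant = "P1", bird = NA,
        visits = 0L, recording_hours = 5))
    expect_warning(r <- richness(onlyPlants, "s2", "bird"), "no bird")
    expect_equal(r, 0L)
})

test_that("sesPD is calibrated for uniform draws and detects clustering", {
    set.seed(77)
    tree <- ape::rtree(20, br = rexp)
    pool <- tree$tip.label
    zs <- replicate(40, {
        comm <- sample(pool, 8)
        zValue(sesPD(tree, comm, pool, nNull = 150))
    })
    expect_lt(abs(mean(zs, na.rm = TRUE)), 0.5)
    # a caterpillar tree's most closely related clade has low PD
    cat <- ape::read.tree(text =
        "(((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,F:5);")
    r <- sesPD(cat, c("A", "B", "C"), cat$tip.label, nNull = 300, seed = 2)
    expect_lt(zValue(r), 0)
    # degenerate: community equals pool
    expect_true(is.na(zValue(sesPD(tree, pool, pool, nNull = 20, seed = 1))))
    # z consistent with the generic zScore on the stored null vector
    r2 <- sesPD(tree, sample(pool, 6), pool, nNull = 100, seed = 3,
                keepNulls = TRUE)
    expect_equal(zValue(r2),
                 zValue(zScore(r2@observed, nullValues(r2))))
})

test_that("FDiv closed cases, invariances and degeneracy", {
    # four species on a square: all equidistant from the vertex centroid
    sq <- matrix(c(-1, -1, 1, 1, -1, 1, -1, 1), 4, 2,
                 dimnames = list(paste0("s", 1:4), c("t1", "t2")))
    expect_equal(functionalDivergence(sq, c(1, 1, 1, 1)), 1)
    expect_equal(functionalDivergence(sq, c(5, 1, 2, 9)), 1)  # any weights

    # square plus centre: weight on the interior species pulls FDiv down
    sq5 <- rbind(sq, s5 = c(0, 0))
    wEven <- c(1, 1, 1, 1, 1)
    wCentre <- c(0.05, 0.05, 0.05, 0.05, 10)
    fEven <- functionalDivergence(sq5, wEven)
    fCentre <- functionalDivergence(sq5, wCentre)
    expect_lt(fCentre, fEven)
    expect_lt(fCentre, 1)
    # hand evaluation of the definition on the standardized coordinates
    X <- scale(sq5)
    dG <- sqrt(rowSums(X^2))       # hull vertices are the 4 corners, G = 0
    w <- wCentre / sum(wCentre)
    dbar <- mean(dG)
    dd <- sum(w * (dG - dbar)); dab <- sum(w * abs(dG - dbar))
    expect_equal(fCentre, (dd + dbar) / (dab + dbar), tolerance = 1e-10)

    # ordering and abundance-rescaling invariance
    set.seed(5)
    X2 <- matrix(rnorm(24), 8, 3,
                 dimnames = list(paste0("s", 1:8), paste0("t", 1:3)))
    ab <- runif(8, 0.5, 3); names(ab) <- rownames(X2)
    f0 <- functionalDivergence(X2, ab)
    perm <- sample(8)
    expect_equal(functionalDivergence(X2[perm, ], ab[perm]), f0,
                 tolerance = 1e-10)
    expect_equal(functionalDivergence(X2, ab * 100), f0, tolerance = 1e-12)
    expect_gt(f0, 0); expect_lte(f0, 1)

    # fewer species than traits + 1
    expect_warning(fd <- functionalDivergence(X2[1:3, ], ab[1:3]), "fewer")
    expect_true(is.na(fd))
})

test_that("diversityReport assembles the site summary", {
    sim <- generateCommunity(simulationConfig(nBirds = 6, nPlants = 8,
                                              nMonths = 8), seed = 9)
    rep <- diversityReport(sim$table, "site1", "bird", sim$traits,
                           tree = sim$birdTree, nNull = 100, seed = 1)
    expect_equal(rep$richness, length(birdSpecies(buildNetwork(sim$table,
                                                               "site1"))))
    expect_true(rep$pd_obs > 0)
    expect_true(is.finite(rep$fdiv) && rep$fdiv > 0 && rep$fdiv <= 1)
})
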