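# helpers: per-bird-per-month and per-plant-per-month visit totals
bmTotals <- function(tab) {
    r <- visitRecords(tab); r <- r[!is.na(r$bird) & r$visits > 0, ]
    tapply(r$visits, list(r$bird, r$month), sum, default = 0)
}
pmTotals <- function(tab) {
    r <- visitRecords(tab); r <- r[r$visits > 0, ]
    tapply(r$visits, list(r$plant, r$month), sum, default = 0)
}

test_that("community null conserves bird-month totals and support exactly", {
    tab <- toyTable()
    obs <- bmTotals(tab)
    filmed <- with(visitRecords(tab),
                   unique(paste(month, plant)[recording_hours > 0]))
    for (k in 1:50) {
        nul <- communityNullSample(tab, "s1", seed = k)
        nr <- visitRecords(nul)
        expect_equal(bmTotals(nul)[rownames(obs), colnames(obs)], obs)
        # visits only on filmed plant-months, hours unchanged
        hit <- nr[nr$visits > 0, ]
        expect_true(all(paste(hit$month, hit$plant) %in% filmed))
        expect_true(all(nr$recording_hours > 0 | nr$visits == 0))
    }
})

test_that("forced allocations are identities", {
    # one bird, one filmed plant in the month -> null identical to observed
    tab <- MonthlyVisitTable(data.frame(
        site = "s1", month = c(1L, 2L), plant = c("P1", "P2"),
        bird = "H1", visits = c(3L, 4L), recording_hours = 2))
    for (k in 1:5) {
        nul <- communityNullSample(tab, "s1", seed = k)
        expect_equal(visitRecords(nul)[, names(visitRecords(tab))],
                     visitRecords(tab))
    }
})

test_that("allocation follows recording-hour proportions in expectation", {
    tab <- allocTable()   # 10 visits, plants filmed 3 h and 1 h
    n <- 2000
    alloc <- matrix(0, n, 2)
    set.seed(99)
    for (k in 1:n) {
        r <- visitRecords(communityNullSample(tab, "s1"))
        alloc[k, ] <- c(sum(r$visits[r$plant == "P1"]),
                        sum(r$visits[r$plant == "P2"]))
    }
    expect_true(all(rowSums(alloc) == 10))       # conservation, every draw
    # multinomial expectation 7.5 / 2.5, binomial SE of the mean
    se <- sqrt(10 * 0.75 * 0.25 / n)
    expect_lt(abs(mean(alloc[, 1]) - 7.5), 3 * se)
    p <- chisq.test(c(sum(alloc[, 1]), sum(alloc[, 2])),
                    p = c(0.75, 0.25))$p.value
    expect_gt(p, 0.01)
})

test_that("temporal constraint blocks cross-month allocation; liberal lifts it", {
    # bird active only in month 1; plant P2 filmed only in month 2
    tab <- MonthlyVisitTable(data.frame(
        site = "s1", month = c(1L, 1L, 2L),
        plant = c("P1", "P3", "P2"), bird = c("H1", "H1", NA),
        visits = c(6L, 4L, 0L), recording_hours = c(2, 2, 50)))
    crossed <- 0
    for (k in 1:30) {
        nulT <- visitRecords(communityNullSample(tab, "s1", seed = k))
        expect_equal(sum(nulT$visits[nulT$plant == "P2"]), 0)
        nulL <- visitRecords(liberalNullSample(tab, "s1", seed = k))
        expect_equal(sum(nulL$visits), 10)    # site-level conservation
        crossed <- crossed + sum(nulL$visits[nulL$plant == "P2"])
    }
    # P2 holds >90% of total hours, so the liberal null must use it
    expect_gt(crossed, 0)
})

test_that("focal-row null changes only the focal bird's records", {
    tab <- toyTable()
    obsPM <- bmTotals(tab)
    for (k in 1:20) {
        nul <- focalRowNullSample(tab, "s1", "H1", seed = k)
        nr <- visitRecords(nul)
        # focal monthly totals preserved
        expect_equal(bmTotals(nul)["H1", colnames(obsPM)], obsPM["H1", ])
        # non-focal records identical to observed
        oth <- nr[!is.na(nr$bird) & nr$bird != "H1", ]
        obs <- visitRecords(tab)
        obs <- obs[!is.na(obs$bird) & obs$bird != "H1", ]
        key <- function(d) d[order(d$month, d$plant, d$bird),
                             c("month", "plant", "bird", "visits")]
        expect_equal(key(oth), key(obs), ignore_attr = TRUE)
    }
    expect_error(focalRowNullSample(tab, "s1", "H9", seed = 1), "not found")
})

test_that("focal-column null preserves plant totals and follows abundance", {
    tab <- toyTable()
    obsPM <- pmTotals(tab)
    for (k in 1:20) {
        nul <- focalColNullSample(tab, "s1", "P1", seed = k)
        expect_equal(pmTotals(nul)["P1", colnames(obsPM)], obsPM["P1", ])
        # other plants' bird allocations untouched
        nr <- visitRecords(nul); obs <- visitRecords(tab)
        key <- function(d) {
            d <- d[d$plant != "P1" & !is.na(d$bird), ]
            d[order(d$month, d$plant, d$bird), c("month", "plant", "bird",
                                                 "visits")]
        }
        expect_equal(key(nr), key(obs), ignore_attr = TRUE)
    }
    # expectation proportional to bird monthly visit shares (month 1: H1 has
    # 9 of 11 visits); average share of P1's 8 visits to H1 ~ 8 * 9/11
    set.seed(3)
    got <- replicate(600, {
        nr <- visitRecords(focalColNullSample(tab, "s1", "P1"))
        sum(nr$visits[nr$plant == "P1" & nr$bird == "H1" & nr$month == 1])
    })
    pexp <- 9 / 11
    se <- sqrt(8 * pexp * (1 - pexp) / 600)
    expect_lt(abs(mean(got) - 8 * pexp), 3 * se)
})

test_that("zScore handles degenerate and centred nulls", {
    expect_true(is.na(zValue(zScore(5, rep(5, 10)))))
    expect_false(is.infinite(zScore(5, rep(5, 10))@z))
    nulls <- c(-1, 1, -1, 1)
    expect_equal(zValue(zScore(0, nulls)), 0)
    expect_equal(zValue(zScore(2, nulls)), 2 / sd(nulls))
    expect_error(zScore(1, numeric(0)), "empty")
})

test_that("communityZScores is deterministic and exposes a trace", {
    sim <- generateCommunity(simulationConfig(nBirds = 4, nPlants = 8,
                                              nMonths = 8), seed = 5)
    z1 <- communityZScores(sim$table, "site1", nSims = 60, seed = 42)
    z2 <- communityZScores(sim$table, "site1", nSims = 60, seed = 42)
    expect_equal(sapply(z1, zValue), sapply(z2, zValue))
    tr <- communityZScores(sim$table, "site1", nSims = 60, seed = 42,
                           trace = TRUE)
    expect_named(tr, c("reports", "trace"))
    expect_equal(nrow(tr$trace), 60)
    expect_equal(sapply(tr$reports, zValue), sapply(z1, zValue))
    # the trace converges to the reported z
    expect_equal(unname(tr$trace[60, ]), unname(sapply(z1, zValue)))
    # same-seed liberal variant also deterministic
    l1 <- communityZScores(sim$table, "site1", nSims = 30, seed = 9,
                           nullModel = "liberal")
    l2 <- communityZScores(sim$table, "site1", nSims = 30, seed = 9,
                           nullModel = "liberal")
    expect_equal(sapply(l1, zValue), sapply(l2, zValue))
})
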