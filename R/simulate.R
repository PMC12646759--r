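# Synthetic monthly visitation data with a tunable bill-corolla matching
# linkage rule, emulating a camera-transect sampling design: monthly
# surveys over ~2 years, per-plant recording hours, Poisson visit budgets
# per hummingbird per month, and phenology windows for plants.

#' Configuration for the synthetic community generator
#'
#' Defaults describe one realistically sized tropical site sampled monthly
#' for two years: 8 hummingbird and 15 plant species; bill and corolla
#' lengths log-normal around 20 mm (spread roughly 10-40 mm); each plant
#' flowers in one contiguous window of 3-12 months and, while flowering, is
#' filmed 60-72 h per month (three 3-day camera deployments at one frame/s
#' give ~72 h); each hummingbird is present in a month with probability
#' 0.7 and then pays a Poisson(10) number of visits, allocated across the
#' flowering plants with probability proportional to
#' `recording_hours * exp(-(bill - corolla)^2 / (2 sigmaMatch^2))`.
#' `sigmaMatch = 2` mm gives strong trait matching; `sigmaMatch = Inf`
#' drops the kernel entirely, making the generator identical to the
#' temporally constrained community null model (the neutral limit used for
#' z-score calibration).
#'
#' @param nBirds,nPlants species pool sizes.
#' @param nMonths number of monthly surveys (default 24).
#' @param sigmaMatch matching-kernel width in mm; `Inf` = neutral.
#' @param billMeanlog,billSdlog,corollaMeanlog,corollaSdlog log-normal
#'   parameters of bill and corolla length (mm).
#' @param birdActivity per-month presence probability of each hummingbird.
#' @param visitIntensity expected visits per present hummingbird per month.
#' @param hoursRange uniform range of monthly recording hours per flowering
#'   plant.
#' @param phenologyRange integer range of flowering-window lengths (months).
#' @param nSites,elevationRange,elevationEffect gradient settings (see
#'   [generateGradient()]): number of sites, elevation span in m, and the
#'   proportional richness change from the bottom to the top of the
#'   gradient (negative = decline; 0 = no elevation effect).
#' @return A validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nBirds = 8L, nPlants = 15L, nMonths = 24L,
                             sigmaMatch = 2,
                             billMeanlog = log(20), billSdlog = 0.35,
                             corollaMeanlog = log(20), corollaSdlog = 0.35,
                             birdActivity = 0.7, visitIntensity = 10,
                             hoursRange = c(60, 72),
                             phenologyRange = c(3L, 12L),
                             nSites = 32L, elevationRange = c(100, 3500),
                             elevationEffect = -0.5) {
    cfg <- list(nBirds = as.integer(nBirds), nPlants = as.integer(nPlants),
                nMonths = as.integer(nMonths), sigmaMatch = sigmaMatch,
                billMeanlog = billMeanlog, billSdlog = billSdlog,
                corollaMeanlog = corollaMeanlog, corollaSdlog = corollaSdlog,
                birdActivity = birdActivity, visitIntensity = visitIntensity,
                hoursRange = hoursRange,
                phenologyRange = as.integer(phenologyRange),
                nSites = as.integer(nSites), elevationRange = elevationRange,
                elevationEffect = elevationEffect)
    with(cfg, {
        stopifnot(nBirds >= 1L, nPlants >= 1L, nMonths >= 1L,
                  sigmaMatch > 0, birdActivity > 0, birdActivity <= 1,
                  visitIntensity > 0, hoursRange[1] > 0,
                  hoursRange[2] >= hoursRange[1],
                  phenologyRange[1] >= 1L,
                  phenologyRange[2] >= phenologyRange[1], nSites >= 1L)
    })
    class(cfg) <- "SimulationConfig"
    cfg
}

# Draw a TraitTable for named species pools.
.drawTraits <- function(cfg, birdNames, plantNames) {
    nb <- length(birdNames); np <- length(plantNames)
    TraitTable(
        plantTraits = data.frame(
            species = plantNames,
            corolla_length = stats::rlnorm(np, cfg$corollaMeanlog,
                                           cfg$corollaSdlog),
            corolla_opening = stats::rlnorm(np, log(6), 0.3),
            corolla_curvature = abs(stats::rnorm(np, 0.02, 0.01)),
            stringsAsFactors = FALSE),
        birdTraits = data.frame(
            species = birdNames,
            bill_length = stats::rlnorm(nb, cfg$billMeanlog, cfg$billSdlog),
            body_mass = stats::rlnorm(nb, log(5), 0.3),
            tail_length = stats::rlnorm(nb, log(50), 0.25),
            wing_chord = stats::rlnorm(nb, log(55), 0.2),
            tarsus_length = stats::rlnorm(nb, log(6), 0.15),
            stringsAsFactors = FALSE))
}

# Simulate one site's records given traits for its local species.
.simSiteRecords <- function(cfg, site, birdNames, plantNames, bills,
                            corollas) {
    nMonths <- cfg$nMonths
    # phenology: one contiguous flowering window per plant
    start <- sample.int(nMonths, length(plantNames), replace = TRUE)
    len <- sample(seq(cfg$phenologyRange[1], cfg$phenologyRange[2]),
                  length(plantNames), replace = TRUE)
    flowering <- matrix(FALSE, nMonths, length(plantNames))
    for (p in seq_along(plantNames))
        flowering[start[p]:min(start[p] + len[p] - 1L, nMonths), p] <- TRUE
    present <- matrix(stats::runif(length(birdNames) * nMonths) <
                          cfg$birdActivity,
                      length(birdNames), nMonths)
    kern <- if (is.finite(cfg$sigmaMatch))
        exp(-outer(bills, corollas, "-")^2 / (2 * cfg$sigmaMatch^2))
    else matrix(1, length(bills), length(corollas))
    out <- list()
    for (m in seq_len(nMonths)) {
        fl <- which(flowering[m, ])
        if (!length(fl)) next
        hours <- stats::setNames(
            stats::runif(length(fl), cfg$hoursRange[1], cfg$hoursRange[2]),
            plantNames[fl])
        visits <- matrix(0, length(birdNames), length(fl))
        for (b in which(present[, m])) {
            v <- stats::rpois(1L, cfg$visitIntensity)
            if (v == 0) next
            pr <- hours * kern[b, fl]
            if (sum(pr) <= 0) pr <- hours
            visits[b, ] <- if (length(fl) == 1L) v
                           else stats::rmultinom(1L, v, pr)[, 1L]
        }
        for (pi in seq_along(fl)) {
            hit <- which(visits[, pi] > 0)
            out[[length(out) + 1L]] <- if (length(hit))
                data.frame(site = site, month = m, plant = plantNames[fl[pi]],
                           bird = birdNames[hit],
                           visits = unname(visits[hit, pi]),
                           recording_hours = unname(hours[pi]),
                           stringsAsFactors = FALSE)
            else
                data.frame(site = site, month = m, plant = plantNames[fl[pi]],
                           bird = NA_character_, visits = 0,
                           recording_hours = unname(hours[pi]),
                           stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

#' Generate one synthetic community
#'
#' Draws traits, phenology, camera effort and monthly visitation for a
#' single site under the configured trait-matching linkage rule, plus a
#' random bifurcating phylogeny (exponential branch lengths) per guild.
#' Fully deterministic given `seed`.
#'
#' @param cfg a [simulationConfig()].
#' @param site site identifier for the records.
#' @param seed optional integer.
#' @return list with elements `table` ([MonthlyVisitTable-class]),
#'   `traits` ([TraitTable-class]), `birdTree` and `plantTree`
#'   ([ape::phylo]).
#' @examples
#' sim <- generateCommunity(simulationConfig(nBirds = 4, nPlants = 6,
#'                                           nMonths = 6), seed = 1)
#' buildNetwork(sim$table, "site1")
#' @export
generateCommunity <- function(cfg = simulationConfig(), site = "site1",
                              seed = NULL) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    .withSeed(seed, {
        birdNames <- sprintf("H%02d", seq_len(cfg$nBirds))
        plantNames <- sprintf("P%02d", seq_len(cfg$nPlants))
        traits <- .drawTraits(cfg, birdNames, plantNames)
        rec <- .simSiteRecords(cfg, site, birdNames, plantNames,
                               birdTraits(traits)$bill_length,
                               plantTraits(traits)$corolla_length)
        birdTree <- ape::rtree(cfg$nBirds, tip.label = birdNames,
                               br = stats::rexp)
        plantTree <- ape::rtree(cfg$nPlants, tip.label = plantNames,
                                br = stats::rexp)
        list(table = MonthlyVisitTable(rec), traits = traits,
             birdTree = birdTree, plantTree = plantTree)
    })
}

#' Generate a multi-site elevational gradient
#'
#' Simulates `cfg$nSites` communities sharing regional species pools and
#' one trait table. Site elevations are evenly spaced over
#' `cfg$elevationRange`; local richness declines linearly with elevation so
#' that the top site keeps a fraction `1 + elevationEffect` of the pool
#' (e.g. `elevationEffect = -0.5` halves richness from bottom to top;
#' 0 makes richness differences pure sampling noise). Local species sets
#' are random draws from the pools.
#'
#' @inheritParams generateCommunity
#' @return list with `table` (all sites), `traits`, `birdTree`,
#'   `plantTree`, and `covariates` (data.frame site, elevation).
#' @export
generateGradient <- function(cfg = simulationConfig(), seed = NULL) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    .withSeed(seed, {
        birdNames <- sprintf("H%02d", seq_len(cfg$nBirds))
        plantNames <- sprintf("P%02d", seq_len(cfg$nPlants))
        traits <- .drawTraits(cfg, birdNames, plantNames)
        bills <- stats::setNames(birdTraits(traits)$bill_length, birdNames)
        cors <- stats::setNames(plantTraits(traits)$corolla_length,
                                plantNames)
        elev <- seq(cfg$elevationRange[1], cfg$elevationRange[2],
                    length.out = cfg$nSites)
        en <- (elev - min(elev)) / max(1, diff(range(elev)))
        recs <- list()
        sites <- sprintf("site%02d", seq_len(cfg$nSites))
        for (s in seq_len(cfg$nSites)) {
            frac <- 1 + cfg$elevationEffect * en[s]
            nb <- max(3L, round(cfg$nBirds * frac))
            np <- max(3L, round(cfg$nPlants * frac))
            lb <- sort(sample(birdNames, min(nb, cfg$nBirds)))
            lp <- sort(sample(plantNames, min(np, cfg$nPlants)))
            recs[[s]] <- .simSiteRecords(cfg, sites[s], lb, lp,
                                         bills[lb], cors[lp])
        }
        list(table = MonthlyVisitTable(do.call(rbind, recs)),
             traits = traits,
             birdTree = ape::rtree(cfg$nBirds, tip.label = birdNames,
                                   br = stats::rexp),
             plantTree = ape::rtree(cfg$nPlants, tip.label = plantNames,
                                    br = stats::rexp),
             covariates = data.frame(site = sites, elevation = elev,
                                     stringsAsFactors = FALSE))
    })
}
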