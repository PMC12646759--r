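# Constrained randomizations of monthly visitation records. All samplers
# reallocate visit COUNTS by multinomial draws (never permute cells), which
# is the only operation that simultaneously preserves each hummingbird's
# visit totals and allocates visits proportionally to plant recording time.

# -- internal draw engines on .siteData tabulations -------------------------
# Each returns a birds x plants x nDraws array of visit counts.

.drawCommunityVisits <- function(sd, nDraws) {
    V <- array(0, c(length(sd$birds), length(sd$plants), nDraws),
               dimnames = list(sd$birds, sd$plants, NULL))
    for (mi in seq_along(sd$months)) {
        h <- sd$hoursMP[mi, ]
        filmed <- which(h > 0)
        if (!length(filmed)) next
        for (bi in seq_along(sd$birds)) {
            v <- sd$birdMonthTotals[bi, mi]
            if (v == 0) next
            if (length(filmed) == 1L) {
                V[bi, filmed, ] <- V[bi, filmed, ] + v
            } else {
                draw <- stats::rmultinom(nDraws, v, h[filmed])
                V[bi, filmed, ] <- V[bi, filmed, ] + draw
            }
        }
    }
    V
}

.drawLiberalVisits <- function(sd, nDraws) {
    V <- array(0, c(length(sd$birds), length(sd$plants), nDraws),
               dimnames = list(sd$birds, sd$plants, NULL))
    ph <- sd$plantHours
    filmed <- which(ph > 0)
    for (bi in seq_along(sd$birds)) {
        v <- sum(sd$birdMonthTotals[bi, ])
        if (v == 0) next
        draw <- stats::rmultinom(nDraws, v, ph[filmed])
        V[bi, filmed, ] <- V[bi, filmed, ] + draw
    }
    V
}

.drawFocalRowVisits <- function(sd, focalBird, nDraws) {
    bi <- match(focalBird, sd$birds)
    if (is.na(bi)) stop("focal bird not found at site: ", focalBird)
    obs <- apply(sd$visitsBPM, c(1L, 2L), sum)
    V <- array(rep(obs, nDraws), c(dim(obs), nDraws),
               dimnames = list(sd$birds, sd$plants, NULL))
    V[bi, , ] <- 0
    for (mi in seq_along(sd$months)) {
        v <- sd$birdMonthTotals[bi, mi]
        if (v == 0) next
        h <- sd$hoursMP[mi, ]
        filmed <- which(h > 0)
        if (length(filmed) == 1L) {
            V[bi, filmed, ] <- V[bi, filmed, ] + v
        } else {
            draw <- stats::rmultinom(nDraws, v, h[filmed])
            V[bi, filmed, ] <- V[bi, filmed, ] + draw
        }
    }
    V
}

.drawFocalColVisits <- function(sd, focalPlant, nDraws) {
    pj <- match(focalPlant, sd$plants)
    if (is.na(pj)) stop("focal plant not found at site: ", focalPlant)
    obs <- apply(sd$visitsBPM, c(1L, 2L), sum)
    V <- array(rep(obs, nDraws), c(dim(obs), nDraws),
               dimnames = list(sd$birds, sd$plants, NULL))
    V[, pj, ] <- 0
    for (mi in seq_along(sd$months)) {
        v <- sum(sd$visitsBPM[, pj, mi])
        if (v == 0) next
        w <- sd$birdMonthTotals[, mi]   # relative abundance from cameras
        act <- which(w > 0)
        if (length(act) == 1L) {
            V[act, pj, ] <- V[act, pj, ] + v
        } else {
            draw <- stats::rmultinom(nDraws, v, w[act])
            V[act, pj, ] <- V[act, pj, ] + draw
        }
    }
    V
}

# Rebuild a MonthlyVisitTable for one site from a birds x plants x months
# visit array plus the (unchanged) months x plants hours matrix.
.visitsToTable <- function(sd, visitsBPM) {
    out <- list()
    for (mi in seq_along(sd$months)) {
        h <- sd$hoursMP[mi, ]
        for (pj in which(h > 0)) {
            vb <- if (length(sd$birds)) visitsBPM[, pj, mi] else numeric(0)
            hit <- which(vb > 0)
            out[[length(out) + 1L]] <- if (length(hit))
                data.frame(site = sd$site, month = sd$months[mi],
                           plant = sd$plants[pj], bird = sd$birds[hit],
                           visits = unname(vb[hit]),
                           recording_hours = unname(h[pj]),
                           stringsAsFactors = FALSE)
            else
                data.frame(site = sd$site, month = sd$months[mi],
                           plant = sd$plants[pj], bird = NA_character_,
                           visits = 0, recording_hours = unname(h[pj]),
                           stringsAsFactors = FALSE)
        }
    }
    MonthlyVisitTable(do.call(rbind, out))
}

# -- public samplers --------------------------------------------------------

#' Draw one table from the temporally constrained community null model
#'
#' For each month and each hummingbird, all of that bird's visits in that
#' month are reallocated across the plants filmed that month by a
#' multinomial draw with probabilities proportional to each plant's
#' recording hours. This preserves phenological overlap (visits can only
#' land on plants flowering, i.e. filmed, that month), every bird's monthly
#' visit total, and allocates visits proportionally to camera effort.
#' Recording hours are unchanged.
#'
#' @param table a [MonthlyVisitTable-class].
#' @param site site identifier.
#' @param seed optional integer for reproducibility.
#' @return A [MonthlyVisitTable-class] containing the site's randomized
#'   records (filmed-only rows included).
#' @export
communityNullSample <- function(table, site, seed = NULL) {
    sd <- .siteData(table, site)
    V3 <- .withSeed(seed, .drawCommunityMonthly(sd))
    .visitsToTable(sd, V3)
}

# Month-resolved single draw of the community null (for table emission).
.drawCommunityMonthly <- function(sd) {
    V <- array(0, dim(sd$visitsBPM), dimnames = dimnames(sd$visitsBPM))
    for (mi in seq_along(sd$months)) {
        h <- sd$hoursMP[mi, ]
        filmed <- which(h > 0)
        if (!length(filmed)) next
        for (bi in seq_along(sd$birds)) {
            v <- sd$birdMonthTotals[bi, mi]
            if (v == 0) next
            if (length(filmed) == 1L) V[bi, filmed, mi] <- v
            else V[bi, filmed, mi] <- stats::rmultinom(1L, v, h[filmed])[, 1L]
        }
    }
    V
}

#' Draw one table from the liberal (non-temporal) null model
#'
#' As [communityNullSample()] but each bird's visits are pooled across
#' months and reallocated over every filmed plant-month at the site with
#' probabilities proportional to recording hours, so a plant can receive
#' visits in months when the bird was not observed. Bird visit totals are
#' conserved at the site level only.
#'
#' @inheritParams communityNullSample
#' @return A [MonthlyVisitTable-class].
#' @export
liberalNullSample <- function(table, site, seed = NULL) {
    sd <- .siteData(table, site)
    hours <- sd$hoursMP
    cells <- which(hours > 0, arr.ind = TRUE)     # filmed (month, plant) cells
    V <- array(0, c(length(sd$birds), length(sd$plants), length(sd$months)))
    .withSeed(seed, {
        for (bi in seq_along(sd$birds)) {
            v <- sum(sd$birdMonthTotals[bi, ])
            if (v == 0) next
            draw <- if (nrow(cells) == 1L) v
                    else stats::rmultinom(1L, v, hours[cells])[, 1L]
            for (ci in which(draw > 0))
                V[bi, cells[ci, 2L], cells[ci, 1L]] <-
                    V[bi, cells[ci, 2L], cells[ci, 1L]] + draw[ci]
        }
    })
    .visitsToTable(sd, V)
}

#' Focal-species null draws (row-wise and column-wise reshuffling)
#'
#' `focalRowNullSample` reallocates only the focal hummingbird's visits,
#' month by month, across the plants filmed that month proportionally to
#' recording hours; every other record is identical to the observed table.
#' `focalColNullSample` redistributes the focal plant's monthly visit totals
#' across hummingbirds proportionally to each bird's total visits at the
#' site in that month (relative abundance as seen by the cameras); all other
#' records are unchanged.
#'
#' @inheritParams communityNullSample
#' @param focalBird,focalPlant the focal species identifier.
#' @return A [MonthlyVisitTable-class] for the site.
#' @export
focalRowNullSample <- function(table, site, focalBird, seed = NULL) {
    sd <- .siteData(table, site)
    V3 <- .withSeed(seed, .drawFocalRowMonthly(sd, focalBird))
    .visitsToTable(sd, V3)
}

#' @rdname focalRowNullSample
#' @export
focalColNullSample <- function(table, site, focalPlant, seed = NULL) {
    sd <- .siteData(table, site)
    V3 <- .withSeed(seed, .drawFocalColMonthly(sd, focalPlant))
    .visitsToTable(sd, V3)
}

# Month-resolved single-draw variants (needed to emit valid tables).
.drawFocalRowMonthly <- function(sd, focalBird) {
    bi <- match(focalBird, sd$birds)
    if (is.na(bi)) stop("focal bird not found at site: ", focalBird)
    V <- sd$visitsBPM
    for (mi in seq_along(sd$months)) {
        v <- sd$birdMonthTotals[bi, mi]
        V[bi, , mi] <- 0
        if (v == 0) next
        h <- sd$hoursMP[mi, ]
        filmed <- which(h > 0)
        if (length(filmed) == 1L) V[bi, filmed, mi] <- v
        else V[bi, filmed, mi] <- stats::rmultinom(1L, v, h[filmed])[, 1L]
    }
    V
}

.drawFocalColMonthly <- function(sd, focalPlant) {
    pj <- match(focalPlant, sd$plants)
    if (is.na(pj)) stop("focal plant not found at site: ", focalPlant)
    V <- sd$visitsBPM
    for (mi in seq_along(sd$months)) {
        v <- sum(V[, pj, mi])
        V[, pj, mi] <- 0
        if (v == 0) next
        w <- sd$birdMonthTotals[, mi]
        act <- which(w > 0)
        if (length(act) == 1L) V[act, pj, mi] <- v
        else V[act, pj, mi] <- stats::rmultinom(1L, v, w[act])[, 1L]
    }
    V
}

# -- ensemble z-scores ------------------------------------------------------

# Evaluate the selected metrics on a visits matrix; NA where undefined.
.metricValues <- function(visitsBP, plantHours, metrics, restarts) {
    net <- .ratesToNetwork("", visitsBP, plantHours)
    out <- stats::setNames(rep(NA_real_, length(metrics)), metrics)
    if (is.null(net)) return(out)
    A <- rateMatrix(net)
    for (mm in metrics)
        out[mm] <- switch(mm,
            Q = .optQvalue(A, restarts),
            C = connectance(A),
            H2 = h2Prime(A),
            WNODF = weightedNODF(A))
    out
}

#' Community-level z-scores of network metrics against a null ensemble
#'
#' Draws `nSims` tables from the chosen null model, rebuilds the site
#' network for each draw, computes the selected metrics, and standardizes
#' the observed metrics as z-scores. The observed value of modularity is
#' computed with the same optimizer settings (`restarts`) as the null
#' values so the comparison is unbiased. Draws where a metric is undefined
#' (e.g. the network collapses below 2x2 after dropping empty species) are
#' excluded from that metric's null vector and counted; if more than 10% of
#' draws are dropped a warning flags the report.
#'
#' @param table a [MonthlyVisitTable-class].
#' @param site site identifier.
#' @param nSims number of null simulations (default 1000).
#' @param seed optional integer master seed.
#' @param metrics subset of `c("Q", "C", "H2", "WNODF")`.
#' @param nullModel `"temporal"` (monthly reshuffling, the default) or
#'   `"liberal"` (visits pooled across months).
#' @param restarts modularity optimizer restarts used for both observed and
#'   null networks.
#' @param keepNulls store the per-draw metric values in the reports.
#' @param trace also return a running-z convergence trace per metric.
#' @return A named list of [ZScoreReport-class], one per metric; with
#'   `trace = TRUE` a list with elements `reports` and `trace` (a matrix of
#'   running z against number of simulations).
#' @export
communityZScores <- function(table, site, nSims = 1000L, seed = NULL,
                             metrics = c("Q", "C", "H2", "WNODF"),
                             nullModel = c("temporal", "liberal"),
                             restarts = 3L, keepNulls = FALSE, trace = FALSE) {
    stopifnot(nSims >= 2L)
    nullModel <- match.arg(nullModel)
    metrics <- match.arg(metrics, c("Q", "C", "H2", "WNODF"),
                         several.ok = TRUE)
    sd <- .siteData(table, site)
    obsBP <- if (length(sd$birds)) apply(sd$visitsBPM, c(1L, 2L), sum)
             else stop("empty network: no visits at site ", site)
    .withSeed(seed, {
        observed <- .metricValues(obsBP, sd$plantHours, metrics, restarts)
        V <- switch(nullModel,
                    temporal = .drawCommunityVisits(sd, nSims),
                    liberal = .drawLiberalVisits(sd, nSims))
        nullMat <- matrix(NA_real_, nSims, length(metrics),
                          dimnames = list(NULL, metrics))
        for (s in seq_len(nSims))
            nullMat[s, ] <- .metricValues(V[, , s, drop = FALSE][, , 1L],
                                          sd$plantHours, metrics, restarts)
        reports <- lapply(metrics, function(mm) {
            vals <- nullMat[, mm]
            ok <- !is.na(vals)
            if (mean(!ok) > 0.10)
                warning(sprintf(
                    "site %s, metric %s: %.0f%% of null draws undefined",
                    site, mm, 100 * mean(!ok)))
            .zreport(mm, observed[[mm]], vals[ok], nDropped = sum(!ok),
                     keepNulls = keepNulls)
        })
        names(reports) <- metrics
        if (!trace) return(reports)
        tr <- sapply(metrics, function(mm) {
            vals <- nullMat[, mm]; vals <- vals[!is.na(vals)]
            n <- seq_along(vals)
            mu <- cumsum(vals) / n
            s2 <- (cumsum(vals^2) - n * mu^2) / pmax(n - 1, 1)
            ifelse(n >= 2 & s2 > 0,
                   (observed[[mm]] - mu) / sqrt(pmax(s2, 0)), NA_real_)
        })
        list(reports = reports, trace = tr)
    })
}
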