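# Species-level contributions to community network structure: the observed
# community metric is compared against its distribution when only the focal
# species' visits are randomized (row-wise for hummingbirds, column-wise for
# plants), the rest of the matrix held fixed.

#' Contribution of one species to each community network metric
#'
#' Draws `nSims` focal-randomized tables (row-wise reshuffling for a
#' hummingbird, column-wise for a plant), rebuilds the whole site network
#' for every draw, recomputes each community metric, and reports the
#' z-score of the observed community metric against that null distribution.
#' A positive z means the species' real interactions raise the metric above
#' the expectation under its own randomized behaviour; a negative z means
#' they lower it. A focal species whose visits are fully forced (a single
#' available partner every month) yields a degenerate null and `z = NA`.
#'
#' @param table a [MonthlyVisitTable-class].
#' @param site site identifier.
#' @param species focal species identifier.
#' @param guild `"bird"` or `"plant"`.
#' @param nSims null draws per metric (default 1000).
#' @param seed optional integer.
#' @param metrics subset of `c("Q", "C", "H2", "WNODF")`.
#' @param restarts modularity restarts inside the null loop (default 3; the
#'   loop is the pipeline's hot path).
#' @param keepNulls store per-draw metric values.
#' @return A list with elements `site`, `species`, `guild` and `reports`
#'   (named list of [ZScoreReport-class], one per metric).
#' @export
speciesContribution <- function(table, site, species,
                                guild = c("bird", "plant"), nSims = 1000L,
                                seed = NULL,
                                metrics = c("Q", "C", "H2", "WNODF"),
                                restarts = 3L, keepNulls = FALSE) {
    guild <- match.arg(guild)
    metrics <- match.arg(metrics, c("Q", "C", "H2", "WNODF"),
                         several.ok = TRUE)
    sd <- .siteData(table, site)
    ok <- if (guild == "bird") species %in% sd$birds
          else species %in% sd$plants && sum(sd$visitsBPM[, match(
              species, sd$plants), ]) > 0
    if (!ok) stop("focal species '", species, "' has no visits at site ", site)
    obsBP <- apply(sd$visitsBPM, c(1L, 2L), sum)
    .withSeed(seed, {
        observed <- .metricValues(obsBP, sd$plantHours, metrics, restarts)
        V <- if (guild == "bird") .drawFocalRowVisits(sd, species, nSims)
             else .drawFocalColVisits(sd, species, nSims)
        nullMat <- matrix(NA_real_, nSims, length(metrics),
                          dimnames = list(NULL, metrics))
        for (s in seq_len(nSims))
            nullMat[s, ] <- .metricValues(V[, , s, drop = FALSE][, , 1L],
                                          sd$plantHours, metrics, restarts)
        reports <- lapply(metrics, function(mm) {
            vals <- nullMat[, mm]
            .zreport(mm, observed[[mm]], vals[!is.na(vals)],
                     nDropped = sum(is.na(vals)), keepNulls = keepNulls)
        })
        names(reports) <- metrics
        list(site = site, species = species, guild = guild, reports = reports)
    })
}

#' Contributions of every species at a site
#'
#' Applies [speciesContribution()] to each hummingbird and each visited
#' plant at the site. Per-species sub-seeds are derived deterministically
#' from the master seed and the species identifier, so results do not
#' depend on iteration order. Per-species failures are caught, logged as
#' warnings and skipped without aborting the batch.
#'
#' @inheritParams speciesContribution
#' @return A list of per-species results (see [speciesContribution()]);
#'   empty (with a warning) if the site has no visits.
#' @export
allContributions <- function(table, site, nSims = 1000L, seed = NULL,
                             metrics = c("Q", "C", "H2", "WNODF"),
                             restarts = 3L) {
    sd <- .siteData(table, site)
    visited <- sd$plants[colSums(apply(sd$visitsBPM, c(1L, 2L), sum)) > 0]
    todo <- rbind(
        if (length(sd$birds)) data.frame(species = sd$birds, guild = "bird"),
        if (length(visited)) data.frame(species = visited, guild = "plant"))
    if (is.null(todo) || !nrow(todo)) {
        warning("site ", site, " has no visited species")
        return(list())
    }
    out <- vector("list", nrow(todo))
    for (i in seq_len(nrow(todo))) {
        sseed <- if (is.null(seed)) NULL
                 else .childSeed(seed, paste(site, todo$species[i]))
        out[[i]] <- tryCatch(
            speciesContribution(table, site, todo$species[i], todo$guild[i],
                                nSims = nSims, seed = sseed,
                                metrics = metrics, restarts = restarts),
            error = function(e) {
                warning("contribution failed for ", todo$species[i], ": ",
                        conditionMessage(e))
                NULL
            })
    }
    out[!vapply(out, is.null, logical(1))]
}

#' Flatten contribution results into a tidy table
#'
#' @param contribs result of [allContributions()] (or a list of
#'   [speciesContribution()] results).
#' @return data.frame with one row per (site, species, metric).
#' @export
contributionTable <- function(contribs) {
    do.call(rbind, lapply(contribs, function(cr) {
        zScoreTable(cr$reports,
                    meta = data.frame(site = cr$site, species = cr$species,
                                      guild = cr$guild))
    }))
}
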