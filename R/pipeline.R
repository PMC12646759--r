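# End-to-end orchestration: data -> networks -> metrics -> null z-scores ->
# species contributions -> trait mismatch -> diversity -> tidy CSVs plus a
# JSON run manifest.

#' Run the full network analysis
#'
#' Drives every analysis stage over a set of sites and writes one tidy CSV
#' per stage plus a JSON manifest (configuration, seed, package version,
#' per-stage timings, dropped-draw counts). All randomness is derived
#' deterministically from `seed` with per-site and per-species sub-streams,
#' so two runs with the same inputs and seed produce byte-identical files.
#'
#' Before any computation, inputs are cross-checked: every interacting
#' species must have traits (when the trait-mismatch stage is on) and every
#' species must be on its guild's tree (when diversity with trees is on);
#' violations abort with the offending species named.
#'
#' @param table a [MonthlyVisitTable-class] (or a path readable by
#'   [readVisitTable()]).
#' @param traits a [TraitTable-class], required for the trait-mismatch and
#'   diversity stages.
#' @param birdTree,plantTree optional [ape::phylo] trees for sesPD.
#' @param sites site identifiers to analyse (default: all in `table`).
#' @param nSims community-null simulations per site (default 1000).
#' @param contributionSims focal-null simulations per species (default
#'   `nSims`).
#' @param restarts modularity restarts for observed/community-null networks.
#' @param contributionRestarts restarts inside the focal loops (default 3).
#' @param nullModel `"temporal"` or `"liberal"`.
#' @param stages character subset of
#'   `c("metrics", "nulls", "contributions", "traitmatch", "diversity")`.
#' @param seed integer master seed (required for a reproducible manifest).
#' @param outDir output directory, created if needed.
#' @return (invisibly) a named list of the result data.frames and the
#'   manifest.
#' @export
runAnalysis <- function(table, traits = NULL, birdTree = NULL,
                        plantTree = NULL, sites = NULL, nSims = 1000L,
                        contributionSims = nSims, restarts = 10L,
                        contributionRestarts = 3L,
                        nullModel = c("temporal", "liberal"),
                        stages = c("metrics", "nulls", "contributions",
                                   "traitmatch", "diversity"),
                        seed = 1L, outDir = ".") {
    nullModel <- match.arg(nullModel)
    stages <- match.arg(stages, c("metrics", "nulls", "contributions",
                                  "traitmatch", "diversity"),
                        several.ok = TRUE)
    if (is.character(table)) table <- readVisitTable(table)
    stopifnot(is(table, "MonthlyVisitTable"), nSims >= 2L)
    rec <- visitRecords(table)
    if (is.null(sites)) sites <- sort(unique(rec$site))
    .preflight(rec, traits, birdTree, plantTree, stages)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    res <- list()
    timings <- list()
    tick <- function(stage, expr) {
        t0 <- proc.time()[["elapsed"]]
        out <- expr
        timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
        out
    }
    if ("metrics" %in% stages)
        res$metrics <- tick("metrics", do.call(rbind, lapply(sites,
            function(s) {
                net <- buildNetwork(table, s)
                part <- optimizeModularity(net, restarts = restarts,
                                           seed = .childSeed(seed, paste0("obsQ:", s)))
                data.frame(site = s, Q = part@Q, C = connectance(net),
                           H2 = h2Prime(net), WNODF = weightedNODF(net),
                           stringsAsFactors = FALSE)
            })))
    if ("nulls" %in% stages)
        res$community_zscores <- tick("nulls", do.call(rbind, lapply(sites,
            function(s) {
                reps <- communityZScores(table, s, nSims = nSims,
                                         seed = .childSeed(seed, paste0("null:", s)),
                                         nullModel = nullModel,
                                         restarts = min(restarts, 3L))
                zScoreTable(reps, meta = data.frame(site = s))
            })))
    if ("contributions" %in% stages)
        res$contributions <- tick("contributions", do.call(rbind,
            lapply(sites, function(s)
                contributionTable(allContributions(
                    table, s, nSims = contributionSims,
                    seed = .childSeed(seed, paste0("contrib:", s)),
                    restarts = contributionRestarts)))))
    if ("traitmatch" %in% stages)
        res$trait_mismatch <- tick("traitmatch", do.call(rbind,
            lapply(sites, function(s) .siteTM(table, s, traits,
                contributionSims, .childSeed(seed, paste0("tm:", s))))))
    if ("diversity" %in% stages)
        res$diversity <- tick("diversity", do.call(rbind, lapply(sites,
            function(s) rbind(
                diversityReport(table, s, "bird", traits, birdTree,
                                seed = .childSeed(seed, paste0("divb:", s))),
                diversityReport(table, s, "plant", traits, plantTree,
                                seed = .childSeed(seed, paste0("divp:", s)))))))
    for (nm in names(res))
        utils::write.table(res[[nm]], file.path(outDir, paste0(nm, ".csv")),
                           sep = ",", row.names = FALSE, quote = FALSE)
    manifest <- list(
        package = "hummnet",
        version = as.character(utils::packageVersion("hummnet")),
        seed = seed, nSims = nSims, contributionSims = contributionSims,
        restarts = restarts, contributionRestarts = contributionRestarts,
        nullModel = nullModel, stages = stages, sites = sites,
        timings = timings,
        dropped = if (!is.null(res$community_zscores))
            sum(res$community_zscores$n_dropped) else 0L)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(c(res, list(manifest = manifest)))
}

# Trait-mismatch z for every species at a site (tidy rows).
.siteTM <- function(table, site, traits, nSims, seed) {
    sd <- .siteData(table, site)
    visited <- sd$plants[colSums(apply(sd$visitsBPM, c(1L, 2L), sum)) > 0]
    rows <- list()
    for (sp in sd$birds) {
        rep <- tmZScore(table, site, sp, "bird", traits, nSims = nSims,
                        seed = .childSeed(seed, sp))
        rows[[length(rows) + 1L]] <- zScoreTable(rep,
            meta = data.frame(site = site, species = sp, guild = "bird"))
    }
    for (sp in visited) {
        rep <- tmZScore(table, site, sp, "plant", traits, nSims = nSims,
                        seed = .childSeed(seed, sp))
        rows[[length(rows) + 1L]] <- zScoreTable(rep,
            meta = data.frame(site = site, species = sp, guild = "plant"))
    }
    do.call(rbind, rows)
}

.preflight <- function(rec, traits, birdTree, plantTree, stages) {
    vrec <- rec[!is.na(rec$bird) & rec$visits > 0, , drop = FALSE]
    birds <- unique(vrec$bird); plants <- unique(rec$plant)
    if (any(c("traitmatch", "diversity") %in% stages)) {
        if (is.null(traits))
            stop("traits are required for the requested stages")
        mb <- setdiff(birds, rownames(birdTraits(traits)))
        mp <- setdiff(plants, rownames(plantTraits(traits)))
        if (length(mb) || length(mp))
            stop("missing traits for: ",
                 paste(c(mb, mp), collapse = ", "))
    }
    if ("diversity" %in% stages) {
        if (!is.null(birdTree)) {
            mb <- setdiff(birds, birdTree$tip.label)
            if (length(mb)) stop("bird tree lacks tips: ",
                                 paste(mb, collapse = ", "))
        }
        if (!is.null(plantTree)) {
            mp <- setdiff(plants, plantTree$tip.label)
            if (length(mp)) stop("plant tree lacks tips: ",
                                 paste(mp, collapse = ", "))
        }
    }
    invisible(TRUE)
}

#' Descriptive summary of z-scores across sites
#'
#' Per statistic: mean z, its standard deviation, a 95% normal-theory
#' confidence interval for the mean, and the number of sites (degenerate or
#' missing z values excluded and counted). This is the descriptive surface
#' on which downstream significance tests (t-tests, GLMMs) operate; no
#' model fitting is done here.
#'
#' @param ztable data.frame with columns `statistic` and `z` (as produced
#'   by [zScoreTable()], [runAnalysis()] outputs, or
#'   [contributionTable()]).
#' @return data.frame: statistic, mean_z, sd_z, ci_lo, ci_hi, n, n_dropped.
#'   An empty input yields an empty frame with a warning; a zero-variance z
#'   vector yields a degenerate (zero-width) CI flagged by `sd_z = 0`.
#' @export
summarizeZScores <- function(ztable) {
    if (is.null(ztable) || !nrow(ztable)) {
        warning("empty z-score table")
        return(data.frame(statistic = character(0), mean_z = numeric(0),
                          sd_z = numeric(0), ci_lo = numeric(0),
                          ci_hi = numeric(0), n = integer(0),
                          n_dropped = integer(0)))
    }
    do.call(rbind, lapply(split(ztable, ztable$statistic), function(df) {
        z <- df$z[is.finite(df$z)]
        n <- length(z)
        mu <- mean(z); sdev <- if (n > 1) stats::sd(z) else 0
        half <- if (n > 1) stats::qt(0.975, n - 1) * sdev / sqrt(n) else 0
        data.frame(statistic = df$statistic[1L], mean_z = mu, sd_z = sdev,
                   ci_lo = mu - half, ci_hi = mu + half, n = n,
                   n_dropped = nrow(df) - n, stringsAsFactors = FALSE)
    }))
}
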