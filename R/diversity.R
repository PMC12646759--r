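# Site-level diversity: taxonomic richness, Faith's phylogenetic diversity
# and its standardized effect size, and Villeger functional divergence.

#' Taxonomic richness of a guild at a site
#'
#' Number of distinct species of the guild with at least one record at the
#' site. For plants, filmed-only (zero-visit) records count as presence;
#' for hummingbirds a species must have at least one visit.
#'
#' @param table a [MonthlyVisitTable-class].
#' @param site site identifier.
#' @param guild `"bird"` or `"plant"`.
#' @return integer count (0 with a warning if the guild is absent).
#' @export
richness <- function(table, site, guild = c("bird", "plant")) {
    guild <- match.arg(guild)
    sd <- .siteData(table, site)
    n <- if (guild == "bird") length(sd$birds) else length(sd$plants)
    if (n == 0L) warning("no ", guild, " species recorded at site ", site)
    n
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting the given taxa and
#' the root. A single taxon returns its root-to-tip path length (the
#' rooted convention; the alternative convention returns 0).
#'
#' @param tree a rooted [ape::phylo] tree with branch lengths.
#' @param taxa character vector of tip labels.
#' @return numeric summed branch length.
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' faithPD(tree, c("A", "B", "C"))  # 5
#' faithPD(tree, c("A", "B"))       # 3
#' @export
faithPD <- function(tree, taxa) {
    validatePhylogeny(tree)
    taxa <- unique(as.character(taxa))
    miss <- setdiff(taxa, tree$tip.label)
    if (length(miss))
        stop("taxa not in tree: ", paste(miss, collapse = ", "))
    if (!length(taxa)) return(0)
    # union of the edges on each taxon's path to the root
    parent <- integer(max(tree$edge))
    elen <- numeric(max(tree$edge))
    parent[tree$edge[, 2L]] <- tree$edge[, 1L]
    elen[tree$edge[, 2L]] <- tree$edge.length
    root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
    used <- logical(max(tree$edge))
    for (tip in match(taxa, tree$tip.label)) {
        node <- tip
        while (node != root && !used[node]) {
            used[node] <- TRUE
            node <- parent[node]
        }
    }
    sum(elen[used])
}

#' Standardized effect size of Faith's PD
#'
#' Compares the community's PD with the PD of `nNull` random draws of the
#' same number of tips from a species pool (tip-label randomization within
#' the pool). Negative z indicates phylogenetic clustering relative to the
#' pool; positive z, overdispersion.
#'
#' @param tree rooted [ape::phylo].
#' @param community character vector of tip labels, a subset of `pool`.
#' @param pool character vector of tip labels defining the null draw pool
#'   (e.g. the regional species list).
#' @param nNull number of null draws (default 999).
#' @param seed optional integer.
#' @param keepNulls store null PD values in the report.
#' @return A [ZScoreReport-class] with statistic `"ses_pd"`; the z slot is
#'   `NA` when the null is degenerate (e.g. `community` equals `pool`).
#' @export
sesPD <- function(tree, community, pool, nNull = 999L, seed = NULL,
                  keepNulls = FALSE) {
    community <- unique(as.character(community))
    pool <- unique(as.character(pool))
    if (length(setdiff(community, pool)))
        stop("community must be a subset of the pool")
    if (length(setdiff(pool, tree$tip.label)))
        stop("pool must be a subset of the tree's tips")
    obs <- faithPD(tree, community)
    nulls <- .withSeed(seed, vapply(seq_len(nNull), function(s)
        faithPD(tree, sample(pool, length(community))), numeric(1)))
    .zreport("ses_pd", obs, nulls, keepNulls = keepNulls)
}

# Identify the vertices of the convex hull of the rows of X by a
# separating-hyperplane linear program (boot::simplex): point x_i is a hull
# vertex iff some direction a with |a|_1 <= 1 satisfies
# a.(x_i - x_j) >= t for all j with optimal t > 0.
.hullVertices <- function(X, tol = 1e-8) {
    n <- nrow(X); d <- ncol(X)
    vapply(seq_len(n), function(i) {
        diffs <- sweep(X[-i, , drop = FALSE], 2L, X[i, ])  # x_j - x_i
        # vars: a+ (d), a- (d), t; maximize t
        A1 <- cbind(diffs, -diffs, 1)
        A1 <- rbind(A1, c(rep(1, 2 * d), 0))               # |a|_1 <= 1
        b1 <- c(rep(0, nrow(diffs)), 1)
        sol <- boot::simplex(a = c(rep(0, 2 * d), 1),
                             A1 = A1, b1 = b1, maxi = TRUE)
        sol$solved >= 0 && sol$value > tol
    }, logical(1))
}

#' Functional divergence (FDiv)
#'
#' The abundance-weighted tendency of species to lie toward the extremes of
#' the occupied trait space (Villeger et al. 2008). Traits are standardized
#' to zero mean and unit variance; the species forming the vertices of the
#' convex hull of the standardized trait cloud define the hull centroid G;
#' with `dG_i` each species' Euclidean distance to G and `w` the relative
#' abundances, `FDiv = (Dd + mean(dG)) / (D|d| + mean(dG))` where
#' `Dd = sum w_i (dG_i - mean(dG))` and `D|d| = sum w_i |dG_i - mean(dG)|`.
#' FDiv is in (0, 1], equals 1 when all species are equidistant from G, and
#' is invariant to positive rescaling of the abundances.
#'
#' @param traitMatrix numeric species x traits matrix with species rownames.
#' @param abundances positive per-species weights, aligned with the rows
#'   (recycled names checked when named).
#' @return numeric FDiv in (0, 1]; `NA` with a warning when there are fewer
#'   species than traits + 1 (the convex hull is degenerate).
#' @export
functionalDivergence <- function(traitMatrix, abundances) {
    X <- as.matrix(traitMatrix)
    if (!is.null(names(abundances)) && !is.null(rownames(X)))
        abundances <- abundances[rownames(X)]
    w <- as.numeric(abundances)
    stopifnot(length(w) == nrow(X))
    if (any(!is.finite(w)) || any(w <= 0))
        stop("abundance weights must be positive")
    keep <- apply(X, 2L, function(x) stats::sd(x) > 0)
    if (!all(keep)) {
        warning("dropping constant trait(s): ",
                paste(colnames(X)[!keep], collapse = ", "))
        X <- X[, keep, drop = FALSE]
    }
    if (nrow(X) < ncol(X) + 1L || ncol(X) == 0L) {
        warning("fewer species than traits + 1; FDiv undefined")
        return(NA_real_)
    }
    X <- scale(X)
    vert <- .hullVertices(X)
    if (!any(vert)) return(NA_real_)
    G <- colMeans(X[vert, , drop = FALSE])
    dG <- sqrt(rowSums(sweep(X, 2L, G)^2))
    w <- w / sum(w)
    dbar <- mean(dG)
    dd <- sum(w * (dG - dbar))
    dabs <- sum(w * abs(dG - dbar))
    (dd + dbar) / (dabs + dbar)
}

#' Site-level diversity report for one guild
#'
#' Convenience wrapper producing richness, observed Faith's PD, its
#' standardized effect size against a pool, and functional divergence with
#' abundances taken as each species' total visitation rate at the site.
#'
#' @param table a [MonthlyVisitTable-class].
#' @param site site identifier.
#' @param guild `"bird"` or `"plant"`.
#' @param traits a [TraitTable-class]; plant FDiv uses corolla length,
#'   opening and curvature, bird FDiv uses bill length, body mass, tail
#'   length, wing chord and tarsus length.
#' @param tree optional [ape::phylo] for the guild; when NULL the PD fields
#'   are NA.
#' @param pool species pool for [sesPD()]; defaults to the guild's species
#'   across all sites in `table`.
#' @param nNull null draws for sesPD.
#' @param seed optional integer.
#' @return one-row data.frame: site, guild, richness, pd_obs, ses_pd_z,
#'   fdiv.
#' @export
diversityReport <- function(table, site, guild = c("bird", "plant"), traits,
                            tree = NULL, pool = NULL, nNull = 999L,
                            seed = NULL) {
    guild <- match.arg(guild)
    net <- buildNetwork(table, site)
    A <- rateMatrix(net)
    if (guild == "bird") {
        sp <- rownames(A); ab <- rowSums(A)
        tm <- as.matrix(birdTraits(traits)[sp, c(
            "bill_length", "body_mass", "tail_length", "wing_chord",
            "tarsus_length")])
    } else {
        sp <- colnames(A); ab <- colSums(A)
        tm <- as.matrix(plantTraits(traits)[sp, c(
            "corolla_length", "corolla_opening", "corolla_curvature")])
    }
    rownames(tm) <- sp
    rich <- richness(table, site, guild)
    pd <- zpd <- NA_real_
    if (!is.null(tree)) {
        if (is.null(pool)) {
            allRec <- visitRecords(table)
            pool <- if (guild == "bird")
                unique(allRec$bird[!is.na(allRec$bird) & allRec$visits > 0])
            else unique(allRec$plant)
            pool <- intersect(pool, tree$tip.label)
        }
        comm <- intersect(sp, tree$tip.label)
        pd <- faithPD(tree, comm)
        zpd <- zValue(sesPD(tree, comm, pool, nNull = nNull, seed = seed))
    }
    fd <- suppressWarnings(functionalDivergence(tm, ab))
    data.frame(site = site, guild = guild, richness = rich, pd_obs = pd,
               ses_pd_z = zpd, fdiv = fd, stringsAsFactors = FALSE)
}
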