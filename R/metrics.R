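# Community-level descriptors of a quantitative bipartite network:
# connectance, weighted NODF nestedness, H2' specialization, and Barber
# modularity of a given partition (the optimizer lives in modularity.R).

.asRates <- function(net) {
    if (is(net, "QuantitativeNetwork")) rateMatrix(net)
    else if (is.matrix(net)) net
    else stop("expected a QuantitativeNetwork or a numeric matrix")
}

#' Connectance of a quantitative network
#'
#' The proportion of realized links among possible links: the number of
#' strictly positive cells divided by rows x columns.
#'
#' @param net a [QuantitativeNetwork-class] (or a bare rate matrix).
#' @return numeric in (0, 1] for a non-empty network.
#' @examples
#' connectance(matrix(c(1, 2, 0, 3), 2, 2,
#'                    dimnames = list(c("H1","H2"), c("P1","P2"))))
#' @export
connectance <- function(net) {
    A <- .asRates(net)
    if (!length(A)) stop("empty network")
    sum(A > 0) / length(A)
}

#' Weighted NODF nestedness
#'
#' Weighted nestedness based on overlap and decreasing fill (after
#' Almeida-Neto & Ulrich 2011). Rows and columns are sorted into decreasing
#' order; for an ordered pair (u above v) satisfying the strict
#' decreasing-order condition, the pairwise score is 100 times the fraction
#' of v's positive cells whose entries are strictly smaller than u's
#' corresponding entries; tied or reversed pairs score 0. WNODF is the mean
#' score over all row pairs and all column pairs, in [0, 100].
#'
#' Two conventions for ordering and gating pairs are provided. The default,
#' `"totals"`, sorts and gates on the weighted marginal totals. Because
#' visitation rates are continuous, ties have measure zero and the metric
#' discriminates even among near-saturated quantitative matrices. The
#' `"fill"` convention of the binary-derived published algorithm (and of
#' vegan/bipartite) sorts on the number of occupied cells with totals as
#' tie-break and gates on strictly decreasing fill; on matrices whose rows
#' or columns are equally filled (e.g. dense networks) most pairs tie and
#' score 0, a known degeneracy of fill-based NODF on saturated matrices.
#'
#' @param net a [QuantitativeNetwork-class] or rate matrix with at least 2
#'   rows and 2 columns.
#' @param comparison `"totals"` (default) or `"fill"`; see Details.
#' @return numeric in [0, 100]; `NA` for a degenerate (single row or single
#'   column) network.
#' @export
weightedNODF <- function(net, comparison = c("totals", "fill")) {
    comparison <- match.arg(comparison)
    A <- .asRates(net)
    if (nrow(A) < 2L || ncol(A) < 2L) return(NA_real_)
    pairSum <- function(M) {
        key <- if (comparison == "fill") rowSums(M > 0) else rowSums(M)
        M <- M[order(key, rowSums(M), decreasing = TRUE), , drop = FALSE]
        key <- if (comparison == "fill") rowSums(M > 0) else rowSums(M)
        s <- 0
        for (u in seq_len(nrow(M) - 1L)) for (v in (u + 1L):nrow(M)) {
            if (key[u] > key[v] && any(M[v, ] > 0)) {
                pos <- M[v, ] > 0
                s <- s + 100 * sum(M[v, pos] < M[u, pos]) / sum(pos)
            }
        }
        s
    }
    npairs <- choose(nrow(A), 2L) + choose(ncol(A), 2L)
    (pairSum(A) + pairSum(t(A))) / npairs
}

#' H2' network-level specialization
#'
#' Standardized two-dimensional Shannon entropy of the interaction matrix:
#' `H2' = (H2max - H2) / (H2max - H2min)` where `H2 = -sum p_ij log p_ij`
#' over cell proportions, `H2max` is the entropy of the outer product of the
#' marginal distributions (the expectation when partners are used in
#' proportion to availability), and `H2min` is the entropy of a maximally
#' packed matrix obtained by a greedy continuous mass-packing: repeatedly
#' allocate `min(remaining row mass, remaining column mass)` to the pair of
#' currently largest marginals. The result is clamped to [0, 1]; 1 means
#' perfect selectiveness (e.g. an exclusive diagonal matrix), 0 means
#' interactions exactly proportional to marginal availability.
#'
#' @param net a [QuantitativeNetwork-class] or rate matrix with at least 2
#'   rows and 2 columns and positive total.
#' @return numeric in [0, 1]; `NA` when the standardization range is
#'   degenerate.
#' @export
h2Prime <- function(net) {
    A <- .asRates(net)
    if (nrow(A) < 2L || ncol(A) < 2L) return(NA_real_)
    m <- sum(A)
    if (m <= 0) stop("network has zero total rate")
    p <- A / m
    ent <- function(x) { x <- x[x > 0]; -sum(x * log(x)) }
    H2 <- ent(p)
    pr <- rowSums(p); pc <- colSums(p)
    H2max <- ent(pr) + ent(pc)  # entropy of outer(pr, pc)
    H2min <- .h2minPack(pr, pc)
    if (abs(H2max - H2min) < 1e-12) return(NA_real_)
    min(1, max(0, (H2max - H2) / (H2max - H2min)))
}

# Greedy continuous packing of marginal masses; returns the entropy of the
# packed cell masses. Deterministic: ties broken by first (smallest) index.
.h2minPack <- function(pr, pc) {
    H <- 0
    repeat {
        i <- which.max(pr); j <- which.max(pc)
        a <- min(pr[i], pc[j])
        if (a <= 1e-15) break
        H <- H - a * log(a)
        pr[i] <- pr[i] - a; pc[j] <- pc[j] - a
    }
    H
}

#' Barber modularity of a given bipartite partition
#'
#' Evaluates the weighted Barber bipartite modularity
#' `Q = (1/m) * sum_ij (A_ij - k_i d_j / m) delta(g_i, g_j)` where `A` is the
#' rate matrix with total `m`, `k_i` and `d_j` the row and column marginal
#' totals, and `delta` indicates that bird i and plant j share a module.
#'
#' @param net a [QuantitativeNetwork-class] or rate matrix.
#' @param partition a [ModulePartition-class], or a list with integer
#'   elements `rows` and `cols` giving module ids.
#' @return numeric Q in (-1, 1).
#' @export
barberModularity <- function(net, partition) {
    A <- .asRates(net)
    if (is(partition, "ModulePartition"))
        partition <- moduleLabels(partition)
    gr <- as.integer(partition$rows); gc <- as.integer(partition$cols)
    stopifnot(length(gr) == nrow(A), length(gc) == ncol(A))
    m <- sum(A)
    k <- rowSums(A); d <- colSums(A)
    agree <- outer(gr, gc, "==")
    sum((A - outer(k, d) / m)[agree]) / m
}
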