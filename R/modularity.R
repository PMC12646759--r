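# Weighted bipartite module detection: alternating label propagation to a
# local optimum of Barber Q, followed by agglomerative module merging, with
# random restarts (DIRTLPAwb+-style search).

# Q from integer label vectors (contiguity not required).
.qLabels <- function(A, m, k, d, gr, gc) {
    agree <- outer(gr, gc, "==")
    sum((A - outer(k, d) / m)[agree]) / m
}

# One label-propagation run from an initial column labelling.
# Rows adopt the column-side label with the best Q gain and vice versa,
# ties broken by the smallest label id, until Q stops improving.
.lpaRun <- function(A, m, k, d, gc0, tol, maxit = 100L) {
    gc <- gc0
    gr <- rep(1L, nrow(A))
    best <- -Inf
    for (it in seq_len(maxit)) {
        labs <- sort(unique(gc))
        Ic <- outer(gc, labs, "==") + 0
        S <- A %*% Ic                      # rows x labels rate mass
        D <- as.vector(crossprod(Ic, d))   # label column-marginal totals
        gr <- labs[max.col(S / m - outer(k, D) / m^2, ties.method = "first")]
        labs <- sort(unique(gr))
        Ir <- outer(gr, labs, "==") + 0
        Tm <- crossprod(A, Ir)             # cols x labels rate mass
        K <- as.vector(crossprod(Ir, k))
        gc <- labs[max.col(Tm / m - outer(d, K) / m^2, ties.method = "first")]
        q <- .qLabels(A, m, k, d, gr, gc)
        if (q <= best + tol) break
        best <- q
    }
    list(gr = gr, gc = gc)
}

# Greedy agglomerative merging of modules while Q increases.
.mergeModules <- function(A, m, k, d, gr, gc, tol) {
    labs <- sort(unique(c(gr, gc)))
    gr <- match(gr, labs); gc <- match(gc, labs)
    L <- length(labs)
    if (L > 1L) {
        Ir <- outer(gr, seq_len(L), "==") + 0
        Ic <- outer(gc, seq_len(L), "==") + 0
        E <- crossprod(Ir, A %*% Ic)       # module-pair rate mass
        K <- as.vector(crossprod(Ir, k))
        D <- as.vector(crossprod(Ic, d))
        alive <- rep(TRUE, L)
        repeat {
            idx <- which(alive)
            if (length(idx) < 2L) break
            gain <- matrix(-Inf, L, L)
            for (a in idx) for (b in idx) if (a < b)
                gain[a, b] <- (E[a, b] + E[b, a]) / m -
                    (K[a] * D[b] + K[b] * D[a]) / m^2
            bestPair <- arrayInd(which.max(gain), dim(gain))
            if (gain[bestPair] <= tol) break
            a <- bestPair[1L]; b <- bestPair[2L]
            gr[gr == b] <- a; gc[gc == b] <- a
            E[a, ] <- E[a, ] + E[b, ]; E[, a] <- E[, a] + E[, b]
            K[a] <- K[a] + K[b]; D[a] <- D[a] + D[b]
            alive[b] <- FALSE
        }
    }
    labs <- sort(unique(c(gr, gc)))
    list(gr = match(gr, labs), gc = match(gc, labs),
         Q = .qLabels(A, m, k, d, gr, gc))
}

.optQ <- function(A, restarts, tol) {
    m <- sum(A); k <- rowSums(A); d <- colSums(A)
    r <- nrow(A); cc <- ncol(A)
    if (r == 1L || cc == 1L)
        return(list(gr = rep(1L, r), gc = rep(1L, cc), Q = 0))
    best <- NULL
    for (s in seq_len(max(1L, restarts))) {
        gc0 <- if (s == 1L) seq_len(cc)
               else sample.int(min(r, cc), cc, replace = TRUE)
        run <- .lpaRun(A, m, k, d, gc0, tol)
        run <- .mergeModules(A, m, k, d, run$gr, run$gc, tol)
        if (is.null(best) || run$Q > best$Q + tol) best <- run
    }
    if (best$Q < 0)  # never worse than the single-module partition
        best <- list(gr = rep(1L, r), gc = rep(1L, cc), Q = 0)
    best
}

#' Optimize Barber modularity by label propagation with module merging
#'
#' Searches for the bipartite partition maximizing weighted Barber
#' modularity. Each restart runs an alternating weighted label propagation
#' (rows adopt the column-side module with the largest modularity gain and
#' vice versa, ties resolved to the smallest module id) to a local optimum,
#' then greedily merges module pairs while Q increases. The best partition
#' over `restarts` initializations is returned; the first initialization is
#' deterministic (each column its own module), later ones are random, so the
#' result is reproducible given `seed`. The returned Q is never below the
#' single-module partition (Q >= 0).
#'
#' @param net a [QuantitativeNetwork-class] or rate matrix.
#' @param restarts number of initializations (default 10).
#' @param seed optional integer; when given, results are reproducible and
#'   the ambient RNG state is left untouched.
#' @param tol minimum Q improvement accepted during propagation and merging.
#' @return A [ModulePartition-class] with `rowLabels`, `colLabels` and `Q`.
#' @examples
#' A <- matrix(0, 4, 4, dimnames = list(paste0("H", 1:4), paste0("P", 1:4)))
#' A[cbind(1:4, 1:4)] <- 1            # 4 equal blocks
#' optimizeModularity(A, seed = 1)    # Q = 1 - 1/4
#' @export
optimizeModularity <- function(net, restarts = 10L, seed = NULL, tol = 1e-10) {
    A <- .asRates(net)
    if (!length(A) || sum(A) <= 0) stop("empty network")
    res <- .withSeed(seed, .optQ(A, restarts, tol))
    new("ModulePartition", rowLabels = as.integer(res$gr),
        colLabels = as.integer(res$gc), Q = res$Q)
}

# Fast internal entry point used inside null loops: returns only Q.
.optQvalue <- function(A, restarts, tol = 1e-10) .optQ(A, restarts, tol)$Q
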