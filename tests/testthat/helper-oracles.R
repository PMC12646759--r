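# Independent straight-from-definition oracles. These deliberately use a
# different code path (explicit double loops, no shared helpers) from the
# package implementations they check.

# Weighted NODF: sort rows/cols into decreasing order (marginal totals, or
# occupied-cell fill with totals as tie-break); for each ordered pair with
# a strictly decreasing key, 100 * (# cells where the lower entry is
# positive and strictly below the upper) / (# positive cells in the lower);
# mean over all row and column pairs.
oracleWNODF <- function(A, comparison = "totals") {
    score <- function(M) {
        keyOf <- function(M) {
            if (comparison == "fill") apply(M, 1, function(x) sum(x > 0))
            else rowSums(M)
        }
        M <- M[order(keyOf(M), rowSums(M), decreasing = TRUE), ,
               drop = FALSE]
        fl <- keyOf(M)
        vals <- c()
        for (u in seq_len(nrow(M))) for (v in seq_len(nrow(M))) {
            if (u >= v) next
            if (fl[u] > fl[v] && sum(M[v, ] > 0) > 0) {
                np <- 0; nlt <- 0
                for (j in seq_len(ncol(M))) {
                    if (M[v, j] > 0) {
                        np <- np + 1
                        if (M[v, j] < M[u, j]) nlt <- nlt + 1
                    }
                }
                vals <- c(vals, 100 * nlt / np)
            } else vals <- c(vals, 0)
        }
        vals
    }
    mean(c(score(A), score(t(A))))
}

# H2': same formulas, independent loop structure.
oracleH2 <- function(A) {
    p <- A / sum(A)
    H2 <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
        if (p[i, j] > 0) H2 <- H2 - p[i, j] * log(p[i, j])
    pr <- rowSums(p); pc <- colSums(p)
    O <- pr %o% pc
    H2max <- -sum(O[O > 0] * log(O[O > 0]))
    # greedy continuous packing for H2min
    H2min <- 0
    r <- pr; cc <- pc
    while (TRUE) {
        i <- order(r, decreasing = TRUE)[1]
        j <- order(cc, decreasing = TRUE)[1]
        a <- min(r[i], cc[j])
        if (a <= 1e-15) break
        H2min <- H2min - a * log(a)
        r[i] <- r[i] - a
        cc[j] <- cc[j] - a
    }
    if (abs(H2max - H2min) < 1e-12) return(NA_real_)
    min(1, max(0, (H2max - H2) / (H2max - H2min)))
}

# Barber bipartite modularity by naive double summation.
oracleBarberQ <- function(A, gr, gc) {
    m <- sum(A)
    q <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
        if (gr[i] == gc[j])
            q <- q + A[i, j] - sum(A[i, ]) * sum(A[, j]) / m
    q / m
}

# Trait mismatch by explicit pairwise summation.
oracleTM <- function(A, bills, corollas, focal, guild) {
    num <- 0; den <- 0
    if (guild == "bird") {
        i <- match(focal, rownames(A))
        for (j in seq_len(ncol(A))) {
            num <- num + abs(bills[focal] - corollas[colnames(A)[j]]) * A[i, j]
            den <- den + A[i, j]
        }
    } else {
        j <- match(focal, colnames(A))
        for (i in seq_len(nrow(A))) {
            num <- num + abs(bills[rownames(A)[i]] - corollas[focal]) * A[i, j]
            den <- den + A[i, j]
        }
    }
    unname(num / den)
}

# Random positive-ish rate matrix with guaranteed non-empty rows/columns.
randomRateMatrix <- function(nr, nc, fill = 0.7) {
    repeat {
        A <- matrix(ifelse(runif(nr * nc) < fill,
                           round(runif(nr * nc, 0.1, 9), 3), 0), nr, nc)
        if (all(rowSums(A) > 0) && all(colSums(A) > 0)) break
    }
    dimnames(A) <- list(sprintf("H%02d", seq_len(nr)),
                        sprintf("P%02d", seq_len(nc)))
    A
}
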