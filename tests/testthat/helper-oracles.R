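# Independent oracles and graph fixtures used across the suite.
# Deliberately written from first principles (no package internals, no
# igraph) so the implementation is checked against a second route.

# Literal scalar biweight midcorrelation: median/MAD, Tukey weights on the
# 9-MAD scale, weighted cross-product over the product of weighted norms.
oracleBicor <- function(x, y) {
    prep <- function(v) {
        med <- median(v)
        s <- median(abs(v - med))
        u <- (v - med) / (9 * s)
        w <- ifelse(1 - abs(u) > 0, (1 - u^2)^2, 0)
        (v - med) * w
    }
    a <- prep(x)
    b <- prep(y)
    sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# Build a BinaryAdjacency from an unnamed 0/1 matrix (upper triangle used).
mkAdj <- function(m, ids = NULL) {
    n <- nrow(m)
    if (is.null(ids))
        ids <- sprintf("g%02d", seq_len(n))
    m <- (m + t(m)) > 0
    m <- m * 1
    diag(m) <- 0
    dimnames(m) <- list(ids, ids)
    BinaryAdjacency(m)
}

# Random symmetric 0/1 adjacency on n vertices with edge probability p.
randomAdj <- function(n, p) {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- rbinom(n * (n - 1) / 2, 1, p)
    mkAdj(m)
}

# Graph on n vertices from an integer edge bitmask (for exhaustive sweeps).
adjFromBits <- function(n, bits) {
    m <- matrix(0, n, n)
    idx <- which(upper.tri(m))
    on <- as.logical(bitwAnd(bits, 2^(seq_along(idx) - 1)) > 0)
    m[idx[on]] <- 1
    mkAdj(m)
}

# Brute-force k-clique percolation: enumerate every complete k-subset,
# link k-cliques sharing k - 1 vertices, take connected-component unions.
# Returns a list of sorted gene-id vectors, sorted by decreasing size then
# lexicographic first member (same deterministic order as the package).
oracleKCliqueCommunities <- function(a, k) {
    v <- adjValues(a)
    ids <- rownames(v)
    n <- nrow(v)
    if (n < k)
        return(list())
    subsets <- combn(n, k, simplify = FALSE)
    complete <- Filter(function(s) all(v[s, s][upper.tri(v[s, s])] == 1),
                       subsets)
    L <- length(complete)
    if (L == 0L)
        return(list())
    parent <- seq_len(L)
    findRoot <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
    }
    if (L > 1L) {
        for (i in seq_len(L - 1L)) {
            for (j in seq(i + 1L, L)) {
                if (length(intersect(complete[[i]], complete[[j]])) >= k - 1) {
                    ri <- findRoot(i); rj <- findRoot(j)
                    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
                }
            }
        }
    }
    roots <- vapply(seq_len(L), findRoot, integer(1))
    mods <- lapply(unique(roots), function(r)
        sort(ids[sort(unique(unlist(complete[roots == r])))]))
    sizes <- lengths(mods)
    first <- vapply(mods, `[`, character(1), 1L)
    mods[order(-sizes, first, method = "radix")]
}

# Convenience: module list of a ModuleSet in the oracle's canonical form.
moduleList <- function(ms) modules(ms)
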