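.checkSameGenes <- function(cNormal, cDisease) {
    stopifnot(is(cNormal, "CorrelationMatrix"),
              is(cDisease, "CorrelationMatrix"))
    if (!identical(geneIds(cNormal), geneIds(cDisease)))
        stop("the two correlation matrices must cover the same genes ",
             "in the same order")
}

#' Binarize a pair of correlation matrices into a differential graph
#'
#' Turns two condition-specific correlation matrices into one binary
#' differential-coexpression graph. Three edge rules are available:
#'
#' * `"gain"`: an edge joins genes i and j when their normal-condition
#'   correlation is >= `t1` AND their disease-condition correlation is
#'   <= `t2` (coexpressed in normal, lost in disease).
#' * `"loss"`: the mirrored rule — normal correlation <= `t1` AND disease
#'   correlation >= `t2` (coexpression gained in disease).
#' * `"absdiff"`: an edge when |c_N(i,j) - c_D(i,j)| >= `t3` AND
#'   |c_N(i,j)| >= |c_D(i,j)|. The difference is taken on signed
#'   correlations, so correlation reversals (e.g. +0.9 to -0.7, a change of
#'   1.6) are captured; the magnitude comparison uses absolute values.
#'
#' In gain/loss modes correlations are compared as absolute values when
#' `useAbsolute = TRUE` (the default), or as signed values otherwise.
#'
#' @param cNormal,cDisease [CorrelationMatrix-class] objects over identical
#'   gene sets (normal and disease conditions).
#' @param mode edge rule, one of `"gain"`, `"loss"`, `"absdiff"`.
#' @param t1,t2 thresholds in [0, 1] for the normal and disease matrices
#'   (gain/loss modes only).
#' @param t3 threshold in [0, 2] on the correlation change (absdiff mode
#'   only).
#' @param useAbsolute compare absolute correlations in gain/loss modes.
#' @return a [BinaryAdjacency-class]; symmetric, zero diagonal.
#' @examples
#' cn <- CorrelationMatrix(matrix(c(1, .9, .9, 1), 2, 2,
#'     dimnames = list(c("a", "b"), c("a", "b"))))
#' cd <- CorrelationMatrix(matrix(c(1, .1, .1, 1), 2, 2,
#'     dimnames = list(c("a", "b"), c("a", "b"))))
#' binarizeNetwork(cn, cd, mode = "gain", t1 = 0.8, t2 = 0.2)
#' @export
binarizeNetwork <- function(cNormal, cDisease,
                            mode = c("gain", "loss", "absdiff"),
                            t1 = 0.8, t2 = 0.4, t3 = 1.3,
                            useAbsolute = TRUE) {
    mode <- match.arg(mode)
    .checkSameGenes(cNormal, cDisease)
    cn <- corValues(cNormal)
    cd <- corValues(cDisease)
    if (mode %in% c("gain", "loss")) {
        stopifnot(t1 >= 0, t1 <= 1, t2 >= 0, t2 <= 1)
        if (useAbsolute) {
            cn <- abs(cn)
            cd <- abs(cd)
        }
        a <- if (mode == "gain") (cn >= t1) & (cd <= t2)
             else                (cn <= t1) & (cd >= t2)
    } else {
        stopifnot(t3 >= 0, t3 <= 2)
        a <- (abs(cn - cd) >= t3) & (abs(cn) >= abs(cd))
    }
    a <- a * 1
    diag(a) <- 0
    BinaryAdjacency(a)
}

#' Remove isolated genes from a binary graph
#'
#' Drops every gene with degree zero (a gene not connected to any other —
#' an "outlier" of the graph). Idempotent; never adds edges. The result may
#' be empty.
#'
#' @param a a [BinaryAdjacency-class].
#' @return a [BinaryAdjacency-class] on the connected genes only.
#' @export
removeIsolated <- function(a) {
    stopifnot(is(a, "BinaryAdjacency"))
    v <- adjValues(a)
    keep <- rowSums(v) > 0
    BinaryAdjacency(v[keep, keep, drop = FALSE])
}

#' Discard the lowest-degree fraction of genes
#'
#' Removes the `floor(fraction * n)` genes of lowest degree in one pass:
#' degrees are computed once on the input graph, genes are ordered by
#' (degree, gene id) with a stable sort, and the lowest block is dropped.
#' Tied degrees are therefore resolved deterministically by gene-id order.
#'
#' @param a a [BinaryAdjacency-class].
#' @param fraction fraction of genes to discard, in [0, 1).
#' @return a [BinaryAdjacency-class] on the surviving genes.
#' @examples
#' ids <- letters[1:5]
#' star <- matrix(0, 5, 5, dimnames = list(ids, ids))
#' star[1, 2:5] <- star[2:5, 1] <- 1    # hub "a" with 4 leaves
#' geneIds(filterLowDegree(BinaryAdjacency(star), 0.5))
#' @export
filterLowDegree <- function(a, fraction = 0.5) {
    stopifnot(is(a, "BinaryAdjacency"), fraction >= 0, fraction < 1)
    v <- adjValues(a)
    n <- nrow(v)
    nDrop <- floor(fraction * n)
    if (nDrop == 0L)
        return(a)
    deg <- rowSums(v)
    ord <- order(deg, rownames(v), method = "radix")
    keep <- sort(ord[-seq_len(nDrop)])
    BinaryAdjacency(v[keep, keep, drop = FALSE])
}

#' @rdname graphDensity
setMethod("graphDensity", "BinaryAdjacency", function(x) {
    v <- adjValues(x)
    n <- nrow(v)
    if (n < 2L)
        stop("density needs at least 2 genes")
    (sum(v) / 2) / (n * (n - 1) / 2)
})

#' Complete graph on n vertices
#'
#' Convenience constructor for a clique: every pair of vertices is joined.
#'
#' @param n number of vertices (>= 1).
#' @param ids optional character vector of vertex names.
#' @return a [BinaryAdjacency-class].
#' @export
completeGraph <- function(n, ids = sprintf("g%03d", seq_len(n))) {
    stopifnot(n >= 1, length(ids) == n)
    v <- matrix(1, n, n, dimnames = list(ids, ids))
    diag(v) <- 0
    BinaryAdjacency(v)
}
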