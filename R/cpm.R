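.asIgraph <- function(a) {
    igraph::graph_from_adjacency_matrix(adjValues(a) > 0,
                                        mode = "undirected", diag = FALSE)
}

# Deterministic ordering of a list of sorted character vectors:
# lexicographic on the concatenated members.
.orderCliqueList <- function(cliques) {
    if (!length(cliques))
        return(integer())
    keys <- vapply(cliques, paste, character(1), collapse = "\r")
    order(keys, method = "radix")
}

# Plain union-find with path compression; used for clique percolation.
.unionFind <- function(n) {
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    unite <- function(i, j) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    }
    list(find = find, unite = unite,
         roots = function() vapply(seq_len(n), find, integer(1)))
}

#' Enumerate the maximal cliques of a binary graph
#'
#' All maximal complete subgraphs (cliques not contained in any larger
#' clique), each reported once with members sorted, the list sorted
#' lexicographically for deterministic output. Enumeration uses the
#' Bron-Kerbosch algorithm via igraph.
#'
#' @param a a [BinaryAdjacency-class].
#' @param minSize smallest clique size to report (default 1, i.e. isolated
#'   vertices count as maximal cliques).
#' @return a list of sorted character vectors of gene ids.
#' @examples
#' # two triangles sharing an edge
#' m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
#' m[cbind(c(1,1,2,2,3), c(2,3,3,4,4))] <- 1
#' maximalCliques(BinaryAdjacency(m + t(m)))
#' @export
maximalCliques <- function(a, minSize = 1) {
    stopifnot(is(a, "BinaryAdjacency"))
    if (nrow(adjValues(a)) == 0L)
        return(list())
    g <- .asIgraph(a)
    cl <- igraph::max_cliques(g, min = minSize)
    cl <- lapply(cl, function(x) sort(igraph::V(g)$name[x]))
    cl[.orderCliqueList(cl)]
}

# Connected components of the clique-overlap graph: maximal cliques of size
# >= k are linked when they share >= k - 1 vertices. Equivalent to literal
# k-clique percolation (every k-clique lies in a maximal clique; two
# adjacent k-cliques force their maximal cliques into the same component).
.percolate <- function(cliques, k) {
    nc <- length(cliques)
    if (nc == 0L)
        return(integer())
    if (nc == 1L)
        return(1L)
    genes <- sort(unique(unlist(cliques)))
    inc <- matrix(0L, nc, length(genes), dimnames = list(NULL, genes))
    for (i in seq_len(nc))
        inc[i, cliques[[i]]] <- 1L
    overlap <- tcrossprod(inc)
    uf <- .unionFind(nc)
    link <- which(overlap >= k - 1 & upper.tri(overlap), arr.ind = TRUE)
    for (r in seq_len(nrow(link)))
        uf$unite(link[r, 1L], link[r, 2L])
    roots <- uf$roots()
    match(roots, sort(unique(roots)))
}

#' k-clique communities (clique percolation method)
#'
#' Detects overlapping modules as k-clique percolation clusters: a module is
#' the union of all k-cliques reachable from one another through adjacency,
#' where two k-cliques are adjacent when they share k - 1 vertices.
#' Computed by the standard reduction: the maximal cliques of size >= k are
#' the nodes of a clique-overlap graph, linked when they share >= k - 1
#' vertices; modules are the connected components' vertex unions. Modules
#' may overlap in genes; raising k makes them smaller and more cohesive.
#'
#' @param a a [BinaryAdjacency-class].
#' @param k clique size, integer >= 2. `k = 2` reduces to ordinary
#'   connected components of the graph.
#' @return a [ModuleSet-class]; empty when no clique of size k exists.
#' @examples
#' m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
#' m[cbind(c(1,1,2,2,3), c(2,3,3,4,4))] <- 1
#' kCliqueCommunities(BinaryAdjacency(m + t(m)), k = 3)
#' @export
kCliqueCommunities <- function(a, k = 4) {
    stopifnot(is(a, "BinaryAdjacency"))
    k <- as.integer(k)
    if (is.na(k) || k < 2L)
        stop("'k' must be an integer >= 2")
    cliques <- maximalCliques(a, minSize = k)
    comp <- .percolate(cliques, k)
    mods <- list()
    cls <- list()
    for (ci in seq_len(max(comp, 0L))) {
        cl <- cliques[comp == ci]
        mods[[ci]] <- sort(unique(unlist(cl)))
        cls[[ci]] <- cl
    }
    if (length(mods)) {
        sizes <- lengths(mods)
        first <- vapply(mods, `[`, character(1), 1L)
        ord <- order(-sizes, first, method = "radix")
        mods <- mods[ord]
        cls <- cls[ord]
    }
    ModuleSet(modules = mods, cliques = cls, k = k)
}

#' Critical edge probability of k-clique percolation
#'
#' The threshold edge probability at which a giant k-clique percolation
#' cluster appears in an Erdos-Renyi random graph of N vertices:
#' d(k) = 1 / ((k - 1) * N^(1/(k-1))). For k = 2 this is the familiar 1/N
#' giant-component threshold. Exposed as a diagnostic to guide threshold
#' selection: binarization thresholds producing densities far above d(k)
#' yield many overlapping cliques, far below yield none.
#'
#' @param nGenes number of vertices N (>= 1).
#' @param k clique size, integer >= 2.
#' @return a positive number, decreasing in N.
#' @examples
#' criticalThreshold(100, 3)  # 1 / (2 * sqrt(100)) = 0.05
#' @export
criticalThreshold <- function(nGenes, k) {
    stopifnot(nGenes >= 1)
    if (k < 2)
        stop("'k' must be >= 2")
    1 / ((k - 1) * nGenes^(1 / (k - 1)))
}

#' Expected number of k-cliques in a random graph
#'
#' Analytic estimate choose(N, k) * d^(k(k-1)/2) of the number of k-cliques
#' in an Erdos-Renyi graph with edge probability d. At k = 2 this is the
#' expected edge count choose(N, 2) * d.
#'
#' @param nGenes number of vertices N.
#' @param k clique size >= 2.
#' @param d edge probability in [0, 1].
#' @return a non-negative number.
#' @export
estimateTotalKCliques <- function(nGenes, k, d) {
    stopifnot(nGenes >= 0, k >= 2, d >= 0, d <= 1)
    choose(nGenes, k) * d^(k * (k - 1) / 2)
}

# Enumerate every k-clique (complete k-subset) of the graph.
.allKCliques <- function(a, k) {
    v <- adjValues(a)
    if (nrow(v) < k)
        return(list())
    g <- .asIgraph(a)
    cl <- igraph::cliques(g, min = k, max = k)
    cl <- lapply(cl, function(x) sort(igraph::V(g)$name[x]))
    cl[.orderCliqueList(cl)]
}

#' Percolation order parameters of a binary graph
#'
#' Measures the k-clique percolation transition on an observed graph. All
#' k-cliques are enumerated and percolated literally (adjacency = sharing
#' k - 1 vertices). The largest cluster (by vertex count, ties broken by the
#' lexicographically smallest member) yields N* (its vertices) and L* (its
#' k-cliques); order parameters are phi = N*/N and varphi = L*/L where L is
#' the exact total number of k-cliques (varphi = 0 when L = 0). The
#' random-graph critical threshold d(k) for this N is included for
#' reference.
#'
#' @param a a non-empty [BinaryAdjacency-class].
#' @param k clique size, integer >= 2.
#' @return a [PercolationStats-class].
#' @examples
#' orderParameters(completeGraph(5), k = 3)  # phi = 1, varphi = 1
#' @export
orderParameters <- function(a, k = 4) {
    stopifnot(is(a, "BinaryAdjacency"))
    k <- as.integer(k)
    if (is.na(k) || k < 2L)
        stop("'k' must be an integer >= 2")
    n <- nrow(adjValues(a))
    if (n == 0L)
        stop("empty graph")
    cliques <- .allKCliques(a, k)
    L <- length(cliques)
    if (L == 0L) {
        return(new("PercolationStats", nGenes = n, k = k,
                   dk = criticalThreshold(n, k), nStar = 0L, phi = 0,
                   lTotal = 0, lStar = 0, varphi = 0))
    }
    comp <- .percolate(cliques, k)
    nComp <- max(comp)
    verts <- lapply(seq_len(nComp),
                    function(ci) sort(unique(unlist(cliques[comp == ci]))))
    sizes <- lengths(verts)
    first <- vapply(verts, `[`, character(1), 1L)
    best <- order(-sizes, first, method = "radix")[1L]
    nStar <- sizes[best]
    lStar <- sum(comp == best)
    new("PercolationStats", nGenes = n, k = k,
        dk = criticalThreshold(n, k), nStar = as.integer(nStar),
        phi = nStar / n, lTotal = as.numeric(L), lStar = as.numeric(lStar),
        varphi = lStar / L)
}
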