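#' @import methods
NULL

.checkSquareNamed <- function(values) {
    msg <- character()
    if (!is.matrix(values) || !is.numeric(values))
        msg <- c(msg, "'values' must be a numeric matrix")
    else {
        if (nrow(values) != ncol(values))
            msg <- c(msg, "'values' must be square")
        ids <- rownames(values)
        if (nrow(values) > 0L) {
            if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
                msg <- c(msg, "rownames must be unique non-empty gene ids")
            if (!identical(rownames(values), colnames(values)))
                msg <- c(msg, "rownames and colnames must be identical")
        }
        if (anyNA(values))
            msg <- c(msg, "'values' must not contain missing entries")
    }
    msg
}

#' ExpressionMatrix: a genes-by-samples expression matrix for one condition
#'
#' Thin container for a dense, complete expression matrix. Genes are rows
#' (unique identifiers as rownames), samples are columns. A condition label
#' tags which experimental group the samples belong to. Missing values are
#' rejected at construction: the downstream correlation machinery assumes a
#' complete matrix and no imputation is performed.
#'
#' @slot values numeric matrix, genes x samples, no missing entries.
#' @slot condition single character label, e.g. "normal" or "disease".
#'
#' @seealso [ExpressionMatrix()], [bicorMatrix()], [readExpression()]
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
    representation(values = "matrix", condition = "character"),
    validity = function(object) {
        v <- object@values
        msg <- character()
        if (!is.numeric(v))
            msg <- c(msg, "'values' must be numeric")
        if (anyNA(v) || any(!is.finite(v)))
            msg <- c(msg, "'values' must be finite with no missing entries")
        if (ncol(v) < 2L)
            msg <- c(msg, "at least 2 samples are required")
        ids <- rownames(v)
        if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
            msg <- c(msg, "rownames must be unique non-empty gene ids")
        sids <- colnames(v)
        if (is.null(sids) || anyDuplicated(sids))
            msg <- c(msg, "colnames must be unique sample ids")
        if (length(object@condition) != 1L || is.na(object@condition))
            msg <- c(msg, "'condition' must be a single label")
        if (length(msg)) msg else TRUE
    })

#' Construct an ExpressionMatrix
#'
#' @param values numeric genes x samples matrix with unique rownames (gene
#'   ids) and colnames (sample ids). Colnames are generated if absent.
#' @param condition single character condition label.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), NULL))
#' x <- ExpressionMatrix(m, "normal")
#' geneIds(x)
#' @export
ExpressionMatrix <- function(values, condition = "unspecified") {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(colnames(values)))
        colnames(values) <- paste0("S", seq_len(ncol(values)))
    new("ExpressionMatrix", values = values,
        condition = as.character(condition))
}

#' CorrelationMatrix: symmetric gene-gene biweight midcorrelation matrix
#'
#' Square symmetric matrix of correlation values in [-1, 1], rows/columns
#' named by gene id. The diagonal is 1 except for degenerate genes (zero
#' median absolute deviation) under the "zero" fallback, where the whole
#' row/column including the diagonal is 0.
#'
#' @slot values numeric symmetric matrix in [-1, 1].
#' @seealso [bicorMatrix()]
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
    representation(values = "matrix"),
    validity = function(object) {
        v <- object@values
        msg <- .checkSquareNamed(v)
        if (!length(msg)) {
            if (max(abs(v)) > 1 + 1e-8)
                msg <- c(msg, "correlation values must lie in [-1, 1]")
            if (!isSymmetric(unname(v), tol = 1e-10))
                msg <- c(msg, "'values' must be symmetric")
        }
        if (length(msg)) msg else TRUE
    })

#' @rdname CorrelationMatrix-class
#' @param values numeric symmetric gene x gene matrix with gene ids as
#'   dimnames.
#' @return A [CorrelationMatrix-class] object.
#' @export
CorrelationMatrix <- function(values) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    # clamp round-off just outside [-1, 1]
    values[values > 1] <- pmin(values[values > 1], 1)
    values[values < -1] <- pmax(values[values < -1], -1)
    new("CorrelationMatrix", values = values)
}

#' BinaryAdjacency: an unweighted, undirected gene graph
#'
#' Symmetric 0/1 matrix with zero diagonal encoding the binary differential
#' coexpression graph obtained from two condition-specific correlation
#' matrices by a threshold rule.
#'
#' @slot values numeric symmetric matrix of 0s and 1s, zero diagonal.
#' @seealso [binarizeNetwork()], [graphDensity()], [kCliqueCommunities()]
#' @exportClass BinaryAdjacency
setClass("BinaryAdjacency",
    representation(values = "matrix"),
    validity = function(object) {
        v <- object@values
        msg <- .checkSquareNamed(v)
        if (!length(msg)) {
            if (!all(v %in% c(0, 1)))
                msg <- c(msg, "entries must be 0 or 1")
            if (nrow(v) > 0L && any(diag(v) != 0))
                msg <- c(msg, "diagonal must be zero")
            if (!identical(unname(v), unname(t(v))))
                msg <- c(msg, "'values' must be symmetric")
        }
        if (length(msg)) msg else TRUE
    })

#' @rdname BinaryAdjacency-class
#' @param values symmetric 0/1 gene x gene matrix with gene ids as dimnames;
#'   the diagonal is zeroed.
#' @return A [BinaryAdjacency-class] object.
#' @export
BinaryAdjacency <- function(values) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (nrow(values) > 0L) diag(values) <- 0
    new("BinaryAdjacency", values = values)
}

#' ModuleSet: overlapping k-clique communities
#'
#' The result of clique percolation at a given clique size k: each module is
#' the union of a chain of adjacent k-cliques (maximal cliques of size >= k
#' sharing >= k - 1 genes). Modules may overlap in genes; each constituent
#' clique belongs to exactly one module. All gene vectors are sorted and the
#' module list is ordered by decreasing size, ties broken by the
#' lexicographically smallest member, so output is deterministic.
#'
#' @slot modules list of sorted character vectors (gene ids per module).
#' @slot cliques list (one element per module) of lists of sorted character
#'   vectors: the maximal cliques of size >= k whose union forms the module.
#' @slot k integer clique size used for percolation.
#' @seealso [kCliqueCommunities()], [evaluateRecovery()]
#' @exportClass ModuleSet
setClass("ModuleSet",
    representation(modules = "list", cliques = "list", k = "integer"),
    validity = function(object) {
        msg <- character()
        if (length(object@k) != 1L || is.na(object@k) || object@k < 2L)
            msg <- c(msg, "'k' must be a single integer >= 2")
        if (length(object@modules) != length(object@cliques))
            msg <- c(msg, "'modules' and 'cliques' must have equal length")
        ok <- vapply(object@modules, is.character, logical(1))
        if (length(ok) && !all(ok))
            msg <- c(msg, "modules must be character vectors of gene ids")
        for (i in seq_along(object@modules)) {
            cl <- object@cliques[[i]]
            un <- sort(unique(unlist(cl)))
            if (!identical(un, object@modules[[i]]))
                msg <- c(msg, sprintf(
                    "module %d is not the union of its cliques", i))
        }
        if (length(msg)) msg else TRUE
    })

ModuleSet <- function(modules = list(), cliques = list(), k) {
    new("ModuleSet", modules = modules, cliques = cliques,
        k = as.integer(k))
}

#' PercolationStats: k-clique percolation summary quantities
#'
#' Diagnostics of the k-clique percolation transition on a binary graph:
#' the random-graph critical edge probability d(k) for the graph's size, the
#' vertex count N* and relative size phi = N*/N of the largest percolation
#' cluster, and the k-clique counts L (whole graph), L* (largest cluster)
#' with their ratio varphi = L*/L (0 when L = 0).
#'
#' @slot nGenes integer, number of vertices N.
#' @slot k integer clique size.
#' @slot dk numeric critical threshold d(k).
#' @slot nStar integer, vertices in the largest k-clique cluster.
#' @slot phi numeric in [0, 1], N*/N.
#' @slot lTotal numeric, exact number of k-cliques in the graph.
#' @slot lStar numeric, k-cliques in the largest cluster.
#' @slot varphi numeric in [0, 1], L*/L.
#' @seealso [orderParameters()], [criticalThreshold()]
#' @exportClass PercolationStats
setClass("PercolationStats",
    representation(nGenes = "integer", k = "integer", dk = "numeric",
                   nStar = "integer", phi = "numeric", lTotal = "numeric",
                   lStar = "numeric", varphi = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@phi < 0 || object@phi > 1)
            msg <- c(msg, "'phi' must lie in [0, 1]")
        if (object@varphi < 0 || object@varphi > 1)
            msg <- c(msg, "'varphi' must lie in [0, 1]")
        if (length(msg)) msg else TRUE
    })

#' PermutationResult: empirical significance of the module score
#'
#' Holds the observed global differential-coexpression score, the vector of
#' null scores from group-wise permuted data, and empirical p-values. The
#' plain estimator is #(null >= observed) / n; the add-one variant
#' (#(null >= observed) + 1) / (n + 1) is reported alongside.
#'
#' @slot observed numeric observed score.
#' @slot nullScores numeric vector of length nPermutations.
#' @slot pValue plain empirical p-value in [0, 1].
#' @slot pValueAddOne add-one p-value in (0, 1].
#' @slot nPermutations integer number of permutations.
#' @slot seed integer seed used.
#' @seealso [permutationTest()]
#' @exportClass PermutationResult
setClass("PermutationResult",
    representation(observed = "numeric", nullScores = "numeric",
                   pValue = "numeric", pValueAddOne = "numeric",
                   nPermutations = "integer", seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (length(object@nullScores) != object@nPermutations)
            msg <- c(msg, "'nullScores' length must equal 'nPermutations'")
        if (object@pValue < 0 || object@pValue > 1)
            msg <- c(msg, "'pValue' must lie in [0, 1]")
        if (object@pValueAddOne <= 0 || object@pValueAddOne > 1)
            msg <- c(msg, "'pValueAddOne' must lie in (0, 1]")
        if (length(msg)) msg else TRUE
    })
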