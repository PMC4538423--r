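#' @rdname accessors
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("geneIds", "CorrelationMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("geneIds", "BinaryAdjacency", function(x) rownames(x@values))
#' @rdname accessors
setMethod("geneIds", "ModuleSet",
    function(x) sort(unique(unlist(x@modules))))

#' @rdname accessors
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("conditionLabel", "ExpressionMatrix", function(x) x@condition)

#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)
#' @rdname accessors
setMethod("corValues", "CorrelationMatrix", function(x) x@values)
#' @rdname accessors
setMethod("adjValues", "BinaryAdjacency", function(x) x@values)

#' @rdname accessors
setMethod("modules", "ModuleSet", function(x) x@modules)
#' @rdname accessors
setMethod("moduleCliques", "ModuleSet", function(x) x@cliques)
#' @rdname accessors
setMethod("cliqueK", "ModuleSet", function(x) x@k)

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d genes x %d samples (condition: %s)\n",
                nrow(object@values), ncol(object@values), object@condition))
})

setMethod("show", "CorrelationMatrix", function(object) {
    v <- object@values
    off <- v[upper.tri(v)]
    cat(sprintf("CorrelationMatrix: %d genes", nrow(v)))
    if (length(off))
        cat(sprintf("; off-diagonal range [%.3f, %.3f]",
                    min(off), max(off)))
    cat("\n")
})

setMethod("show", "BinaryAdjacency", function(object) {
    v <- object@values
    cat(sprintf("BinaryAdjacency: %d genes, %d edges\n",
                nrow(v), sum(v) / 2))
})

setMethod("show", "ModuleSet", function(object) {
    cat(sprintf("ModuleSet: %d module(s) at k = %d\n",
                length(object@modules), object@k))
    for (i in seq_along(object@modules)) {
        m <- object@modules[[i]]
        cat(sprintf("  [%d] %d genes, %d clique(s): %s%s\n", i, length(m),
                    length(object@cliques[[i]]),
                    paste(utils::head(m, 6), collapse = ", "),
                    if (length(m) > 6) ", ..." else ""))
    }
})

setMethod("show", "PercolationStats", function(object) {
    cat(sprintf(paste0(
        "PercolationStats (k = %d): N = %d, d(k) = %.4g\n",
        "  largest cluster: N* = %d (phi = %.3f); ",
        "k-cliques: L = %g, L* = %g (varphi = %.3f)\n"),
        object@k, object@nGenes, object@dk, object@nStar, object@phi,
        object@lTotal, object@lStar, object@varphi))
})

setMethod("show", "PermutationResult", function(object) {
    cat(sprintf(paste0(
        "PermutationResult: observed score %.4g over %d permutations\n",
        "  p = %.4g (plain), %.4g (add-one); seed %d\n"),
        object@observed, object@nPermutations, object@pValue,
        object@pValueAddOne, object@seed))
})

#' @rdname accessors
#' @export
observedScore <- function(x) {
    stopifnot(is(x, "PermutationResult"))
    x@observed
}

#' @rdname accessors
#' @export
nullScores <- function(x) {
    stopifnot(is(x, "PermutationResult"))
    x@nullScores
}

#' Empirical p-values of a permutation test
#'
#' @param x a [PermutationResult-class].
#' @param addOne if `TRUE`, return the add-one estimator
#'   (#(null >= observed) + 1) / (n + 1) instead of the plain one.
#' @return a number in [0, 1].
#' @export
pValue <- function(x, addOne = FALSE) {
    stopifnot(is(x, "PermutationResult"))
    if (addOne) x@pValueAddOne else x@pValue
}
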