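#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: `geneIds` returns
#' the ordered gene identifiers, `sampleIds` the sample identifiers,
#' `conditionLabel` the condition tag of an expression matrix, and
#' `exprValues` / `corValues` / `adjValues` the underlying numeric matrices.
#'
#' @param x an object of one of the package's classes.
#' @return `geneIds`, `sampleIds`: character vectors; `conditionLabel`:
#'   single character; the `*Values` accessors: numeric matrices;
#'   `modules`, `moduleCliques`: lists; `cliqueK`: integer.
#' @name accessors
#' @aliases geneIds sampleIds conditionLabel exprValues corValues adjValues
#'   modules moduleCliques cliqueK
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))
#' @rdname accessors
#' @export
setGeneric("adjValues", function(x) standardGeneric("adjValues"))
#' @rdname accessors
#' @export
setGeneric("modules", function(x) standardGeneric("modules"))
#' @rdname accessors
#' @export
setGeneric("moduleCliques", function(x) standardGeneric("moduleCliques"))
#' @rdname accessors
#' @export
setGeneric("cliqueK", function(x) standardGeneric("cliqueK"))

#' Graph density of a binary adjacency
#'
#' Number of edges divided by the maximum possible number of edges,
#' n(n-1)/2 for an undirected simple graph on n vertices; a complete graph
#' (clique) has density exactly 1.
#'
#' @param x a [BinaryAdjacency-class] with at least 2 genes.
#' @return a number in [0, 1].
#' @examples
#' k4 <- completeGraph(4)
#' graphDensity(k4)  # 1
#' @export
setGeneric("graphDensity", function(x) standardGeneric("graphDensity"))
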