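#' Read an expression matrix from tab-separated text
#'
#' Expected dialect: one header row (first field a label for the gene-id
#' column, remaining fields sample ids), then one row per gene: gene id
#' followed by numeric values. Duplicate gene ids, non-numeric cells and
#' ragged rows are rejected with the offending line number.
#'
#' @param path file path.
#' @param condition condition label to attach.
#' @return an [ExpressionMatrix-class].
#' @seealso [writeExpression()] — `readExpression(writeExpression(x))`
#'   round-trips.
#' @export
readExpression <- function(path, condition = "unspecified") {
    lines <- readLines(path)
    if (length(lines) < 2L)
        stop("expression file needs a header row and at least one gene row")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != nf[1L]))
        stop("ragged row at line ", which(nf != nf[1L])[1L],
             " of '", path, "'")
    header <- fields[[1L]]
    ids <- vapply(fields[-1L], `[`, character(1), 1L)
    dup <- which(duplicated(ids))
    if (length(dup))
        stop("duplicate gene id '", ids[dup[1L]], "' at line ",
             dup[1L] + 1L, " of '", path, "'")
    vals <- matrix(NA_real_, length(ids), nf[1L] - 1L)
    for (i in seq_along(ids)) {
        row <- suppressWarnings(as.numeric(fields[[i + 1L]][-1L]))
        if (anyNA(row))
            stop("non-numeric cell at line ", i + 1L, " of '", path, "'")
        vals[i, ] <- row
    }
    dimnames(vals) <- list(ids, header[-1L])
    ExpressionMatrix(vals, condition)
}

#' Write an expression matrix as tab-separated text
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
    stopifnot(is(x, "ExpressionMatrix"))
    v <- exprValues(x)
    lines <- c(paste(c("gene", colnames(v)), collapse = "\t"),
               vapply(seq_len(nrow(v)), function(i)
                   paste(c(rownames(v)[i],
                           format(v[i, ], digits = 15, trim = TRUE,
                                  scientific = FALSE)),
                         collapse = "\t"), character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' Write a correlation matrix as square tab-separated text
#'
#' Header row and first column carry the gene ids.
#'
#' @param x a [CorrelationMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCorrelation <- function(x, path) {
    stopifnot(is(x, "CorrelationMatrix"))
    v <- corValues(x)
    utils::write.table(format(v, digits = 10, trim = TRUE), path,
                       sep = "\t", quote = FALSE, col.names = NA)
    invisible(path)
}

#' Write a binary graph as a two-column edge list
#'
#' One row per edge, the two gene ids lexicographically ordered within each
#' row and rows sorted lexicographically, so output is byte-identical
#' across runs. No header.
#'
#' @param a a [BinaryAdjacency-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(a, path) {
    stopifnot(is(a, "BinaryAdjacency"))
    v <- adjValues(a)
    idx <- which(v > 0 & upper.tri(v), arr.ind = TRUE)
    g1 <- rownames(v)[idx[, 1L]]
    g2 <- rownames(v)[idx[, 2L]]
    lo <- pmin(g1, g2)
    hi <- pmax(g1, g2)
    ord <- order(lo, hi, method = "radix")
    writeLines(paste(lo[ord], hi[ord], sep = "\t"), path)
    invisible(path)
}

#' Write a binary graph in GraphML format
#'
#' @param a a [BinaryAdjacency-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(a, path) {
    stopifnot(is(a, "BinaryAdjacency"))
    igraph::write_graph(.asIgraph(a), path, format = "graphml")
    invisible(path)
}

#' Write detected modules as a clique table
#'
#' Tab-separated table with one row per constituent clique: module number,
#' clique number (within the module), then the clique's gene symbols —
#' mirroring the clique-by-clique presentation of module tables in the
#' differential-coexpression literature. Rows are ragged when cliques
#' differ in size.
#'
#' @param mods a [ModuleSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeModules <- function(mods, path) {
    stopifnot(is(mods, "ModuleSet"))
    lines <- c("module\tclique\tgenes")
    cls <- moduleCliques(mods)
    for (m in seq_along(cls))
        for (ci in seq_along(cls[[m]]))
            lines <- c(lines, paste(c(m, ci, cls[[m]][[ci]]),
                                    collapse = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Write modules (and optional diagnostics) as JSON
#'
#' @param mods a [ModuleSet-class].
#' @param path output file path.
#' @param stats optional [PercolationStats-class] to embed.
#' @param config optional [pipelineConfig()] echo for provenance.
#' @return `path`, invisibly.
#' @export
writeModulesJSON <- function(mods, path, stats = NULL, config = NULL) {
    stopifnot(is(mods, "ModuleSet"))
    out <- list(k = cliqueK(mods), n_modules = length(modules(mods)),
                modules = modules(mods), cliques = moduleCliques(mods))
    if (!is.null(stats))
        out$percolation <- list(
            n_genes = stats@nGenes, k = stats@k, d_k = stats@dk,
            n_star = stats@nStar, phi = stats@phi, l_total = stats@lTotal,
            l_star = stats@lStar, varphi = stats@varphi)
    if (!is.null(config))
        out$config <- unclass(config)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Write a permutation-test result as JSON
#'
#' @param x a [PermutationResult-class].
#' @param path output file path.
#' @param config optional [pipelineConfig()] echo.
#' @param nullScorePath optional path for a single-column text dump of the
#'   null scores (for downstream plotting).
#' @return `path`, invisibly.
#' @export
writePermutationJSON <- function(x, path, config = NULL,
                                 nullScorePath = NULL) {
    stopifnot(is(x, "PermutationResult"))
    out <- list(observed_score = x@observed, p_value = x@pValue,
                p_value_add_one = x@pValueAddOne,
                n_permutations = x@nPermutations, seed = x@seed,
                null_scores = x@nullScores)
    if (!is.null(config))
        out$config <- unclass(config)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    if (!is.null(nullScorePath))
        writeLines(format(x@nullScores, digits = 15, trim = TRUE),
                   nullScorePath)
    invisible(path)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; absent keys take the
#' defaults. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a validated `"PipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    known <- names(formals(pipelineConfig))
    bad <- setdiff(names(cfg), known)
    if (length(bad))
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    do.call(pipelineConfig, cfg)
}

#' Write the planted-benchmark dataset to a directory
#'
#' Writes `control.tsv` and `disease.tsv` in the standard expression
#' dialect plus `truth.txt` (one planted gene id per line).
#'
#' @param bench result of [generateBenchmark()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBenchmark <- function(bench, dir) {
    stopifnot(is.list(bench),
              all(c("control", "disease", "truth") %in% names(bench)))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeExpression(bench$control, file.path(dir, "control.tsv"))
    writeExpression(bench$disease, file.path(dir, "disease.tsv"))
    writeLines(bench$truth, file.path(dir, "truth.txt"))
    invisible(dir)
}
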