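#' Pipeline configuration
#'
#' Bundles every tunable of the detection pipeline into a validated list.
#' Defaults follow the method's real-data protocol: absolute-difference
#' binarization at `t3 = 1.3`, minimum clique size `k = 4`, isolated-gene
#' removal followed by discarding the lower half of genes by degree.
#' For gain/loss modes, `t1`/`t2` bound the normal/disease correlations
#' (on absolute values by default).
#'
#' @param mode binarization rule: `"gain"`, `"loss"` or `"absdiff"` (see
#'   [binarizeNetwork()]).
#' @param t1,t2 gain/loss thresholds in [0, 1].
#' @param t3 absolute-difference threshold in [0, 2].
#' @param useAbsolute compare absolute correlations in gain/loss modes.
#' @param k clique size for percolation (>= 2).
#' @param filterFraction fraction of lowest-degree genes discarded after
#'   isolated-gene removal, in [0, 1).
#' @param maxPOutliers,fallback correlation options, see [bicor()].
#' @param nPermutations permutations for [permutationTest()] when the
#'   pipeline runs it.
#' @param seed integer seed.
#' @return a named list of class `"PipelineConfig"`.
#' @examples
#' pipelineConfig(mode = "gain", t1 = 0.8, t2 = 0.4, filterFraction = 0)
#' @export
pipelineConfig <- function(mode = c("absdiff", "gain", "loss"),
                           t1 = 0.8, t2 = 0.4, t3 = 1.3,
                           useAbsolute = TRUE, k = 4,
                           filterFraction = 0.5, maxPOutliers = 1,
                           fallback = c("zero", "pearson", "error"),
                           nPermutations = 1000, seed = 1) {
    cfg <- list(mode = match.arg(mode), t1 = t1, t2 = t2, t3 = t3,
                useAbsolute = isTRUE(useAbsolute), k = as.integer(k),
                filterFraction = filterFraction,
                maxPOutliers = maxPOutliers,
                fallback = match.arg(fallback),
                nPermutations = as.integer(nPermutations),
                seed = as.integer(seed))
    class(cfg) <- "PipelineConfig"
    .validateConfig(cfg)
}

.validateConfig <- function(cfg) {
    if (!inherits(cfg, "PipelineConfig")) {
        stopifnot(is.list(cfg))
        cfg <- do.call(pipelineConfig, cfg)
    }
    stopifnot(cfg$mode %in% c("gain", "loss", "absdiff"),
              cfg$t1 >= 0, cfg$t1 <= 1, cfg$t2 >= 0, cfg$t2 <= 1,
              cfg$t3 >= 0, cfg$t3 <= 2, cfg$k >= 2,
              cfg$filterFraction >= 0, cfg$filterFraction < 1,
              cfg$maxPOutliers > 0, cfg$maxPOutliers <= 1,
              cfg$nPermutations >= 1)
    cfg
}

# Correlation -> binarization -> isolated removal -> degree pruning ->
# k-clique percolation. Returns all intermediates.
.detectModules <- function(xNormal, xDisease, mode, t1, t2, t3,
                           useAbsolute = TRUE, k = 4, filterFraction = 0.5,
                           maxPOutliers = 1, fallback = "zero") {
    cNormal <- bicorMatrix(xNormal, maxPOutliers = maxPOutliers,
                           fallback = fallback)
    cDisease <- bicorMatrix(xDisease, maxPOutliers = maxPOutliers,
                            fallback = fallback)
    net <- binarizeNetwork(cNormal, cDisease, mode = mode,
                           t1 = t1, t2 = t2, t3 = t3,
                           useAbsolute = useAbsolute)
    net <- removeIsolated(net)
    if (filterFraction > 0 && nrow(adjValues(net)) > 0L)
        net <- filterLowDegree(net, filterFraction)
    mods <- if (nrow(adjValues(net)) == 0L)
        ModuleSet(k = k)
    else
        kCliqueCommunities(net, k = k)
    list(cNormal = cNormal, cDisease = cDisease, network = net,
         modules = mods)
}

#' Run the full differential-coexpression pipeline
#'
#' End-to-end composition: biweight midcorrelation matrices for both
#' conditions, threshold binarization into one differential graph,
#' isolated-gene removal, optional low-degree pruning, k-clique community
#' detection, percolation diagnostics, and (optionally) the permutation
#' significance test. All stages are deterministic given the config seed.
#'
#' An empty graph after filtering is not an error: the result carries an
#' empty [ModuleSet-class] and a warning is issued.
#'
#' @param xNormal,xDisease [ExpressionMatrix-class] objects over the same
#'   genes (>= 2 samples each).
#' @param config a [pipelineConfig()] list.
#' @param permute run [permutationTest()] (can be slow; the permutation
#'   count comes from the config).
#' @param outputDir if non-`NULL`, a directory into which all artifacts are
#'   written: correlation matrices, edge list, modules (TSV and JSON with
#'   the config echo), and the permutation result.
#' @return a list with elements `cNormal`, `cDisease`
#'   ([CorrelationMatrix-class]), `network` ([BinaryAdjacency-class], after
#'   filtering), `modules` ([ModuleSet-class]), `stats`
#'   ([PercolationStats-class] or `NULL` for an empty graph),
#'   `permutation` ([PermutationResult-class] or `NULL`), and `config`.
#' @examples
#' b <- generateBenchmark(sigma = 0.1, seed = 42)
#' cfg <- pipelineConfig(mode = "gain", t1 = 0.8, t2 = 0.4,
#'                       filterFraction = 0, k = 4)
#' res <- runPipeline(b$control, b$disease, cfg)
#' res$modules
#' @export
runPipeline <- function(xNormal, xDisease, config = pipelineConfig(),
                        permute = FALSE, outputDir = NULL) {
    config <- .validateConfig(config)
    det <- .detectModules(xNormal, xDisease, mode = config$mode,
                          t1 = config$t1, t2 = config$t2, t3 = config$t3,
                          useAbsolute = config$useAbsolute, k = config$k,
                          filterFraction = config$filterFraction,
                          maxPOutliers = config$maxPOutliers,
                          fallback = config$fallback)
    if (nrow(adjValues(det$network)) == 0L)
        warning("no genes survive binarization/filtering; ",
                "returning an empty ModuleSet")
    stats <- if (nrow(adjValues(det$network)) > 0L)
        orderParameters(det$network, k = config$k)
    else NULL
    perm <- if (permute)
        permutationTest(xNormal, xDisease, config = config,
                        nPermutations = config$nPermutations,
                        seed = config$seed)
    else NULL
    res <- list(cNormal = det$cNormal, cDisease = det$cDisease,
                network = det$network, modules = det$modules,
                stats = stats, permutation = perm, config = config)
    if (!is.null(outputDir))
        .writePipelineArtifacts(res, outputDir)
    res
}

.writePipelineArtifacts <- function(res, outputDir) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    writeCorrelation(res$cNormal, file.path(outputDir, "bicor_normal.tsv"))
    writeCorrelation(res$cDisease, file.path(outputDir, "bicor_disease.tsv"))
    writeEdgeList(res$network, file.path(outputDir, "edges.tsv"))
    writeModules(res$modules, file.path(outputDir, "modules.tsv"))
    writeModulesJSON(res$modules, file.path(outputDir, "modules.json"),
                     stats = res$stats, config = res$config)
    if (!is.null(res$permutation))
        writePermutationJSON(res$permutation,
                             file.path(outputDir, "permutation.json"),
                             config = res$config)
    invisible(NULL)
}
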