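#' Global differential-coexpression score of a module set
#'
#' Sums, over all modules and over all unordered gene pairs within each
#' module, the absolute change in correlation between the two conditions,
#' |c_N(i,j) - c_D(i,j)|. Genes shared by overlapping modules contribute to
#' each module containing them. An empty module set scores 0. The score is
#' a magnitude of differential coexpression: large values mean the detected
#' modules concentrate strong correlation changes.
#'
#' @param cNormal,cDisease [CorrelationMatrix-class] objects over the same
#'   genes (which must include every module gene).
#' @param mods a [ModuleSet-class].
#' @return a single non-negative number.
#' @export
moduleScore <- function(cNormal, cDisease, mods) {
    .checkSameGenes(cNormal, cDisease)
    stopifnot(is(mods, "ModuleSet"))
    cn <- corValues(cNormal)
    cd <- corValues(cDisease)
    unknown <- setdiff(unlist(modules(mods)), rownames(cn))
    if (length(unknown))
        stop("module gene(s) absent from the correlation matrices: ",
             paste(unknown, collapse = ", "))
    total <- 0
    for (m in modules(mods)) {
        if (length(m) < 2L)
            next
        d <- abs(cn[m, m, drop = FALSE] - cd[m, m, drop = FALSE])
        total <- total + sum(d[upper.tri(d)])
    }
    total
}

#' Group-wise permutation of expression data
#'
#' Samples from the no-coexpression null: within each condition, each
#' gene's values are shuffled across samples independently of every other
#' gene, destroying all between-gene covariance while preserving each
#' gene's marginal value multiset. Deterministic given `seed`.
#'
#' @param xNormal,xDisease [ExpressionMatrix-class] objects over the same
#'   genes.
#' @param seed integer seed.
#' @return a list with permuted `normal` and `disease`
#'   [ExpressionMatrix-class] objects.
#' @export
permuteExpression <- function(xNormal, xDisease, seed = 1) {
    stopifnot(is(xNormal, "ExpressionMatrix"),
              is(xDisease, "ExpressionMatrix"))
    if (!identical(geneIds(xNormal), geneIds(xDisease)))
        stop("the two expression matrices must cover the same genes ",
             "in the same order")
    set.seed(as.integer(seed))
    shuffle <- function(x) {
        v <- exprValues(x)
        for (i in seq_len(nrow(v)))
            v[i, ] <- v[i, sample.int(ncol(v))]
        ExpressionMatrix(v, conditionLabel(x))
    }
    list(normal = shuffle(xNormal), disease = shuffle(xDisease))
}

# Upper-tail empirical p-value: the alternative is a large differential
# change, so the exceedance set is {null >= observed}.
.empiricalP <- function(null, observed) {
    exceed <- sum(null >= observed)
    list(plain = exceed / length(null),
         addOne = (exceed + 1) / (length(null) + 1))
}

#' Permutation test of module significance
#'
#' Assesses whether the detected modules' global differential-coexpression
#' score could arise from independent genes. The observed score comes from
#' running the full pipeline (correlation, binarization, filtering, module
#' detection, scoring) on the real data. Each null score reruns that entire
#' pipeline on a group-wise permuted dataset (see [permuteExpression()]),
#' scoring whatever modules that run detects (0 when none) — the null thus
#' accounts for module selection, not just rescoring fixed modules. The
#' plain empirical p-value is #(null >= observed) / n; the add-one variant
#' (#(null >= observed) + 1) / (n + 1) is reported alongside and is never
#' exactly 0.
#'
#' When the observed pipeline finds no modules the test is uninformative:
#' the p-value is reported as 1 with a warning.
#'
#' @param xNormal,xDisease [ExpressionMatrix-class] objects over the same
#'   genes.
#' @param config a [pipelineConfig()] list (thresholds, k, filtering,
#'   correlation options).
#' @param nPermutations number of permuted datasets (>= 1; 1000 for a
#'   0.001-resolution p-value).
#' @param seed integer master seed; per-permutation seeds are derived from
#'   it, so the whole result is reproducible bit-for-bit.
#' @return a [PermutationResult-class].
#' @export
permutationTest <- function(xNormal, xDisease, config = pipelineConfig(),
                            nPermutations = 1000, seed = 1) {
    stopifnot(nPermutations >= 1)
    config <- .validateConfig(config)
    det <- .detectModules(xNormal, xDisease, mode = config$mode,
                          t1 = config$t1, t2 = config$t2, t3 = config$t3,
                          useAbsolute = config$useAbsolute, k = config$k,
                          filterFraction = config$filterFraction,
                          maxPOutliers = config$maxPOutliers,
                          fallback = config$fallback)
    observed <- moduleScore(det$cNormal, det$cDisease, det$modules)
    noObserved <- length(modules(det$modules)) == 0L
    null <- numeric(nPermutations)
    for (b in seq_len(nPermutations)) {
        perm <- permuteExpression(xNormal, xDisease,
                                  seed = .deriveSeed(seed, b))
        pd <- .detectModules(perm$normal, perm$disease, mode = config$mode,
                             t1 = config$t1, t2 = config$t2, t3 = config$t3,
                             useAbsolute = config$useAbsolute, k = config$k,
                             filterFraction = config$filterFraction,
                             maxPOutliers = config$maxPOutliers,
                             fallback = config$fallback)
        null[b] <- moduleScore(pd$cNormal, pd$cDisease, pd$modules)
    }
    p <- .empiricalP(null, observed)
    pPlain <- p$plain
    pAdd <- p$addOne
    if (noObserved) {
        warning("the observed pipeline detected no modules; ",
                "p-value reported as 1")
        pPlain <- 1
        pAdd <- 1
    }
    new("PermutationResult", observed = observed, nullScores = null,
        pValue = pPlain, pValueAddOne = pAdd,
        nPermutations = as.integer(nPermutations),
        seed = as.integer(seed))
}
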