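mkCorPair <- function(delta, ids = c("a", "b", "c")) {
    n <- length(ids)
    cn <- matrix(0.9, n, n, dimnames = list(ids, ids))
    diag(cn) <- 1
    cd <- cn - delta
    diag(cd) <- 1
    list(normal = CorrelationMatrix(cn), disease = CorrelationMatrix(cd))
}

test_that("module score sums |delta correlation| over within-module pairs", {
    # all pairwise changes 1.5: one 3-gene module -> 3 pairs * 1.5 = 4.5
    cp <- mkCorPair(1.5)
    ms <- ModuleSet(modules = list(c("a", "b", "c")),
                    cliques = list(list(c("a", "b", "c"))), k = 3)
    expect_equal(moduleScore(cp$normal, cp$disease, ms), 4.5)

    empty <- ModuleSet(k = 4)
    expect_equal(moduleScore(cp$normal, cp$disease, empty), 0)

    # invariant to gene order inside the module definition
    ms2 <- ModuleSet(modules = list(c("a", "b", "c")),
                     cliques = list(list(c("c", "a", "b"))), k = 3)
    expect_equal(moduleScore(cp$normal, cp$disease, ms2), 4.5)

    bad <- ModuleSet(modules = list(c("a", "zz")),
                     cliques = list(list(c("a", "zz"))), k = 2)
    expect_error(moduleScore(cp$normal, cp$disease, bad), "absent")
})

test_that("overlapping modules each contribute their own pairs", {
    cp <- mkCorPair(0.5, ids = c("a", "b", "c", "d"))
    ms <- ModuleSet(modules = list(c("a", "b", "c"), c("b", "c", "d")),
                    cliques = list(list(c("a", "b", "c")),
                                   list(c("b", "c", "d"))), k = 3)
    # pair (b, c) counted in both modules: 6 pairs * 0.5 = 3
    expect_equal(moduleScore(cp$normal, cp$disease, ms), 3)
})

test_that("group-wise permutation preserves per-gene value multisets", {
    set.seed(61)
    mk <- function(cond) ExpressionMatrix(
        matrix(rnorm(5 * 8), 5, 8, dimnames = list(paste0("g", 1:5), NULL)),
        cond)
    xn <- mk("normal")
    xd <- mk("disease")
    p <- permuteExpression(xn, xd, seed = 9)
    for (g in geneIds(xn)) {
        expect_equal(sort(unname(exprValues(p$normal)[g, ])),
                     sort(unname(exprValues(xn)[g, ])))
        expect_equal(sort(unname(exprValues(p$disease)[g, ])),
                     sort(unname(exprValues(xd)[g, ])))
    }
    # the permutation actually moves things and is seed-deterministic
    expect_false(identical(exprValues(p$normal), exprValues(xn)))
    p2 <- permuteExpression(xn, xd, seed = 9)
    expect_identical(exprValues(p$normal), exprValues(p2$normal))
    expect_identical(exprValues(p$disease), exprValues(p2$disease))
    p3 <- permuteExpression(xn, xd, seed = 10)
    expect_false(identical(exprValues(p$normal), exprValues(p3$normal)))
})

test_that("empirical p-value estimators count exceedances", {
    p <- bmkc:::.empiricalP(c(5, 1, 1, 1), 2)
    expect_equal(p$plain, 1 / 4)
    expect_equal(p$addOne, 2 / 5)
    expect_equal(bmkc:::.empiricalP(c(1, 1, 1), 2)$plain, 0)
    expect_equal(bmkc:::.empiricalP(c(2, 2), 2)$plain, 1)  # ties exceed
})

test_that("permutation test on a planted signal is significant and reproducible", {
    b <- generateBenchmark(nSignal = 10, nNoise = 20, nSamples = 20,
                           sigma = 0.1, seed = 13)
    cfg <- pipelineConfig(mode = "gain", t1 = 0.8, t2 = 0.4,
                          filterFraction = 0, k = 4)
    pr <- permutationTest(b$control, b$disease, cfg,
                          nPermutations = 25, seed = 3)
    expect_gt(observedScore(pr), max(nullScores(pr)))
    expect_equal(pValue(pr), 0)
    expect_equal(pValue(pr, addOne = TRUE), 1 / 26)
    expect_length(nullScores(pr), 25)

    pr2 <- permutationTest(b$control, b$disease, cfg,
                           nPermutations = 25, seed = 3)
    expect_identical(nullScores(pr), nullScores(pr2))
    expect_identical(observedScore(pr), observedScore(pr2))
})

test_that("no observed modules yields p = 1 with a warning", {
    set.seed(77)
    mk <- function(cond) ExpressionMatrix(
        matrix(rnorm(15 * 10), 15, 10,
               dimnames = list(sprintf("g%02d", 1:15), NULL)), cond)
    cfg <- pipelineConfig(mode = "gain", t1 = 0.999, t2 = 0.001,
                          filterFraction = 0, k = 4)
    expect_warning(
        pr <- permutationTest(mk("n"), mk("d"), cfg, nPermutations = 5,
                              seed = 1),
        "no modules")
    expect_equal(pValue(pr), 1)
})
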