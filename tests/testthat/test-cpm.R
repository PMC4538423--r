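# two triangles sharing the edge b-c
twoTrianglesEdge <- function() {
    m <- matrix(0, 4, 4)
    m[1, 2] <- m[1, 3] <- m[2, 3] <- m[2, 4] <- m[3, 4] <- 1
    mkAdj(m, letters[1:4])
}

test_that("maximal cliques are enumerated once each, deterministically", {
    cl <- maximalCliques(twoTrianglesEdge())
    expect_equal(cl, list(c("a", "b", "c"), c("b", "c", "d")))
    expect_equal(maximalCliques(completeGraph(5)),
                 list(sprintf("g%03d", 1:5)))
    edgeless <- mkAdj(matrix(0, 3, 3))
    expect_equal(maximalCliques(edgeless),
                 list("g01", "g02", "g03"))
    expect_equal(maximalCliques(edgeless, minSize = 2), list())
})

test_that("k-clique communities merge via k-1 overlap only", {
    # shared edge (overlap 2 = k - 1): one community of all 4 genes
    ms <- kCliqueCommunities(twoTrianglesEdge(), k = 3)
    expect_equal(modules(ms), list(letters[1:4]))
    expect_equal(length(moduleCliques(ms)[[1]]), 2)

    # shared vertex only (overlap 1 < k - 1): two separate triangles
    m <- matrix(0, 5, 5)
    m[1, 2] <- m[1, 3] <- m[2, 3] <- 1
    m[3, 4] <- m[3, 5] <- m[4, 5] <- 1
    ms2 <- kCliqueCommunities(mkAdj(m, letters[1:5]), k = 3)
    expect_equal(modules(ms2), list(c("a", "b", "c"), c("c", "d", "e")))

    # no clique of size k at all
    expect_equal(modules(kCliqueCommunities(completeGraph(4), k = 5)),
                 list())
    expect_error(kCliqueCommunities(completeGraph(4), k = 1), ">= 2")
})

test_that("communities match the brute-force k-subset oracle", {
    set.seed(42)
    for (rep in 1:40) {
        n <- sample(4:8, 1)
        a <- randomAdj(n, runif(1, 0.3, 0.8))
        for (k in 3:4)
            expect_equal(moduleList(kCliqueCommunities(a, k)),
                         oracleKCliqueCommunities(a, k))
    }
})

test_that("communities at k + 1 nest inside communities at k", {
    set.seed(19)
    for (rep in 1:15) {
        a <- randomAdj(10, 0.55)
        mk <- modules(kCliqueCommunities(a, 3))
        mk1 <- modules(kCliqueCommunities(a, 4))
        for (m1 in mk1)
            expect_true(any(vapply(mk, function(m0) all(m1 %in% m0),
                                   logical(1))))
    }
})

test_that("deleting edges never grows the covered vertex set", {
    set.seed(27)
    for (rep in 1:15) {
        a <- randomAdj(9, 0.6)
        v <- adjValues(a)
        idx <- which(v > 0 & upper.tri(v), arr.ind = TRUE)
        if (nrow(idx) == 0) next
        drop <- idx[sample(nrow(idx), 1), ]
        v2 <- v
        v2[drop[1], drop[2]] <- v2[drop[2], drop[1]] <- 0
        before <- unique(unlist(modules(kCliqueCommunities(a, 3))))
        after <- unique(unlist(modules(kCliqueCommunities(
            BinaryAdjacency(v2), 3))))
        expect_true(all(after %in% before))
    }
})

test_that("every module is dense and its cliques are complete", {
    set.seed(8)
    for (rep in 1:10) {
        a <- randomAdj(10, 0.6)
        ms <- kCliqueCommunities(a, 3)
        v <- adjValues(a)
        for (i in seq_along(modules(ms))) {
            for (cl in moduleCliques(ms)[[i]]) {
                sub <- v[cl, cl]
                expect_true(all(sub[upper.tri(sub)] == 1))
            }
        }
    }
})

test_that("critical threshold follows the closed form", {
    expect_equal(criticalThreshold(100, 3), 1 / (2 * sqrt(100)))
    for (N in c(1, 7, 100, 4765))
        expect_equal(criticalThreshold(N, 2), 1 / N)
    for (k in 2:6)
        expect_equal(criticalThreshold(1, k), 1 / (k - 1))
    expect_error(criticalThreshold(10, 1), ">= 2")
})

test_that("order parameters measure the largest percolation cluster", {
    ps <- orderParameters(completeGraph(5), k = 3)
    expect_equal(ps@phi, 1)
    expect_equal(ps@varphi, 1)
    expect_equal(ps@lTotal, choose(5, 3))

    # two disjoint triangles + 4 isolated vertices: N* = 3 of N = 10
    m <- matrix(0, 10, 10)
    m[1, 2] <- m[1, 3] <- m[2, 3] <- 1
    m[4, 5] <- m[4, 6] <- m[5, 6] <- 1
    ps2 <- orderParameters(mkAdj(m), k = 3)
    expect_equal(ps2@nStar, 3L)
    expect_equal(ps2@phi, 0.3)
    expect_equal(ps2@lTotal, 2)
    expect_equal(ps2@varphi, 0.5)

    # no k-clique: all order parameters zero
    ps3 <- orderParameters(mkAdj(matrix(0, 4, 4)), k = 3)
    expect_equal(ps3@phi, 0)
    expect_equal(ps3@varphi, 0)
})

test_that("analytic k-clique count estimate is exact at k = 2", {
    for (d in c(0, 0.3, 1))
        expect_equal(estimateTotalKCliques(50, 2, d), choose(50, 2) * d)
    expect_equal(estimateTotalKCliques(20, 4, 0.5),
                 choose(20, 4) * 0.5^6)
})
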