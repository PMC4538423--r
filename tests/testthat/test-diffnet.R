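mkCor <- function(m, ids = sprintf("g%02d", seq_len(nrow(m)))) {
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    dimnames(m) <- list(ids, ids)
    CorrelationMatrix(m)
}

test_that("gain rule keeps pairs coexpressed in normal and lost in disease", {
    cn <- mkCor(rbind(c(1, 0.9, 0.9), c(0, 1, 0.9), c(0, 0, 1)))
    cd <- mkCor(rbind(c(1, 0.1, 0.5), c(0, 1, 0.1), c(0, 0, 1)))
    a <- adjValues(binarizeNetwork(cn, cd, "gain", t1 = 0.8, t2 = 0.2))
    expect_equal(a[1, 2], 1)   # 0.9 >= 0.8 and 0.1 <= 0.2
    expect_equal(a[1, 3], 0)   # disease 0.5 > 0.2 fails
    expect_equal(a[2, 3], 1)
    expect_equal(unname(diag(a)), rep(0, 3))
})

test_that("loss rule is the mirrored inequality", {
    cn <- mkCor(rbind(c(1, 0.1, 0.5), c(0, 1, 0.1), c(0, 0, 1)))
    cd <- mkCor(rbind(c(1, 0.9, 0.9), c(0, 1, 0.5), c(0, 0, 1)))
    a <- adjValues(binarizeNetwork(cn, cd, "loss", t1 = 0.2, t2 = 0.8))
    expect_equal(a[1, 2], 1)   # 0.1 <= 0.2 and 0.9 >= 0.8
    expect_equal(a[1, 3], 0)   # normal 0.5 > 0.2 fails
    expect_equal(a[2, 3], 0)   # disease 0.5 < 0.8 fails
})

test_that("absdiff rule captures reversals on signed correlations", {
    cn <- mkCor(rbind(c(1, 0.9, 0.9), c(0, 1, -0.2), c(0, 0, 1)))
    cd <- mkCor(rbind(c(1, -0.7, 0.1), c(0, 1, 0.9), c(0, 0, 1)))
    a <- adjValues(binarizeNetwork(cn, cd, "absdiff", t3 = 1.3))
    expect_equal(a[1, 2], 1)   # |0.9 - (-0.7)| = 1.6 and |0.9| >= |-0.7|
    expect_equal(a[1, 3], 0)   # difference 0.8 < 1.3
    expect_equal(a[2, 3], 0)   # |Δ| = 1.1 < 1.3 and |-0.2| < |0.9|
})

test_that("binarization matches a literal per-pair oracle on random input", {
    set.seed(91)
    for (rep in 1:10) {
        n <- 6
        r1 <- matrix(runif(n * n, -1, 1), n)
        r2 <- matrix(runif(n * n, -1, 1), n)
        cn <- mkCor(r1)
        cd <- mkCor(r2)
        v1 <- corValues(cn)
        v2 <- corValues(cd)
        t1 <- runif(1); t2 <- runif(1); t3 <- runif(1, 0, 2)
        gain <- adjValues(binarizeNetwork(cn, cd, "gain", t1, t2))
        absd <- adjValues(binarizeNetwork(cn, cd, "absdiff", t3 = t3))
        for (i in seq_len(n - 1)) {
            for (j in seq(i + 1, n)) {
                expect_equal(gain[i, j],
                    as.numeric(abs(v1[i, j]) >= t1 && abs(v2[i, j]) <= t2))
                expect_equal(absd[i, j],
                    as.numeric(abs(v1[i, j] - v2[i, j]) >= t3 &&
                               abs(v1[i, j]) >= abs(v2[i, j])))
            }
        }
    }
})

test_that("edge sets shrink monotonically in the thresholds", {
    set.seed(14)
    for (rep in 1:10) {
        cn <- mkCor(matrix(runif(64, -1, 1), 8))
        cd <- mkCor(matrix(runif(64, -1, 1), 8))
        e <- function(a) sum(adjValues(a)) / 2
        t1 <- runif(1, 0, 0.8); t2 <- runif(1, 0.2, 1)
        base <- binarizeNetwork(cn, cd, "gain", t1, t2)
        up1 <- binarizeNetwork(cn, cd, "gain", t1 + 0.15, t2)
        dn2 <- binarizeNetwork(cn, cd, "gain", t1, t2 - 0.15)
        expect_lte(e(up1), e(base))
        expect_lte(e(dn2), e(base))
        t3 <- runif(1, 0, 1.5)
        expect_lte(e(binarizeNetwork(cn, cd, "absdiff", t3 = t3 + 0.3)),
                   e(binarizeNetwork(cn, cd, "absdiff", t3 = t3)))
    }
})

test_that("gene-set mismatch is rejected", {
    cn <- mkCor(matrix(0.5, 3, 3))
    cd <- mkCor(matrix(0.5, 3, 3), ids = c("x", "y", "z"))
    expect_error(binarizeNetwork(cn, cd, "gain"), "same genes")
})

test_that("removeIsolated drops zero-degree genes and is idempotent", {
    m <- matrix(0, 5, 5)
    m[1, 2] <- m[2, 3] <- m[3, 4] <- 1   # g05 isolated
    a <- mkAdj(m)
    r <- removeIsolated(a)
    expect_equal(geneIds(r), sprintf("g%02d", 1:4))
    expect_equal(adjValues(removeIsolated(r)), adjValues(r))
    empty <- removeIsolated(mkAdj(matrix(0, 3, 3)))
    expect_equal(nrow(adjValues(empty)), 0)
})

test_that("low-degree filtering drops the lowest block with stable ties", {
    # star K_{1,4}: hub g01 degree 4, leaves degree 1
    m <- matrix(0, 5, 5)
    m[1, 2:5] <- 1
    star <- mkAdj(m)
    f <- filterLowDegree(star, 0.5)   # floor(0.5 * 5) = 2 leaves dropped
    expect_equal(length(geneIds(f)), 3)
    expect_true("g01" %in% geneIds(f))
    expect_equal(geneIds(f), c("g01", "g04", "g05"))  # ties by gene id

    # 2-regular cycle: removal determined purely by the id tie-break
    cyc <- mkAdj(rbind(c(0, 1, 0, 1), c(0, 0, 1, 0),
                       c(0, 0, 0, 1), c(0, 0, 0, 0)))
    expect_equal(geneIds(filterLowDegree(cyc, 0.5)), c("g03", "g04"))
    expect_equal(adjValues(filterLowDegree(star, 0)), adjValues(star))
})

test_that("filters never add edges", {
    set.seed(5)
    for (rep in 1:10) {
        a <- randomAdj(10, 0.3)
        pairs <- function(x) {
            v <- adjValues(x)
            if (nrow(v) == 0) return(character(0))
            idx <- which(v > 0 & upper.tri(v), arr.ind = TRUE)
            paste(rownames(v)[idx[, 1]], rownames(v)[idx[, 2]])
        }
        expect_true(all(pairs(removeIsolated(a)) %in% pairs(a)))
        expect_true(all(pairs(filterLowDegree(a, 0.4)) %in% pairs(a)))
    }
})

test_that("graph density matches edges over possible edges", {
    expect_equal(graphDensity(completeGraph(4)), 1)
    expect_equal(graphDensity(mkAdj(matrix(0, 4, 4))), 0)
    path3 <- mkAdj(rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)))
    expect_equal(graphDensity(path3), 2 / 3)
    expect_error(graphDensity(completeGraph(1)), "at least 2")
})
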