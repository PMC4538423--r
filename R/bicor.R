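#' Unscaled median absolute deviation
#'
#' The plain median of absolute deviations from the median,
#' `median(|v - median(v)|)`, with no consistency factor. This is the scale
#' used throughout the biweight midcorrelation: weights vanish at deviations
#' of 9 times this quantity. A constant vector has `madUnscaled` 0 and is
#' treated as degenerate by [bicor()].
#'
#' @param v non-empty numeric vector.
#' @return a single non-negative number.
#' @examples
#' madUnscaled(c(1, 2, 3))       # 1
#' madUnscaled(c(5, 5, 5))       # 0
#' @export
madUnscaled <- function(v) {
    if (length(v) == 0L)
        stop("'v' must be non-empty")
    stats::mad(v, constant = 1)
}

# Side-wise u rescaling for maxPOutliers < 1: if more than the allowed
# proportion of points on one side of the median have |u| >= 1, shrink that
# side's u so its (1 - maxPOutliers) quantile of |u| sits at 1.
.capOutliers <- function(u, maxPOutliers) {
    if (maxPOutliers >= 1)
        return(u)
    for (side in c(-1, 1)) {
        idx <- which(sign(u) == side)
        if (!length(idx))
            next
        au <- abs(u[idx])
        if (mean(au >= 1) > maxPOutliers) {
            q <- stats::quantile(au, probs = 1 - maxPOutliers,
                                 names = FALSE, type = 7)
            if (q > 1)
                u[idx] <- u[idx] / q
        }
    }
    u
}

#' Tukey biweight weights for the biweight midcorrelation
#'
#' Given a vector v, computes u_i = (v_i - median(v)) / (9 * mad(v)) with the
#' unscaled MAD and weights w_i = (1 - u_i^2)^2 if |u_i| < 1 and 0 otherwise.
#' A point at the median has weight exactly 1; points at least 9 MADs from
#' the median have weight 0 and are the implicit outliers. With
#' `maxPOutliers < 1` the u values on each side of the median are rescaled
#' so that at most that proportion of points per side receive zero weight.
#'
#' @param v numeric vector with positive [madUnscaled()]; otherwise the
#'   fallback policy applies.
#' @param maxPOutliers maximum allowed proportion of zero-weight points on
#'   each side of the median, in (0, 1]. Default 1 (no capping).
#' @param fallback what to do when `madUnscaled(v)` is 0: `"zero"` returns
#'   all-zero weights (the gene is degenerate and correlates 0 with
#'   everything), `"pearson"` returns unit weights, `"error"` stops.
#' @return numeric vector of weights in [0, 1], same length as `v`.
#' @examples
#' v <- c(1:9, 100)
#' bicorWeights(v)
#' @export
bicorWeights <- function(v, maxPOutliers = 1,
                         fallback = c("zero", "pearson", "error")) {
    fallback <- match.arg(fallback)
    if (length(v) == 0L)
        stop("'v' must be non-empty")
    stopifnot(maxPOutliers > 0, maxPOutliers <= 1)
    s <- madUnscaled(v)
    if (s == 0) {
        return(switch(fallback,
            zero = rep(0, length(v)),
            pearson = rep(1, length(v)),
            error = stop("madUnscaled(v) is 0 and fallback is 'error'")))
    }
    u <- .capOutliers((v - stats::median(v)) / (9 * s), maxPOutliers)
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
    w
}

# Prepare one vector for the bicor cross-product: returns the
# median-centered, weight-multiplied values and a degeneracy flag.
# Under the "pearson" fallback a degenerate vector is mean-centered with
# unit weights (plain Pearson on that side).
.bicorPrep <- function(v, maxPOutliers, fallback) {
    s <- madUnscaled(v)
    if (s == 0) {
        if (fallback == "error")
            stop("zero median absolute deviation and fallback is 'error'")
        if (fallback == "pearson") {
            y <- v - mean(v)
            return(list(y = y, degenerate = all(y == 0)))
        }
        return(list(y = rep(0, length(v)), degenerate = TRUE))
    }
    w <- bicorWeights(v, maxPOutliers = maxPOutliers, fallback = fallback)
    list(y = (v - stats::median(v)) * w, degenerate = FALSE)
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation: each vector is median-centered and down-weighted by
#' Tukey biweight weights on the 9-MAD scale (see [bicorWeights()]), then
#' correlated by the weighted cross-product normalized by the product of the
#' weighted norms. Values lie in [-1, 1]: `bicor(x, x)` is 1 and
#' `bicor(x, -x)` is -1 for any vector with positive MAD. Unlike Pearson
#' correlation, a single gross outlier has almost no influence.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @inheritParams bicorWeights
#' @return a single correlation value in [-1, 1]; 0 (with a warning) for a
#'   degenerate vector under the `"zero"` fallback.
#' @examples
#' x <- 1:10
#' bicor(x, x)           # 1
#' bicor(x, -x)          # -1
#' y <- x; y[10] <- 100  # gross outlier
#' bicor(x, y) > cor(x, y)
#' @export
bicor <- function(x, y, maxPOutliers = 1,
                  fallback = c("zero", "pearson", "error")) {
    fallback <- match.arg(fallback)
    if (length(x) != length(y))
        stop("'x' and 'y' must have equal length")
    if (length(x) < 2L)
        stop("need at least 2 observations")
    px <- .bicorPrep(x, maxPOutliers, fallback)
    py <- .bicorPrep(y, maxPOutliers, fallback)
    nx <- sqrt(sum(px$y^2))
    ny <- sqrt(sum(py$y^2))
    if (px$degenerate || py$degenerate || nx == 0 || ny == 0) {
        warning("degenerate vector (zero MAD or zero weighted norm); ",
                "returning correlation 0")
        return(0)
    }
    r <- sum(px$y * py$y) / (nx * ny)
    max(-1, min(1, r))
}

#' Biweight midcorrelation matrix of an expression matrix
#'
#' Computes all pairwise biweight midcorrelations between the genes (rows)
#' of an [ExpressionMatrix-class], vectorized as a single cross-product of
#' the per-gene weighted, median-centered profiles. Equals element-wise
#' application of [bicor()].
#'
#' Genes with zero MAD (or zero weighted norm) are degenerate: under the
#' `"zero"` fallback their whole row/column, including the diagonal, is 0
#' and a single warning names them; under `"pearson"` they are
#' mean-centered with unit weights; under `"error"` the call stops.
#'
#' @param x an [ExpressionMatrix-class] with >= 2 genes.
#' @inheritParams bicorWeights
#' @return a [CorrelationMatrix-class] over the same genes.
#' @examples
#' set.seed(1)
#' x <- ExpressionMatrix(matrix(rnorm(150), 5, 30,
#'     dimnames = list(paste0("g", 1:5), NULL)), "normal")
#' bicorMatrix(x)
#' @export
bicorMatrix <- function(x, maxPOutliers = 1,
                        fallback = c("zero", "pearson", "error")) {
    fallback <- match.arg(fallback)
    stopifnot(is(x, "ExpressionMatrix"))
    v <- exprValues(x)
    if (nrow(v) < 2L)
        stop("need at least 2 genes")
    n <- nrow(v)
    Y <- matrix(0, n, ncol(v))
    degenerate <- logical(n)
    for (i in seq_len(n)) {
        p <- .bicorPrep(v[i, ], maxPOutliers, fallback)
        Y[i, ] <- p$y
        degenerate[i] <- p$degenerate
    }
    norms <- sqrt(rowSums(Y^2))
    degenerate <- degenerate | norms == 0
    if (any(degenerate))
        warning("degenerate gene(s) with zero MAD or weighted norm: ",
                paste(rownames(v)[degenerate], collapse = ", "),
                "; their correlations are set to 0")
    norms[degenerate] <- 1  # avoid 0/0; rows are zero anyway
    R <- tcrossprod(Y / norms)
    diag(R) <- ifelse(degenerate, 0, 1)
    R[degenerate, ] <- 0
    R[, degenerate] <- 0
    dimnames(R) <- list(rownames(v), rownames(v))
    CorrelationMatrix(R)
}
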