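#' @include AllClasses.R
NULL

#' Pairwise leading-logFC distance
#'
#' For every sample pair, selects the \code{top} genes with the largest
#' absolute expression difference for that pair (pairwise mode) and
#' returns the root-mean-square of those differences. With
#' \code{top = nrow(expr)} this reduces to the plain RMS difference.
#'
#' @param expr expression matrix (genes x samples), e.g. VST values.
#' @param top number of top genes per pair (default 300).
#' @return symmetric distance matrix with zero diagonal.
#' @export
leadingLogFCDistance <- function(expr, top = 300) {
    expr <- as.matrix(expr)
    if (top <= 0) stop("top must be positive", call. = FALSE)
    top <- min(top, nrow(expr))
    n <- ncol(expr)
    d <- matrix(0, n, n, dimnames = list(colnames(expr), colnames(expr)))
    for (i in seq_len(n - 1L)) {
        di <- (expr[, (i + 1L):n, drop = FALSE] - expr[, i])^2
        for (jj in seq_len(ncol(di))) {
            tp <- sort.int(di[, jj], decreasing = TRUE,
                           method = "quick")[seq_len(top)]
            d[i, i + jj] <- d[i + jj, i] <- sqrt(mean(tp))
        }
    }
    d
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson scaling of a distance matrix: double-centred
#' \eqn{-d^2/2}, eigendecomposition, coordinates from the top-k
#' non-negative eigenpairs. Variance explained is each eigenvalue over
#' the sum of positive eigenvalues (negative eigenvalues from
#' non-Euclidean distances are truncated). Axis signs follow the
#' convention that the first nonzero loading of each axis is positive.
#'
#' @param d symmetric distance matrix.
#' @param k number of dimensions (default 2), \code{k < nrow(d)}.
#' @return list with \code{coordinates} (samples x k),
#'   \code{var_explained} per returned axis, and \code{degenerate}
#'   (TRUE when all distances are zero, in which case coordinates are
#'   zero and var_explained NA).
#' @export
classicalMDS <- function(d, k = 2) {
    d <- as.matrix(d)
    n <- nrow(d)
    stopifnot(k >= 1, k < n)
    if (all(d == 0)) {
        return(list(coordinates = matrix(0, n, k,
                                         dimnames = list(rownames(d), NULL)),
                    var_explained = rep(NA_real_, k), degenerate = TRUE))
    }
    mds <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
    pos <- mds$eig[mds$eig > 1e-12 * max(mds$eig)]
    ve <- mds$eig[seq_len(k)] / sum(pos)
    coords <- mds$points
    if (ncol(coords) < k)   # degenerate trailing axes
        coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
    for (j in seq_len(k)) {
        nz <- which(abs(coords[, j]) > 1e-12)
        if (length(nz) && coords[nz[1L], j] < 0)
            coords[, j] <- -coords[, j]
    }
    rownames(coords) <- rownames(d)
    list(coordinates = coords[, seq_len(k), drop = FALSE],
         var_explained = pmax(ve, 0), degenerate = FALSE)
}

#' Hierarchical clustering on Pearson correlation distance
#'
#' Distance \code{1 - r} between items (samples = columns or genes =
#' rows), average linkage. Zero-variance items are rejected by name.
#'
#' @param expr expression matrix (genes x samples).
#' @param axis cluster \code{"samples"} (columns) or \code{"genes"}
#'   (rows).
#' @param linkage agglomeration method (default \code{"average"}).
#' @return an \code{\link[stats]{hclust}} tree (merge heights on the
#'   1 - r scale, leaf order deterministic).
#' @export
pearsonHclust <- function(expr, axis = c("samples", "genes"),
                          linkage = "average") {
    axis <- match.arg(axis)
    m <- if (axis == "samples") t(as.matrix(expr)) else as.matrix(expr)
    v <- apply(m, 1, stats::var)
    if (any(v == 0))
        stop("zero-variance item(s): ",
             paste(rownames(m)[v == 0], collapse = ", "), call. = FALSE)
    dd <- stats::as.dist(1 - stats::cor(t(m)))
    stats::hclust(dd, method = linkage)
}

#' Compare per-gene coefficients of variation between two groups
#'
#' Within each group, the per-gene CV is SD/mean of expression across
#' that group's samples; the two CV distributions are compared over
#' genes by a Welch two-sample t-test (Welch-Satterthwaite df). Genes
#' whose within-group mean is zero have an undefined CV and are dropped
#' (counted in the output).
#'
#' @param expr expression matrix (genes x samples).
#' @param samples data.frame of cage factors aligned with columns.
#' @param groupBy name of the two-level grouping factor (e.g.
#'   \code{"stock"}).
#' @return list with \code{cv} (genes x 2 matrix), \code{t}, \code{df},
#'   \code{p} (group 1 minus group 2), and \code{n_dropped}.
#' @export
cvCompare <- function(expr, samples, groupBy) {
    expr <- as.matrix(expr)
    g <- factor(as.data.frame(samples)[[groupBy]])
    if (nlevels(g) != 2L)
        stop("groupBy must have exactly two levels", call. = FALSE)
    if (any(table(g) < 3L))
        stop("need at least 3 samples per group", call. = FALSE)
    cv <- sapply(levels(g), function(lv) {
        m <- expr[, g == lv, drop = FALSE]
        mu <- rowMeans(m)
        ifelse(mu == 0, NA_real_, apply(m, 1, stats::sd) / mu)
    })
    drop <- rowSums(is.na(cv)) > 0
    tt <- stats::t.test(cv[!drop, 1L], cv[!drop, 2L])
    list(cv = cv, t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value,
         n_dropped = sum(drop), groups = levels(g))
}
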