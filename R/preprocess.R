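#' @include AllClasses.R
NULL

#' Remove transcripts with low total counts
#'
#' Keeps genes whose total read count across all libraries reaches
#' \code{minTotal} (default 50, i.e. transcripts with fewer than 50 total
#' reads are removed); the original gene order is preserved.
#'
#' @param x a \linkS4class{NutriSet}.
#' @param minTotal minimum row sum required to keep a gene.
#' @return the filtered \linkS4class{NutriSet}.
#' @export
filterLowCounts <- function(x, minTotal = 50) {
    stopifnot(is(x, "NutriSet"), minTotal >= 0)
    keep <- rowSums(assay(x, "counts")) >= minTotal
    if (!any(keep))
        warning("all genes removed by the total-count filter",
                call. = FALSE)
    x[keep, ]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes
#' (genes with positive counts in every sample) of the ratio of the
#' gene's count to its geometric mean across samples; factors are then
#' rescaled to geometric mean 1.
#'
#' @param x a \linkS4class{NutriSet} or a count matrix.
#' @return positive numeric vector of size factors, named by sample, with
#'   geometric mean 1.
#' @export
estimateSizeFactors <- function(x) {
    k <- if (is(x, "NutriSet")) assay(x, "counts") else as.matrix(x)
    pos <- rowSums(k > 0) == ncol(k)
    if (!any(pos))
        stop("no gene has positive counts in all samples; supply deeper ",
             "data or use a pseudo-reference fallback", call. = FALSE)
    ref <- k[pos, , drop = FALSE]
    geo <- exp(rowMeans(log(ref)))
    s <- apply(ref / geo, 2, stats::median)
    s <- s / exp(mean(log(s)))
    setNames(s, colnames(k))
}

#' Fit the parametric dispersion-mean trend
#'
#' Gene-wise method-of-moments dispersions on normalized counts,
#' \eqn{\hat\alpha_g = \max(0, (var_g - \bar\mu_g)/\bar\mu_g^2)}, are
#' regressed on \eqn{1/\bar\mu} by iteratively reweighted least squares
#' (gamma-style weights \eqn{1/fitted^2}) to obtain the trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu}. Genes with zero moment estimates or
#' non-positive normalized means are excluded from the fit; a degenerate
#' intercept is clamped to \code{1e-8} with a warning, and a negative
#' slope to 0.
#'
#' @param x a \linkS4class{NutriSet} or count matrix.
#' @param s size factors from \code{\link{estimateSizeFactors}}.
#' @return a \linkS4class{DispersionTrend}.
#' @export
fitDispersionTrend <- function(x, s = estimateSizeFactors(x)) {
    k <- if (is(x, "NutriSet")) assay(x, "counts") else as.matrix(x)
    u <- sweep(k, 2, s, `/`)
    mu <- rowMeans(u)
    v <- apply(u, 1, stats::var)
    ok <- mu > 0
    if (sum(ok) < 50)
        stop("need at least 50 genes with positive normalized mean",
             call. = FALSE)
    alpha <- pmax(0, (v[ok] - mu[ok]) / mu[ok]^2)
    use <- alpha > 0
    am <- alpha[use]
    xm <- 1 / mu[ok][use]
    ## IRLS: OLS start, then gamma-style weights 1/fitted^2
    co <- stats::coef(stats::lm(am ~ xm))
    for (i in 1:8) {
        fit <- pmax(co[1] + co[2] * xm, 1e-10)
        co <- stats::coef(stats::lm(am ~ xm, weights = 1 / fit^2))
    }
    a0 <- unname(co[1]); a1 <- unname(co[2])
    if (is.na(a0) || a0 <= 0) {
        warning("degenerate dispersion fit: clamping a0 to 1e-8",
                call. = FALSE)
        a0 <- 1e-8
    }
    if (is.na(a1) || a1 < 0) a1 <- 0
    new("DispersionTrend", a0 = a0, a1 = a1)
}

#' Closed-form variance-stabilizing transformation
#'
#' For normalized counts \eqn{u = K_{gi}/s_i} under the dispersion trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu}, returns
#' \deqn{\log_2\frac{1 + a_1 + 2 a_0 u + 2\sqrt{a_0 u (1 + a_1 + a_0 u)}}
#'   {4 a_0},}
#' which is strictly increasing in \eqn{u}, finite at \eqn{u = 0}
#' (\eqn{\log_2((1+a_1)/(4a_0))}) and asymptotically \eqn{\log_2 u} plus
#' a constant.
#'
#' @param x a \linkS4class{NutriSet} or count matrix.
#' @param s size factors.
#' @param trend a \linkS4class{DispersionTrend}.
#' @return matrix of transformed values with attribute
#'   \code{transform = "vst"}.
#' @export
vstTransform <- function(x, s = estimateSizeFactors(x),
                         trend = fitDispersionTrend(x, s)) {
    k <- if (is(x, "NutriSet")) assay(x, "counts") else as.matrix(x)
    validObject(trend)
    u <- sweep(k, 2, s, `/`)
    a0 <- trend@a0; a1 <- trend@a1
    out <- log2((1 + a1 + 2 * a0 * u +
                     2 * sqrt(a0 * u * (1 + a1 + a0 * u))) / (4 * a0))
    attr(out, "transform") <- "vst"
    out
}

#' Log counts-per-million
#'
#' \eqn{\log_2((K_{gi} + 0.5)/(L_i + 1) \times 10^6)} with \eqn{L_i} the
#' column (library) sum — the offset form used by precision-weighted
#' linear modelling.
#'
#' @param x a \linkS4class{NutriSet} or count matrix.
#' @return matrix of log2-cpm values with attribute
#'   \code{transform = "logcpm"}.
#' @export
logCPM <- function(x) {
    k <- if (is(x, "NutriSet")) assay(x, "counts") else as.matrix(x)
    L <- colSums(k)
    if (any(L <= 0)) stop("library sizes must be positive", call. = FALSE)
    out <- log2(sweep(k + 0.5, 2, L + 1, `/`) * 1e6)
    attr(out, "transform") <- "logcpm"
    out
}
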