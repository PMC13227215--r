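#' @include AllClasses.R
NULL

#' Build a treatment-coded design matrix with blocking
#'
#' Expands the requested factors into a full-rank design matrix with an
#' intercept: one indicator column per non-reference level. Diet is
#' releveled so that the sugar-only diet is the reference, mirroring the
#' analysis in which all protein/lipid diets are contrasted against
#' sugar-fed bees; source colony enters as fixed-effect indicators
#' (blocking).
#'
#' @param samples data.frame of cage factors (or \code{colData} of a
#'   \linkS4class{NutriSet}).
#' @param terms character vector of factor names drawn from
#'   \code{samples}, e.g. \code{c("diet", "colony")}.
#' @return numeric design matrix, rows aligned with \code{samples}.
#' @export
buildDesign <- function(samples, terms) {
    samples <- as.data.frame(samples)
    missing <- setdiff(terms, colnames(samples))
    if (length(missing))
        stop("terms not found in sample table: ",
             paste(missing, collapse = ", "), call. = FALSE)
    df <- samples[, terms, drop = FALSE]
    for (tm in terms) {
        f <- factor(df[[tm]])
        if (tm == "diet" && "sugar" %in% levels(f))
            f <- stats::relevel(f, "sugar")
        df[[tm]] <- f
    }
    constant <- vapply(df, function(f) nlevels(f) < 2L, TRUE)
    if (any(constant))
        stop("factor(s) with a single level: ",
             paste(terms[constant], collapse = ", "), call. = FALSE)
    X <- stats::model.matrix(
        stats::as.formula(paste("~", paste(terms, collapse = " + "))), df)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        stop("design is rank deficient; aliased column(s): ",
             paste(aliased, collapse = ", "), call. = FALSE)
    }
    X
}

#' Precision weights from the mean-variance trend
#'
#' Implements the standard precision-weight recipe: (1) unweighted
#' gene-wise least squares on log-cpm; (2) per-gene square-root residual
#' SD paired with average log2 count (mean log-cpm +
#' \eqn{\log_2(\tilde L + 1) - \log_2 10^6}, \eqn{\tilde L} the geometric
#' mean library size); (3) lowess of sqrt-SD on average log-count,
#' span 0.5; (4) each observation's fitted log-count is interpolated on
#' the trend (flat extrapolation beyond the range) and the weight is the
#' interpolated value to the power -4.
#'
#' @param x a \linkS4class{NutriSet} or count matrix.
#' @param design design matrix from \code{\link{buildDesign}}.
#' @param span lowess span for the trend.
#' @return list with \code{weights} (genes x samples, all finite and
#'   positive), \code{logcpm}, and the lowess \code{trend}
#'   (data.frame x, y).
#' @export
voomWeights <- function(x, design, span = 0.5) {
    k <- if (is(x, "NutriSet")) assay(x, "counts") else as.matrix(x)
    if (nrow(k) < 10)
        stop("mean-variance trend needs at least 10 genes", call. = FALSE)
    if (nrow(design) != ncol(k))
        stop("design rows must match samples", call. = FALSE)
    df <- ncol(k) - qr(design)$rank
    if (df < 2)
        stop("need at least 2 residual degrees of freedom", call. = FALSE)
    L <- colSums(k)
    y <- logCPM(k)

    qrX <- qr(design)
    beta <- t(qr.coef(qrX, t(y)))
    fitted <- beta %*% t(design)
    res <- y - fitted
    sigma <- sqrt(rowSums(res^2) / df)

    amean <- rowMeans(y) + mean(log2(L + 1)) - log2(1e6)
    sqrtSd <- sqrt(sigma)
    lo <- stats::lowess(amean, sqrtSd, f = span)
    trendFun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)

    fittedCount <- fitted + matrix(log2(L + 1), nrow(k), ncol(k),
                                   byrow = TRUE) - log2(1e6)
    w <- trendFun(fittedCount)^-4
    dim(w) <- dim(k)
    dimnames(w) <- dimnames(k)
    if (any(!is.finite(w)) || any(w <= 0))
        stop("non-finite or non-positive precision weights", call. = FALSE)
    list(weights = w, logcpm = y,
         trend = data.frame(x = lo$x, y = lo$y))
}

#' Gene-wise weighted least squares
#'
#' Fits one weighted linear model per gene, retaining the full unscaled
#' coefficient covariance \eqn{(X'WX)^{-1}} so that contrast variances
#' can later be formed exactly (weights differ per gene).
#'
#' @param y expression matrix (genes x samples), e.g. log-cpm.
#' @param design design matrix.
#' @param weights optional genes x samples precision weights (unit
#'   weights when \code{NULL}).
#' @return a \linkS4class{GeneFitSet}.
#' @export
fitGeneLms <- function(y, design, weights = NULL) {
    y <- as.matrix(y)
    G <- nrow(y); n <- ncol(y); p <- ncol(design)
    if (!is.null(weights)) {
        weights <- as.matrix(weights)
        if (!all(dim(weights) == dim(y)))
            stop("weights must match the expression matrix", call. = FALSE)
        if (any(!is.finite(weights)) || any(weights <= 0))
            stop("weights must be finite and positive", call. = FALSE)
    }
    rk <- qr(design)$rank
    if (rk < p) stop("design must have full column rank", call. = FALSE)
    df <- n - rk
    if (df <= 0) stop("no residual degrees of freedom", call. = FALSE)

    beta <- matrix(NA_real_, G, p, dimnames = list(rownames(y),
                                                   colnames(design)))
    sdu <- beta
    sigma <- numeric(G)
    covA <- array(NA_real_, c(p, p, G))
    for (g in seq_len(G)) {
        w <- if (is.null(weights)) rep(1, n) else weights[g, ]
        fit <- stats::lm.wfit(design, y[g, ], w)
        XtWX <- crossprod(design * sqrt(w))
        V <- chol2inv(chol(XtWX))
        beta[g, ] <- fit$coefficients
        covA[, , g] <- V
        sdu[g, ] <- sqrt(diag(V))
        sigma[g] <- sqrt(sum(w * fit$residuals^2) / df)
    }
    new("GeneFitSet", coefficients = beta, stdevUnscaled = sdu,
        sigma = sigma, df = rep(as.numeric(df), G), covArray = covA,
        design = design)
}

#' Build a contrast matrix from coefficient expressions
#'
#' @param contrasts named list of numeric vectors over design columns
#'   (each a contrast specification, not all zero).
#' @param design design matrix whose columns the coefficients refer to.
#' @return columns-as-contrasts numeric matrix.
#' @export
makeContrastMatrix <- function(contrasts, design) {
    p <- ncol(design)
    cm <- vapply(contrasts, function(cc) {
        if (length(cc) != p)
            stop("contrast length must equal number of design columns",
                 call. = FALSE)
        if (all(cc == 0))
            stop("contrast must not be the zero vector", call. = FALSE)
        as.numeric(cc)
    }, numeric(p))
    rownames(cm) <- colnames(design)
    cm
}

#' Reparameterize gene fits to contrasts
#'
#' For each gene, each contrast \eqn{c} becomes an estimate \eqn{c'\beta}
#' with exact unscaled variance \eqn{c'Vc} from the stored per-gene
#' covariance; residual SD and degrees of freedom are unchanged.
#'
#' @param fits a \linkS4class{GeneFitSet} from \code{\link{fitGeneLms}}.
#' @param contrasts contrast matrix (design columns x contrasts), e.g.
#'   from \code{\link{makeContrastMatrix}}, or a named list of vectors.
#' @return a \linkS4class{GeneFitSet} whose coefficients are the contrast
#'   estimates.
#' @export
applyContrasts <- function(fits, contrasts) {
    stopifnot(is(fits, "GeneFitSet"))
    if (is.list(contrasts))
        contrasts <- makeContrastMatrix(contrasts, fits@design)
    cm <- as.matrix(contrasts)
    p <- ncol(fits@coefficients)
    if (nrow(cm) != p)
        stop("contrast rows must match design columns", call. = FALSE)
    if (any(colSums(cm != 0) == 0))
        stop("contrast must not be the zero vector", call. = FALSE)
    if (length(dim(fits@covArray)) != 3L)
        stop("fits have already been reparameterized", call. = FALSE)
    G <- nrow(fits@coefficients)
    est <- fits@coefficients %*% cm
    sdu <- matrix(NA_real_, G, ncol(cm),
                  dimnames = list(rownames(fits@coefficients),
                                  colnames(cm)))
    for (j in seq_len(ncol(cm))) {
        cc <- cm[, j]
        sdu[, j] <- sqrt(vapply(seq_len(G), function(g)
            drop(crossprod(cc, fits@covArray[, , g] %*% cc)), 1.0))
    }
    new("GeneFitSet", coefficients = est, stdevUnscaled = sdu,
        sigma = fits@sigma, df = fits@df,
        covArray = array(numeric(0), c(0, 0, 0)), design = fits@design)
}

## Newton inversion of the trigamma function (decreasing, convex on x>0).
trigammaInverse <- function(y) {
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    x <- 0.5 + 1 / y
    for (i in 1:50) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, 2)
        x <- x + dif
        if (-dif / x < 1e-8) break
    }
    x
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Estimates a scaled inverse-chi-square prior (d0, s0^2) on the residual
#' variances by moment matching on the log scale: with
#' \eqn{e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)}, solve
#' \eqn{\psi'(d_0/2) = \max(0, var(e) - \overline{\psi'(d_g/2)})} for d0
#' (\eqn{d_0 = \infty} when the right side is non-positive), then
#' \eqn{s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))}. Posterior
#' variances are \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)},
#' moderated t statistics \eqn{\hat\beta/(\tilde s_g \sqrt{v})} with
#' \eqn{d_0 + d_g} degrees of freedom.
#'
#' Genes with \eqn{s_g = 0} (exactly replicated values) are excluded from
#' prior estimation but still moderated; if every gene has zero residual
#' variance the data are degenerate and an error is raised.
#'
#' @param fits a (typically contrast-reparameterized)
#'   \linkS4class{GeneFitSet}.
#' @param d0Override force the prior degrees of freedom: \code{0} yields
#'   ordinary (unmoderated) t statistics, \code{Inf} the fully pooled
#'   statistic; \code{NULL} (default) estimates d0 from the data.
#' @return list with \code{prior} (a \linkS4class{ModerationPrior}; d0 =
#'   0 is represented by a prior with the estimated s0sq but bypasses
#'   shrinkage) and \code{results}, a named list of per-contrast
#'   data.frames (gene_id, logFC, t, p, fdr, direction) sorted as input.
#' @export
ebayesModerate <- function(fits, d0Override = NULL) {
    stopifnot(is(fits, "GeneFitSet"))
    if (nrow(fits@coefficients) < 10)
        stop("moderation needs at least 10 genes", call. = FALSE)
    s2 <- fits@sigma^2
    dg <- fits@df
    ok <- s2 > 0
    if (!any(ok))
        stop("all residual variances are zero: degenerate data",
             call. = FALSE)
    e <- log(s2[ok]) - digamma(dg[ok] / 2) + log(dg[ok] / 2)
    rhs <- stats::var(e) - mean(trigamma(dg[ok] / 2))
    if (is.null(d0Override)) {
        d0 <- if (rhs > 0) 2 * trigammaInverse(rhs) else Inf
    } else d0 <- d0Override
    s0sq <- if (is.finite(d0) && d0 > 0)
        exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    else mean(s2[ok])   # d0 = Inf: pooled scale is the mean variance
    prior <- new("ModerationPrior",
                 d0 = if (d0 > 0) d0 else Inf, s0sq = s0sq)
    if (d0 == 0) {            # no moderation: ordinary t
        s2post <- s2
        dfTotal <- dg
    } else if (is.infinite(d0)) {
        s2post <- rep(s0sq, length(s2))
        dfTotal <- rep(Inf, length(s2))
    } else {
        s2post <- (d0 * s0sq + dg * s2) / (d0 + dg)
        dfTotal <- d0 + dg
    }
    results <- lapply(seq_len(ncol(fits@coefficients)), function(j) {
        est <- fits@coefficients[, j]
        tmod <- est / (sqrt(s2post) * fits@stdevUnscaled[, j])
        p <- 2 * stats::pt(-abs(tmod), df = dfTotal)
        data.frame(gene_id = rownames(fits@coefficients),
                   logFC = unname(est), t = unname(tmod), p = unname(p),
                   fdr = bhAdjust(unname(p)),
                   direction = sign(unname(est)),
                   row.names = NULL)
    })
    names(results) <- colnames(fits@coefficients)
    list(prior = prior, results = results)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (ties preserved).
#'
#' @param p numeric vector of p-values in [0, 1]; NaN/NA are rejected.
#' @return vector of adjusted p-values.
#' @export
bhAdjust <- function(p) {
    if (anyNA(p)) stop("p-values must not contain NA/NaN", call. = FALSE)
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]",
                                 call. = FALSE)
    stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Strict thresholds matching the volcano-plot rule: \code{fdr < fdrMax}
#' and \code{|logFC| > lfcMin} (a gene exactly at either threshold is
#' excluded).
#'
#' @param results one per-contrast data.frame from
#'   \code{\link{ebayesModerate}}.
#' @param fdrMax FDR threshold (default 0.05).
#' @param lfcMin absolute log2 fold-change threshold (default 0.6); set
#'   to 0 to call on FDR alone.
#' @param name label for the resulting set.
#' @return a \linkS4class{DEGSet} with per-gene direction signs.
#' @export
callDegs <- function(results, fdrMax = 0.05, lfcMin = 0.6, name = "degs") {
    stopifnot(fdrMax > 0, lfcMin >= 0)
    hit <- results$fdr < fdrMax & abs(results$logFC) > lfcMin
    genes <- results$gene_id[hit]
    new("DEGSet", name = name, genes = genes,
        directions = setNames(as.integer(sign(results$logFC[hit])), genes))
}

#' Moderated differential expression in one call
#'
#' Convenience wrapper: log-cpm, precision weights, gene-wise WLS,
#' optional contrasts, empirical-Bayes moderation and BH adjustment.
#'
#' @param x a \linkS4class{NutriSet}.
#' @param design design matrix from \code{\link{buildDesign}}.
#' @param contrasts optional contrast matrix or named list; when
#'   \code{NULL}, all non-intercept coefficients are tested.
#' @return the \code{\link{ebayesModerate}} result list.
#' @export
runModeratedDE <- function(x, design, contrasts = NULL) {
    vw <- voomWeights(x, design)
    fits <- fitGeneLms(vw$logcpm, design, vw$weights)
    if (is.null(contrasts)) {
        keep <- setdiff(colnames(design), "(Intercept)")
        cm <- diag(ncol(design))[, match(keep, colnames(design)),
                                 drop = FALSE]
        dimnames(cm) <- list(colnames(design), keep)
        contrasts <- cm
    }
    ebayesModerate(applyContrasts(fits, contrasts))
}
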