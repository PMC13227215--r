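#' @include AllClasses.R
NULL

#' Candidate feature set for stock classification
#'
#' Union of the per-stock core DEG sets (genes differentially expressed
#' under every protein/lipid diet within a stock).
#'
#' @param degsets list of two or more \linkS4class{DEGSet}s.
#' @return character vector of gene ids.
#' @export
candidateFeatures <- function(degsets) {
    stopifnot(length(degsets) >= 2)
    u <- Reduce(union, lapply(degsets, geneIds))
    if (!length(u)) stop("union of DEG sets is empty", call. = FALSE)
    sort(u)
}

.standardize <- function(X, center = NULL, scale = NULL) {
    if (is.null(center)) center <- colMeans(X)
    if (is.null(scale)) {
        scale <- apply(X, 2, stats::sd)
        scale[scale == 0] <- 1
    }
    list(X = sweep(sweep(X, 2, center), 2, scale, `/`),
         center = center, scale = scale)
}

## Linear SVM weight vector from an e1071 fit.
.svmW <- function(fit) drop(crossprod(fit$coefs, fit$SV))

## |t| statistic of each feature between classes, restricted to the
## support vectors; 1 when undefined (a class absent or variance zero).
.svScore <- function(Xsv, ysv) {
    if (length(unique(ysv)) < 2L) return(rep(1, ncol(Xsv)))
    a <- Xsv[ysv == levels(ysv)[1L], , drop = FALSE]
    b <- Xsv[ysv == levels(ysv)[2L], , drop = FALSE]
    if (nrow(a) < 2L || nrow(b) < 2L) return(rep(1, ncol(Xsv)))
    se <- sqrt(apply(a, 2, stats::var) / nrow(a) +
                   apply(b, 2, stats::var) / nrow(b))
    tt <- abs(colMeans(a) - colMeans(b)) / se
    tt[!is.finite(tt)] <- 1
    tt
}

#' SVM recursive feature elimination ranking
#'
#' Iteratively fits a linear SVM (cost \code{C}) on internally
#' standardized features and eliminates the lowest-scoring fraction per
#' round; the reversed elimination order is the ranking (best first).
#' With \code{scoring = "sigfeature"} (default) the per-feature score is
#' \eqn{|w_j|} times the absolute two-sample t statistic of the feature
#' computed on the current support vectors, a documented stand-in for
#' significance-weighted SVM-RFE; \code{scoring = "svmrfe"} uses
#' \eqn{|w_j|} alone. Ties break toward the smaller feature index.
#'
#' @param X samples x features matrix.
#' @param labels two-level factor (stock per sample).
#' @param stepFraction fraction of remaining features eliminated per
#'   round (default 0.1, at least one per round).
#' @param C SVM cost parameter (default 1, no inner tuning).
#' @param scoring \code{"sigfeature"} or \code{"svmrfe"}.
#' @param seed integer seed (the fit is deterministic; the seed guards
#'   any downstream stochastic use).
#' @return character vector: all features, most discriminative first.
#' @export
svmRfeRank <- function(X, labels, stepFraction = 0.1, C = 1,
                       scoring = c("sigfeature", "svmrfe"), seed = 1) {
    scoring <- match.arg(scoring)
    X <- as.matrix(X)
    labels <- factor(labels)
    if (nlevels(labels) != 2L)
        stop("labels must have exactly two classes", call. = FALSE)
    if (any(table(labels) < 2L))
        stop("each class needs at least 2 samples", call. = FALSE)
    features <- colnames(X)
    if (is.null(features)) stop("X must have feature names", call. = FALSE)
    set.seed(seed)
    eliminated <- character(0)
    current <- features
    while (length(current) > 1L) {
        std <- .standardize(X[, current, drop = FALSE])
        fit <- e1071::svm(std$X, labels, kernel = "linear", cost = C,
                          scale = FALSE)
        score <- abs(.svmW(fit))
        if (scoring == "sigfeature") {
            svIdx <- fit$index
            score <- score * .svScore(std$X[svIdx, , drop = FALSE],
                                      labels[svIdx])
        }
        nDrop <- max(1L, ceiling(stepFraction * length(current)))
        nDrop <- min(nDrop, length(current) - 1L)
        ord <- order(score, seq_along(current))   # ties: smaller index first
        drop <- current[ord[seq_len(nDrop)]]
        eliminated <- c(drop, eliminated)
        current <- setdiff(current, drop)
    }
    c(current, eliminated)
}

.stratifiedFolds <- function(labels, folds, seed) {
    set.seed(seed)
    fold <- integer(length(labels))
    for (lv in levels(labels)) {
        idx <- sample(which(labels == lv))
        fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
}

#' External cross-validation error curve for SVM-RFE
#'
#' Stratified k-fold cross-validation in which both feature ranking and
#' standardization are recomputed inside every training fold (external
#' CV — the held-out fold never informs feature selection). For each
#' feature count k on the grid, the misclassification rate of a linear
#' SVM restricted to the fold's top-k features is measured on the
#' held-out fold. The returned trace also carries the full-data ranking
#' used for reporting the final feature list.
#'
#' @param X samples x features matrix.
#' @param labels two-level factor.
#' @param kGrid feature counts to score (default powers-of-two style
#'   grid up to the feature count).
#' @param folds number of folds (default 10); each fold must contain
#'   both classes.
#' @param stepFraction,C,scoring passed to \code{\link{svmRfeRank}}.
#' @param seed integer seed controlling fold assignment.
#' @return an \linkS4class{SVMTrace}.
#' @export
externalCvCurve <- function(X, labels, kGrid = NULL, folds = 10,
                            stepFraction = 0.1, C = 1,
                            scoring = c("sigfeature", "svmrfe"),
                            seed = 1) {
    scoring <- match.arg(scoring)
    X <- as.matrix(X)
    labels <- factor(labels)
    if (nlevels(labels) != 2L)
        stop("labels must have exactly two classes", call. = FALSE)
    if (folds > min(table(labels)))
        stop("more folds than the smaller class supports", call. = FALSE)
    p <- ncol(X)
    if (is.null(kGrid)) {
        kGrid <- unique(pmin(c(2^(0:20), p), p))
        kGrid <- kGrid[kGrid >= 1]
    }
    kGrid <- sort(unique(as.integer(kGrid)))
    if (any(kGrid > p)) stop("kGrid exceeds feature count", call. = FALSE)
    fold <- .stratifiedFolds(labels, folds, seed)
    errs <- matrix(NA_real_, folds, length(kGrid))
    for (f in seq_len(folds)) {
        tr <- fold != f; te <- !tr
        if (length(unique(labels[te])) < 2L || length(unique(labels[tr])) < 2L)
            stop("a fold lost one of the classes; reduce folds",
                 call. = FALSE)
        std <- .standardize(X[tr, , drop = FALSE])
        rk <- svmRfeRank(std$X, labels[tr], stepFraction = stepFraction,
                         C = C, scoring = scoring, seed = seed + f)
        Xte <- .standardize(X[te, , drop = FALSE],
                            center = std$center, scale = std$scale)$X
        for (ki in seq_along(kGrid)) {
            feats <- rk[seq_len(kGrid[ki])]
            fit <- e1071::svm(std$X[, feats, drop = FALSE], labels[tr],
                              kernel = "linear", cost = C, scale = FALSE)
            pred <- stats::predict(fit, Xte[, feats, drop = FALSE])
            errs[f, ki] <- mean(pred != labels[te])
        }
    }
    fullStd <- .standardize(X)
    fullRank <- svmRfeRank(fullStd$X, labels, stepFraction = stepFraction,
                           C = C, scoring = scoring, seed = seed)
    new("SVMTrace", kGrid = kGrid,
        cvErrorMean = colMeans(errs),
        cvErrorSd = apply(errs, 2, stats::sd),
        ranking = fullRank, folds = fold)
}

#' Top-k features from the full-data ranking
#'
#' @param trace an \linkS4class{SVMTrace}.
#' @param k number of features (default 20).
#' @return character vector of the k top-ranked features.
#' @export
selectTopFeatures <- function(trace, k = 20) {
    stopifnot(is(trace, "SVMTrace"))
    if (k > length(trace@ranking))
        stop("k exceeds the ranking length", call. = FALSE)
    trace@ranking[seq_len(k)]
}
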