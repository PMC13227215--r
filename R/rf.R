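#' @include AllClasses.R
NULL

#' Random-forest configuration
#'
#' @param nTrees trees per forest (default 1000; keep >= 100 so every
#'   sample appears out-of-bag).
#' @param mtryGrid candidate \code{mtry} values per tuning step; when
#'   \code{NULL}, \code{p/10}, \code{p/3}, \code{p/2} and \code{sqrt(p)}
#'   (rounded, deduplicated, floored at 1) of the current feature count.
#' @param minNodeSize minimum terminal node size (default 5, regression
#'   convention).
#' @param importanceMode \code{"permutation_oob"} (signed OOB permutation
#'   importance, default) or \code{"impurity_corrected"}.
#' @param seed integer seed.
#' @return list of class \code{"RFConfig"}.
#' @export
rfConfig <- function(nTrees = 1000, mtryGrid = NULL, minNodeSize = 5,
                     importanceMode = c("permutation_oob",
                                        "impurity_corrected"),
                     seed = 1) {
    importanceMode <- match.arg(importanceMode)
    structure(list(nTrees = as.integer(nTrees), mtryGrid = mtryGrid,
                   minNodeSize = as.integer(minNodeSize),
                   importanceMode = importanceMode,
                   seed = as.integer(seed)),
              class = "RFConfig")
}

.mtryGrid <- function(p, grid) {
    if (!is.null(grid)) return(sort(unique(pmin(pmax(1L, as.integer(grid)),
                                                p))))
    sort(unique(pmax(1L, floor(c(p / 10, p / 3, p / 2, sqrt(p))))))
}

#' Fit a random-forest regression with out-of-bag scoring
#'
#' @param X samples x features matrix of normalized expression.
#' @param y numeric response (per-cage weight, mg).
#' @param config an \code{\link{rfConfig}}.
#' @param mtry number of candidate features per split; when \code{NULL},
#'   tuned over \code{config$mtryGrid} by OOB RMSE.
#' @return list with \code{model} (ranger fit), \code{mtry},
#'   \code{oob_pred}, \code{oob_rmse}, \code{oob_r2} and signed
#'   \code{importance} per feature.
#' @export
rfOobFit <- function(X, y, config = rfConfig(), mtry = NULL) {
    X <- as.matrix(X)
    if (nrow(X) < 10) stop("need at least 10 samples", call. = FALSE)
    if (anyNA(X) || anyNA(y)) stop("missing values not allowed",
                                   call. = FALSE)
    imode <- if (config$importanceMode == "permutation_oob") "permutation"
             else "impurity_corrected"
    fitOne <- function(m) {
        set.seed(config$seed)
        ranger::ranger(x = X, y = y, num.trees = config$nTrees,
                       mtry = m, min.node.size = config$minNodeSize,
                       importance = imode, num.threads = 1L)
    }
    if (is.null(mtry)) {
        grid <- .mtryGrid(ncol(X), config$mtryGrid)
        fits <- lapply(grid, fitOne)
        rmse <- vapply(fits, function(f) sqrt(f$prediction.error), 1.0)
        best <- which.min(rmse)
        model <- fits[[best]]
        mtry <- grid[best]
    } else model <- fitOne(mtry)
    pred <- model$predictions
    if (anyNA(pred))
        stop("some samples were never out-of-bag; increase nTrees",
             call. = FALSE)
    sse <- sum((pred - y)^2)
    sst <- sum((y - mean(y))^2)
    list(model = model, mtry = mtry, oob_pred = pred,
         oob_rmse = sqrt(mean((pred - y)^2)),
         oob_r2 = if (sst > 0) 1 - sse / sst else 0,  # constant response
         importance = model$variable.importance)
}

#' Recursive feature elimination by OOB importance
#'
#' Iteratively: tune \code{mtry} over the grid by OOB RMSE, record the
#' round, then drop every feature whose importance is strictly negative
#' (features that actively hurt OOB performance; a feature the forest
#' never used scores exactly zero and is retained, since there is no
#' evidence against it). Stops when no feature drops, fewer than 2
#' remain, or the round limit is hit. The optimal round minimizes OOB
#' RMSE, ties broken toward the smaller feature set.
#'
#' @param X samples x features matrix.
#' @param y numeric response.
#' @param config an \code{\link{rfConfig}}; the seed advances
#'   deterministically across rounds.
#' @param maxRounds safety cap on elimination rounds (default 50).
#' @return an \linkS4class{RFETrace}.
#' @export
rfeSelect <- function(X, y, config = rfConfig(), maxRounds = 50) {
    X <- as.matrix(X)
    if (ncol(X) < 2) stop("need at least 2 features", call. = FALSE)
    features <- colnames(X)
    if (is.null(features)) stop("X must have feature names", call. = FALSE)
    rounds <- list(); sets <- list()
    for (r in seq_len(maxRounds)) {
        cfg <- config; cfg$seed <- config$seed + r - 1L
        fit <- rfOobFit(X[, features, drop = FALSE], y, cfg)
        rounds[[r]] <- data.frame(n_features = length(features),
                                  mtry = fit$mtry,
                                  oob_rmse = fit$oob_rmse,
                                  oob_r2 = fit$oob_r2)
        sets[[r]] <- features
        keep <- features[fit$importance >= 0]
        if (length(keep) == length(features) || length(keep) < 2) break
        features <- keep
    }
    tab <- do.call(rbind, rounds)
    ## argmin OOB RMSE; ties -> later round = smaller nested set
    best <- which(tab$oob_rmse == min(tab$oob_rmse))
    opt <- best[length(best)]
    new("RFETrace", rounds = tab, featureSets = sets,
        optimumRound = as.integer(opt))
}

#' Pearson correlations between features and the weight response
#'
#' @param expr expression matrix (genes x samples) or samples x features
#'   matrix; orientation is resolved against \code{length(y)}.
#' @param y numeric response.
#' @param featureIds features to report (default all).
#' @return data.frame (gene_id, r, p, n) sorted by descending r;
#'   zero-variance features carry NA r/p and a \code{flagged} marker.
#' @export
weightCorrelations <- function(expr, y, featureIds = NULL) {
    m <- as.matrix(expr)
    if (ncol(m) != length(y) && nrow(m) == length(y)) m <- t(m)
    if (ncol(m) != length(y))
        stop("expression and response dimensions disagree", call. = FALSE)
    if (!is.null(featureIds)) {
        missing <- setdiff(featureIds, rownames(m))
        if (length(missing))
            stop("unknown feature id(s): ",
                 paste(utils::head(missing, 5), collapse = ", "),
                 call. = FALSE)
        m <- m[featureIds, , drop = FALSE]
    }
    n <- length(y)
    v <- apply(m, 1, stats::var)
    r <- rep(NA_real_, nrow(m)); p <- r
    ok <- v > 0 & stats::var(y) > 0
    if (any(ok)) {
        r[ok] <- as.vector(stats::cor(t(m[ok, , drop = FALSE]), y))
        tstat <- r[ok] * sqrt((n - 2) / pmax(1 - r[ok]^2, .Machine$double.eps))
        p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    out <- data.frame(gene_id = rownames(m), r = r, p = p, n = n,
                      flagged = !ok, row.names = NULL)
    out[order(-out$r, out$gene_id, na.last = TRUE), , drop = FALSE]
}

#' Select a biomarker panel by correlation cutoff
#'
#' Panel rule: \eqn{r \ge rCut} (inclusive) and \eqn{p < alpha} with
#' \eqn{r > 0}. Also reports the broader positive-significant tier
#' (\eqn{r > 0}, \eqn{p < alpha}).
#'
#' @param records data.frame from \code{\link{weightCorrelations}}.
#' @param rCut correlation cutoff in (0, 1), default 0.75.
#' @param alpha significance level for the (unadjusted) correlation
#'   p-value, default 0.05.
#' @return list with \code{panel} and \code{positive_significant}
#'   character vectors of gene ids.
#' @export
selectPanel <- function(records, rCut = 0.75, alpha = 0.05) {
    stopifnot(rCut > 0, rCut < 1)
    ok <- !is.na(records$r) & !is.na(records$p)
    posSig <- ok & records$r > 0 & records$p < alpha
    panel <- posSig & records$r >= rCut
    if (!any(panel))
        warning("empty biomarker panel at r >= ", rCut, call. = FALSE)
    list(panel = records$gene_id[panel],
         positive_significant = records$gene_id[posSig])
}
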