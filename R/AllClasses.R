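#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

.BIOTYPES <- c("protein_coding", "lncRNA", "viral", "other")

#' Simulation configuration for the cage-design count simulator
#'
#' Holds every knob of the negative-binomial simulator: the experimental
#' design (stocks, diets, source colonies, cages), the planted expression
#' programs (diet, stock, body weight) and the count-level nuisance
#' parameters (baseline abundance, dispersion trend, library size spread).
#' Defaults reproduce the study design the package targets: 2 genetic
#' stocks (Pol-line, Russian) x 4 diets (sugar reference plus three
#' protein/lipid diets) x 4 + 3 source colonies x 4 cages = 112 cage-level
#' libraries.
#'
#' @slot nGenes number of simulated transcripts.
#' @slot nColoniesPerStock integer vector, source colonies per stock
#'   (recycled to the number of stocks).
#' @slot cagesPerColonyPerDiet replicate cages per colony x diet cell.
#' @slot stocks,diets factor level labels; \code{diets} must contain the
#'   reference level \code{"sugar"}.
#' @slot fracLncRNA proportion of genes annotated lncRNA.
#' @slot nViral number of viral features (simulated as ordinary count rows
#'   flagged \code{viral}).
#' @slot nDietProgram,dietLfc size and log2 effect of the protein/lipid
#'   diet response program.
#' @slot nStockProgram,stockLfc size and log2 effect of the stock program.
#' @slot lncRNABias odds multiplier favouring lncRNAs when sampling the
#'   stock program.
#' @slot nWeightProgram genes whose expression tracks the latent nutrition
#'   score that drives cage weight.
#' @slot weightBeta mg of head+thorax dry mass per unit latent score.
#' @slot weightBaseMg baseline per-bee dry mass, mg.
#' @slot weightNoiseSd residual SD of cage weight, mg.
#' @slot colonySd SD of per-colony random intercepts, log2 units.
#' @slot viralStockLfc log2 shift of viral features in the second stock.
#' @slot baselineLogmeanRange range (log2 counts) of baseline abundances.
#' @slot dispersionA0,dispersionA1 NB dispersion trend
#'   \eqn{\alpha(\mu) = a_0 + a_1/\mu}.
#' @slot libsizeLognormalSd SD of log-normal library size factors.
#' @slot seed integer seed making the dataset fully reproducible.
#' @export
setClass("SimConfig", representation(
    nGenes = "integer",
    nColoniesPerStock = "integer",
    cagesPerColonyPerDiet = "integer",
    stocks = "character",
    diets = "character",
    fracLncRNA = "numeric",
    nViral = "integer",
    nDietProgram = "integer",
    dietLfc = "numeric",
    nStockProgram = "integer",
    stockLfc = "numeric",
    lncRNABias = "numeric",
    nWeightProgram = "integer",
    weightBeta = "numeric",
    weightBaseMg = "numeric",
    weightNoiseSd = "numeric",
    colonySd = "numeric",
    viralStockLfc = "numeric",
    baselineLogmeanRange = "numeric",
    dispersionA0 = "numeric",
    dispersionA1 = "numeric",
    libsizeLognormalSd = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
    if (any(object@nColoniesPerStock < 1L))
        msg <- c(msg, "nColoniesPerStock entries must be >= 1")
    if (object@cagesPerColonyPerDiet < 1L)
        msg <- c(msg, "cagesPerColonyPerDiet must be >= 1")
    if (length(object@stocks) < 1L || anyDuplicated(object@stocks))
        msg <- c(msg, "stocks must be distinct labels")
    if (sum(object@diets == "sugar") != 1L)
        msg <- c(msg, "diets must include exactly one reference level 'sugar'")
    if (object@fracLncRNA <= 0 || object@fracLncRNA >= 1)
        msg <- c(msg, "fracLncRNA must lie in (0, 1)")
    nprog <- object@nDietProgram + object@nStockProgram + object@nViral
    if (nprog > object@nGenes)
        msg <- c(msg, "program sizes plus viral features exceed nGenes")
    if (object@nWeightProgram + object@nViral > object@nGenes)
        msg <- c(msg, "weight program plus viral features exceed nGenes")
    if (object@dispersionA0 <= 0) msg <- c(msg, "dispersionA0 must be > 0")
    if (object@dispersionA1 < 0) msg <- c(msg, "dispersionA1 must be >= 0")
    if (length(object@baselineLogmeanRange) != 2L ||
        diff(object@baselineLogmeanRange) <= 0)
        msg <- c(msg, "baselineLogmeanRange must be an increasing pair")
    if (object@weightNoiseSd < 0) msg <- c(msg, "weightNoiseSd must be >= 0")
    if (object@lncRNABias <= 0) msg <- c(msg, "lncRNABias must be > 0")
    if (length(msg)) msg else TRUE
})

#' Cage-level RNA-seq experiment container
#'
#' Thin \linkS4class{SummarizedExperiment} subclass holding the integer
#' count matrix (assay \code{"counts"}), per-gene biotype annotation in
#' \code{rowData} and the cage factors (stock, diet, colony, weight_mg)
#' in \code{colData}. Simulated datasets additionally carry the planted
#' ground truth in \code{metadata(x)$truth}.
#'
#' @export
setClass("NutriSet", contains = "SummarizedExperiment")

setValidity("NutriSet", function(object) {
    msg <- character()
    if (!"counts" %in% names(assays(object)))
        return("assay 'counts' is required")
    k <- assay(object, "counts")
    if (anyNA(k)) msg <- c(msg, "counts must not contain missing values")
    else {
        if (any(k < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(k != round(k))) msg <- c(msg, "counts must be integral")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (!"biotype" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain a 'biotype' column")
    else if (!all(rowData(object)$biotype %in% .BIOTYPES))
        msg <- c(msg, sprintf("biotype values must be one of: %s",
                              paste(.BIOTYPES, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Parametric dispersion-mean trend
#'
#' Coefficients of the negative-binomial dispersion trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu} fitted across genes; \code{a0} is the
#' asymptotic dispersion and \code{a1} the extra-Poisson low-count term.
#' Feeds the closed-form variance-stabilizing transformation.
#'
#' @slot a0,a1 trend coefficients (\code{a0 > 0}, \code{a1 >= 0}).
#' @export
setClass("DispersionTrend", representation(a0 = "numeric", a1 = "numeric"))

setValidity("DispersionTrend", function(object) {
    msg <- character()
    if (length(object@a0) != 1L || object@a0 <= 0)
        msg <- c(msg, "a0 must be a single value > 0")
    if (length(object@a1) != 1L || object@a1 < 0)
        msg <- c(msg, "a1 must be a single value >= 0")
    if (length(msg)) msg else TRUE
})

#' Per-gene weighted least-squares fits
#'
#' Results of gene-wise weighted linear models: coefficient estimates,
#' residual SDs and degrees of freedom, and the full unscaled coefficient
#' covariance \eqn{(X'WX)^{-1}} per gene (weights differ by gene, so the
#' covariance cannot be shared). After \code{\link{applyContrasts}} the
#' coefficients are contrast estimates and \code{covUnscaled} their exact
#' unscaled variances \eqn{c'Vc}.
#'
#' @slot coefficients genes x coefficients matrix (log2 scale).
#' @slot stdevUnscaled genes x coefficients matrix of \eqn{\sqrt{v}}.
#' @slot sigma per-gene residual SD.
#' @slot df per-gene residual degrees of freedom.
#' @slot covArray p x p x genes array of unscaled covariances (empty after
#'   reparameterization to contrasts).
#' @slot design the design matrix used for fitting.
#' @export
setClass("GeneFitSet", representation(
    coefficients = "matrix",
    stdevUnscaled = "matrix",
    sigma = "numeric",
    df = "numeric",
    covArray = "array",
    design = "matrix"
))

setValidity("GeneFitSet", function(object) {
    msg <- character()
    if (!identical(dim(object@coefficients), dim(object@stdevUnscaled)))
        msg <- c(msg, "coefficients and stdevUnscaled must share dimensions")
    if (length(object@sigma) != nrow(object@coefficients))
        msg <- c(msg, "sigma length must equal number of genes")
    if (any(object@df <= 0)) msg <- c(msg, "residual df must be > 0")
    if (any(object@sigma < 0)) msg <- c(msg, "sigma must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Empirical-Bayes variance prior
#'
#' The scaled inverse-chi-square prior on gene-wise residual variances
#' estimated by moment matching: \code{d0} prior degrees of freedom
#' (\code{Inf} when the observed variances show no excess spread) and
#' \code{s0sq} prior variance.
#'
#' @slot d0 prior degrees of freedom, \code{> 0} (possibly \code{Inf}).
#' @slot s0sq prior variance, \code{> 0}.
#' @export
setClass("ModerationPrior", representation(d0 = "numeric", s0sq = "numeric"))

setValidity("ModerationPrior", function(object) {
    msg <- character()
    if (!(length(object@d0) == 1L && object@d0 > 0))
        msg <- c(msg, "d0 must be a single value > 0")
    if (!(length(object@s0sq) == 1L && object@s0sq > 0 &&
          is.finite(object@s0sq)))
        msg <- c(msg, "s0sq must be a single finite value > 0")
    if (length(msg)) msg else TRUE
})

#' A named set of differentially expressed genes
#'
#' @slot name set label.
#' @slot genes character vector of unique gene ids.
#' @slot directions optional named integer vector of signs (+1/-1) for a
#'   subset of \code{genes}.
#' @export
setClass("DEGSet", representation(
    name = "character",
    genes = "character",
    directions = "integer"
))

setValidity("DEGSet", function(object) {
    msg <- character()
    if (anyDuplicated(object@genes)) msg <- c(msg, "gene ids must be unique")
    if (length(object@directions) &&
        !all(names(object@directions) %in% object@genes))
        msg <- c(msg, "directions' names must be a subset of genes")
    if (length(object@directions) &&
        !all(object@directions %in% c(-1L, 1L)))
        msg <- c(msg, "directions must be +1 or -1")
    if (length(msg)) msg else TRUE
})

#' Random-forest recursive feature elimination trace
#'
#' One row per elimination round: surviving feature count, tuned
#' \code{mtry}, out-of-bag RMSE and R-squared. Feature sets are strictly
#' nested across rounds; the optimum is the round minimizing OOB RMSE
#' (ties broken toward the smaller set).
#'
#' @slot rounds data.frame with columns n_features, mtry, oob_rmse, oob_r2.
#' @slot featureSets list of character vectors, one per round.
#' @slot optimumRound index of the OOB-RMSE-optimal round.
#' @export
setClass("RFETrace", representation(
    rounds = "data.frame",
    featureSets = "list",
    optimumRound = "integer"
))

setValidity("RFETrace", function(object) {
    msg <- character()
    if (nrow(object@rounds) != length(object@featureSets))
        msg <- c(msg, "rounds and featureSets must have equal length")
    ns <- vapply(object@featureSets, length, 1L)
    if (nrow(object@rounds) && !identical(ns, object@rounds$n_features))
        msg <- c(msg, "n_features must match featureSets lengths")
    if (length(ns) > 1L) {
        nested <- all(vapply(seq_len(length(ns) - 1L), function(i) {
            all(object@featureSets[[i + 1L]] %in% object@featureSets[[i]]) &&
                ns[i + 1L] < ns[i]
        }, TRUE))
        if (!nested) msg <- c(msg, "feature sets must be strictly nested")
    }
    if (nrow(object@rounds)) {
        if (object@optimumRound < 1L ||
            object@optimumRound > nrow(object@rounds))
            msg <- c(msg, "optimumRound out of range")
    }
    if (length(msg)) msg else TRUE
})

#' SVM-RFE external cross-validation trace
#'
#' Misclassification error of a linear SVM restricted to the top-k ranked
#' features, for each k on a grid, scored by stratified external
#' cross-validation in which ranking and standardization are recomputed
#' within every training fold. Also carries the full-data feature ranking
#' used to report the final feature list.
#'
#' @slot kGrid feature counts evaluated.
#' @slot cvErrorMean,cvErrorSd mean and SD of fold error at each k.
#' @slot ranking full-data feature ranking, best first.
#' @slot folds integer fold assignment per sample.
#' @export
setClass("SVMTrace", representation(
    kGrid = "integer",
    cvErrorMean = "numeric",
    cvErrorSd = "numeric",
    ranking = "character",
    folds = "integer"
))

setValidity("SVMTrace", function(object) {
    msg <- character()
    if (length(object@kGrid) != length(object@cvErrorMean) ||
        length(object@kGrid) != length(object@cvErrorSd))
        msg <- c(msg, "kGrid, cvErrorMean and cvErrorSd lengths must agree")
    if (length(object@cvErrorMean) &&
        (any(object@cvErrorMean < 0) || any(object@cvErrorMean > 1)))
        msg <- c(msg, "cv errors must lie in [0, 1]")
    if (anyDuplicated(object@ranking))
        msg <- c(msg, "ranking must not repeat features")
    if (length(msg)) msg else TRUE
})

#' Biotype enrichment result
#'
#' 2x2 contingency (in target set or not x of the biotype or not) with
#' the chi-square statistic (1 df, no continuity correction by default),
#' its p-value, the enrichment direction, and a Fisher exact p-value when
#' an expected cell falls below 1.
#'
#' @slot table 2x2 integer contingency table.
#' @slot chi2,p chi-square statistic and p-value.
#' @slot direction "enriched" or "depleted".
#' @slot fisherP Fisher exact p-value (NA unless computed).
#' @export
setClass("EnrichmentResult", representation(
    table = "matrix",
    chi2 = "numeric",
    p = "numeric",
    direction = "character",
    fisherP = "numeric"
))
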