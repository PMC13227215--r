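#' @include AllClasses.R
NULL

#' Gene biotype annotation
#'
#' @param x a \linkS4class{NutriSet}.
#' @return character vector of biotypes, named by gene id.
#' @export
setGeneric("biotype", function(x) standardGeneric("biotype"))

#' @rdname biotype
#' @export
setMethod("biotype", "NutriSet", function(x) {
    setNames(as.character(rowData(x)$biotype), rownames(x))
})

#' Planted ground truth of a simulated dataset
#'
#' @param x a \linkS4class{NutriSet} produced by
#'   \code{\link{simulateExperiment}}.
#' @return list with elements \code{diet_program}, \code{stock_program},
#'   \code{weight_program}, \code{lncRNA_ids}, \code{viral_ids},
#'   \code{latent_score_per_cage}, \code{true_weights_mg}; \code{NULL} for
#'   datasets read from files without truth.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "NutriSet", function(x) metadata(x)$truth)

#' Per-cage body-weight response (mg per bee)
#'
#' @param x a \linkS4class{NutriSet}.
#' @return numeric vector named by sample id.
#' @export
setGeneric("sampleWeights", function(x) standardGeneric("sampleWeights"))

#' @rdname sampleWeights
#' @export
setMethod("sampleWeights", "NutriSet", function(x) {
    setNames(colData(x)$weight_mg, colnames(x))
})

#' Dispersion trend coefficients
#'
#' @param x a \linkS4class{DispersionTrend}.
#' @return named numeric vector \code{c(a0 = , a1 = )}.
#' @export
setGeneric("trendCoefs", function(x) standardGeneric("trendCoefs"))

#' @rdname trendCoefs
#' @export
setMethod("trendCoefs", "DispersionTrend", function(x) c(a0 = x@a0, a1 = x@a1))

#' Gene ids of a DEG set
#'
#' @param x a \linkS4class{DEGSet}.
#' @return character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "DEGSet", function(x) x@genes)

#' @describeIn geneIds number of genes in the set.
#' @export
setMethod("length", "DEGSet", function(x) length(x@genes))

#' Feature set of the OOB-RMSE-optimal elimination round
#'
#' @param x an \linkS4class{RFETrace}.
#' @return character vector of surviving feature ids.
#' @export
setGeneric("optimumFeatures", function(x) standardGeneric("optimumFeatures"))

#' @rdname optimumFeatures
#' @export
setMethod("optimumFeatures", "RFETrace", function(x) {
    x@featureSets[[x@optimumRound]]
})

#' Elimination rounds of an RFE trace
#'
#' @param x an \linkS4class{RFETrace}.
#' @return data.frame with one row per round.
#' @export
setGeneric("rfeRounds", function(x) standardGeneric("rfeRounds"))

#' @rdname rfeRounds
#' @export
setMethod("rfeRounds", "RFETrace", function(x) x@rounds)

#' Full-data feature ranking of an SVM-RFE trace
#'
#' @param x an \linkS4class{SVMTrace}.
#' @return character vector of features, most discriminative first.
#' @export
setGeneric("featureRanking", function(x) standardGeneric("featureRanking"))

#' @rdname featureRanking
#' @export
setMethod("featureRanking", "SVMTrace", function(x) x@ranking)

setMethod("show", "SimConfig", function(object) {
    n <- sum(object@nColoniesPerStock * object@cagesPerColonyPerDiet *
                 length(object@diets))
    cat("SimConfig:", object@nGenes, "genes,", n, "cage libraries\n")
    cat("  stocks:", paste(object@stocks, collapse = ", "),
        "| diets:", paste(object@diets, collapse = ", "), "\n")
    cat("  programs: diet", object@nDietProgram,
        "(lfc", paste0(object@dietLfc, ")"),
        "stock", object@nStockProgram,
        "(lfc", paste0(object@stockLfc, ")"),
        "weight", object@nWeightProgram, "\n")
    cat("  dispersion trend: a0 =", object@dispersionA0,
        ", a1 =", object@dispersionA1, "| seed:", object@seed, "\n")
})

setMethod("show", "NutriSet", function(object) {
    cat("NutriSet:", nrow(object), "genes x", ncol(object), "samples\n")
    bt <- table(rowData(object)$biotype)
    cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
    if (!is.null(metadata(object)$truth))
        cat("  simulated dataset with planted ground truth\n")
    callNextMethod()
})

setMethod("show", "DispersionTrend", function(object) {
    cat(sprintf("DispersionTrend: alpha(mu) = %.4g + %.4g/mu\n",
                object@a0, object@a1))
})

setMethod("show", "GeneFitSet", function(object) {
    cat("GeneFitSet:", nrow(object@coefficients), "genes,",
        ncol(object@coefficients), "coefficients\n")
    cat("  coefficients:",
        paste(colnames(object@coefficients), collapse = ", "), "\n")
})

setMethod("show", "ModerationPrior", function(object) {
    cat(sprintf("ModerationPrior: d0 = %s, s0^2 = %.4g\n",
                format(object@d0), object@s0sq))
})

setMethod("show", "DEGSet", function(object) {
    cat("DEGSet '", object@name, "': ", length(object@genes), " genes",
        sep = "")
    if (length(object@directions))
        cat(" (", sum(object@directions > 0), " up, ",
            sum(object@directions < 0), " down)", sep = "")
    cat("\n")
})

setMethod("show", "RFETrace", function(object) {
    cat("RFETrace:", nrow(object@rounds), "rounds; optimum at round",
        object@optimumRound, "with",
        object@rounds$n_features[object@optimumRound], "features (OOB RMSE",
        paste0(signif(object@rounds$oob_rmse[object@optimumRound], 4),
               ")\n"))
})

setMethod("show", "SVMTrace", function(object) {
    cat("SVMTrace:", length(object@ranking), "features ranked;",
        length(object@kGrid), "k values scored by",
        max(object@folds), "fold external CV\n")
})

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf("EnrichmentResult: chi2 = %.3f, p = %.3g (%s)\n",
                object@chi2, object@p, object@direction))
    print(object@table)
})
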