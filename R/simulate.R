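#' @include AllClasses.R
NULL

#' Construct a simulation configuration
#'
#' Defaults emulate the cage design of the target study: 2 stocks
#' (Pol-line, Russian) x 4 diets (sugar reference, pollen, Chlorella,
#' spirulina), with 4 and 3 source colonies respectively and 4 replicate
#' cages per colony x diet cell — 112 cage-level libraries in total.
#' 12,000 transcripts are simulated with baseline abundances spread over
#' roughly three orders of magnitude so that the 50-read filter leaves
#' about 11,000 transcripts, a large diet program, a smaller
#' lncRNA-enriched stock program, viral features depressed in the second
#' stock, and a weight program whose expression tracks a latent nutrition
#' score that linearly drives cage dry mass.
#'
#' @param nGenes number of transcripts.
#' @param nColoniesPerStock integer vector of source colonies per stock.
#' @param cagesPerColonyPerDiet replicate cages per colony x diet.
#' @param stocks,diets level labels; \code{diets} must contain "sugar".
#' @param fracLncRNA proportion of genes annotated lncRNA.
#' @param nViral number of viral features.
#' @param nDietProgram,dietLfc protein/lipid diet program size and log2
#'   effect.
#' @param nStockProgram,stockLfc stock program size and log2 effect.
#' @param lncRNABias odds multiplier for lncRNA membership in the stock
#'   program.
#' @param nWeightProgram weight program size.
#' @param weightBeta mg per unit latent nutrition score.
#' @param weightBaseMg baseline per-bee head+thorax dry mass, mg.
#' @param weightNoiseSd residual SD of cage weight, mg.
#' @param colonySd SD of colony random intercepts, log2 units.
#' @param viralStockLfc log2 shift of viral features in the second stock.
#' @param baselineLogmeanRange log2 range of baseline mean counts.
#' @param dispersionA0,dispersionA1 NB dispersion trend coefficients.
#' @param libsizeLognormalSd SD of log-normal library size factors.
#' @param seed integer seed.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nGenes = 500, seed = 1)
#' cfg
#' @export
simConfig <- function(nGenes = 12000,
                      nColoniesPerStock = c(4, 3),
                      cagesPerColonyPerDiet = 4,
                      stocks = c("pol_line", "russian"),
                      diets = c("sugar", "pollen", "chlorella", "spirulina"),
                      fracLncRNA = 0.08,
                      nViral = 5,
                      nDietProgram = 2000,
                      dietLfc = 1.0,
                      nStockProgram = 300,
                      stockLfc = 1.0,
                      lncRNABias = 3,
                      nWeightProgram = 100,
                      weightBeta = 1.5,
                      weightBaseMg = 12,
                      weightNoiseSd = 0.5,
                      colonySd = 0.15,
                      viralStockLfc = -2,
                      baselineLogmeanRange = c(-2, 9),
                      dispersionA0 = 0.05,
                      dispersionA1 = 2,
                      libsizeLognormalSd = 0.3,
                      seed = 1) {
    nprog <- as.integer(c(nDietProgram, nStockProgram, nWeightProgram,
                          nViral))
    if (sum(nprog[c(1, 2, 4)]) > nGenes || sum(nprog[c(3, 4)]) > nGenes)
        stop("program sizes exceed nGenes: reduce nDietProgram/",
             "nStockProgram/nWeightProgram/nViral or raise nGenes",
             call. = FALSE)
    new("SimConfig",
        nGenes = as.integer(nGenes),
        nColoniesPerStock = rep_len(as.integer(nColoniesPerStock),
                                    length(stocks)),
        cagesPerColonyPerDiet = as.integer(cagesPerColonyPerDiet),
        stocks = stocks, diets = diets,
        fracLncRNA = fracLncRNA, nViral = as.integer(nViral),
        nDietProgram = as.integer(nDietProgram), dietLfc = dietLfc,
        nStockProgram = as.integer(nStockProgram), stockLfc = stockLfc,
        lncRNABias = lncRNABias,
        nWeightProgram = as.integer(nWeightProgram),
        weightBeta = weightBeta, weightBaseMg = weightBaseMg,
        weightNoiseSd = weightNoiseSd, colonySd = colonySd,
        viralStockLfc = viralStockLfc,
        baselineLogmeanRange = as.numeric(baselineLogmeanRange),
        dispersionA0 = dispersionA0, dispersionA1 = dispersionA1,
        libsizeLognormalSd = libsizeLognormalSd,
        seed = as.integer(seed))
}

#' Construct a NutriSet from components
#'
#' @param counts integer gene x sample matrix with dimnames.
#' @param samples data.frame / DataFrame of per-cage factors, rows aligned
#'   with count columns (columns typically \code{stock}, \code{diet},
#'   \code{colony}, \code{weight_mg}).
#' @param biotype per-gene biotype, one of protein_coding, lncRNA, viral,
#'   other. Defaults to "other".
#' @param truth optional planted ground-truth list (simulated data).
#' @return a validated \linkS4class{NutriSet}.
#' @export
NutriSet <- function(counts, samples = NULL, biotype = NULL, truth = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(biotype)) biotype <- rep("other", nrow(counts))
    if (is.null(samples))
        samples <- DataFrame(row.names = colnames(counts))
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(biotype = as.character(biotype)),
        colData = as(samples, "DataFrame"))
    out <- new("NutriSet", se)
    if (!is.null(truth)) metadata(out)$truth <- truth
    validObject(out)
    out
}

#' Simulate a cage-design nutritranscriptomics experiment
#'
#' Draws counts \eqn{K_{gi} \sim NB(s_i \mu_{gi}, \alpha(\mu_{gi}))} with
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu} and
#' \deqn{\log_2 \mu_{gi} = b_g + \Delta_{diet} + \Delta_{stock} +
#'   u_{colony(i)} + z_i \gamma_g,}
#' where the diet effect applies to diet-program genes in any
#' protein/lipid (non-sugar) diet, the stock effect to stock-program
#' genes in the second stock, \eqn{u} is a gene-specific random intercept
#' of the source colony,
#' and \eqn{z_i} is a latent per-cage nutrition score (Normal(0, 1) under
#' sugar, Normal(1, 1) under protein/lipid diets) that also drives the
#' response \eqn{weight_i = w_0 + \beta z_i + \epsilon_i}. Viral features
#' receive a stock-specific log2 shift; lncRNAs are upweighted by
#' \code{lncRNABias} when the stock program is sampled. The per-gene
#' weight loadings \eqn{\gamma_g} are drawn uniformly from (0.4, 0.8)
#' log2 units per unit score, planting biomarker-grade effects whose
#' per-gene correlations with the weight response are strong enough to
#' be recoverable by feature selection and correlation triage. Program
#' genes are sampled from transcripts above a detectability floor
#' (baseline log2 mean of 3, about 8 counts per library): an effect
#' planted in an unexpressed transcript would be unmeasurable by design.
#'
#' Everything — memberships, effects, counts, weights — is reproducible
#' from \code{config@seed} alone.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{NutriSet} whose \code{metadata(x)$truth} records
#'   the planted program memberships, latent scores and noiseless weights.
#' @examples
#' sim <- simulateExperiment(simConfig(nGenes = 300, nDietProgram = 40,
#'                                     nStockProgram = 20,
#'                                     nWeightProgram = 10, seed = 7))
#' sim
#' @export
simulateExperiment <- function(config) {
    validObject(config)
    set.seed(config@seed)
    G <- config@nGenes
    geneIds <- sprintf("gene%05d", seq_len(G))

    ## --- sample sheet: stock / colony / diet / cage ---
    sheets <- lapply(seq_along(config@stocks), function(si) {
        stock <- config@stocks[si]
        colonies <- sprintf("%s_colony%d", stock,
                            seq_len(config@nColoniesPerStock[si]))
        expand.grid(cage = seq_len(config@cagesPerColonyPerDiet),
                    diet = config@diets, colony = colonies,
                    stock = stock, stringsAsFactors = FALSE)
    })
    samples <- do.call(rbind, sheets)
    n <- nrow(samples)
    samples$sample_id <- sprintf("cage%03d", seq_len(n))
    rownames(samples) <- samples$sample_id

    ## --- biotypes: viral rows first, then lncRNA fraction of the rest ---
    biotype <- rep("protein_coding", G)
    viralIdx <- if (config@nViral > 0) seq_len(config@nViral) else integer()
    biotype[viralIdx] <- "viral"
    nonViral <- setdiff(seq_len(G), viralIdx)
    nLnc <- round(config@fracLncRNA * length(nonViral))
    lncIdx <- sample(nonViral, nLnc)
    biotype[lncIdx] <- "lncRNA"

    ## --- per-gene baseline abundance (log2 mean counts) ---
    baseline <- runif(G, config@baselineLogmeanRange[1],
                      config@baselineLogmeanRange[2])

    ## --- planted programs: never viral, and only in transcripts above a
    ## detectability floor (log2 mean >= 3, ~8 counts/sample) — an effect
    ## planted in an unexpressed transcript is unmeasurable by design ---
    floorLog2 <- min(3, config@baselineLogmeanRange[2] - 0.5)
    eligible <- nonViral[baseline[nonViral] >= floorLog2]
    if (length(eligible) <
        max(config@nDietProgram + config@nStockProgram,
            config@nWeightProgram)) {
        warning("few transcripts above the expression floor; sampling ",
                "programs from all non-viral genes", call. = FALSE)
        eligible <- nonViral
    }
    dietProg <- sort(sample(eligible, config@nDietProgram))
    stockPool <- setdiff(eligible, dietProg)
    w <- ifelse(biotype[stockPool] == "lncRNA", config@lncRNABias, 1)
    stockProg <- sort(sample(stockPool, config@nStockProgram, prob = w))
    weightProg <- sort(sample(eligible, config@nWeightProgram))

    ## gene-specific colony intercepts: a global shift would be absorbed
    ## by depth normalization and blocking could never matter downstream
    colonies <- unique(samples$colony)
    colonyOffset <- matrix(rnorm(G * length(colonies), 0, config@colonySd),
                           G, length(colonies),
                           dimnames = list(NULL, colonies))

    ## --- latent nutrition score and weight response ---
    isPL <- samples$diet != "sugar"
    z <- rnorm(n, mean = ifelse(isPL, 1, 0), sd = 1)
    trueW <- config@weightBaseMg + config@weightBeta * z
    weight <- trueW + rnorm(n, 0, config@weightNoiseSd)

    ## biomarker-grade loadings: per-gene correlations with weight land
    ## in the range a correlation-triage panel is meant to capture
    gamma <- numeric(G)
    gamma[weightProg] <- runif(config@nWeightProgram, 0.4, 0.8)

    ## --- log2 mean model ---
    log2mu <- matrix(baseline, G, n)
    secondStock <- samples$stock == config@stocks[min(2, length(config@stocks))]
    log2mu[dietProg, isPL] <- log2mu[dietProg, isPL] + config@dietLfc
    log2mu[stockProg, secondStock] <-
        log2mu[stockProg, secondStock] + config@stockLfc
    if (length(viralIdx))
        log2mu[viralIdx, secondStock] <-
            log2mu[viralIdx, secondStock] + config@viralStockLfc
    log2mu <- log2mu + colonyOffset[, samples$colony]
    log2mu <- log2mu + outer(gamma, z)

    mu <- 2^log2mu
    s <- exp(rnorm(n, 0, config@libsizeLognormalSd))
    s <- s / exp(mean(log(s)))
    alpha <- config@dispersionA0 + config@dispersionA1 / mu
    m <- sweep(mu, 2, s, `*`)
    counts <- matrix(rnbinom(G * n, mu = m, size = 1 / alpha), G, n,
                     dimnames = list(geneIds, samples$sample_id))

    truth <- list(
        diet_program = geneIds[dietProg],
        stock_program = geneIds[stockProg],
        weight_program = geneIds[weightProg],
        lncRNA_ids = geneIds[lncIdx],
        viral_ids = geneIds[viralIdx],
        latent_score_per_cage = setNames(z, samples$sample_id),
        true_weights_mg = setNames(trueW, samples$sample_id),
        size_factors = setNames(s, samples$sample_id))

    NutriSet(counts,
             samples = samples[, c("stock", "diet", "colony", "cage")] |>
                 cbind(weight_mg = weight),
             biotype = biotype, truth = truth)
}
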