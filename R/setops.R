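#' @include AllClasses.R
NULL

#' Core DEG set: genes differential in every input set
#'
#' @param degsets list of two or more \linkS4class{DEGSet}s (e.g. one per
#'   protein/lipid diet within a stock).
#' @return a \linkS4class{DEGSet} named by concatenating the inputs;
#'   empty intersections are allowed.
#' @export
intersectCore <- function(degsets) {
    stopifnot(length(degsets) >= 2,
              all(vapply(degsets, is, TRUE, "DEGSet")))
    genes <- Reduce(intersect, lapply(degsets, geneIds))
    new("DEGSet",
        name = paste(vapply(degsets, function(d) d@name, ""),
                     collapse = " & "),
        genes = genes, directions = integer(0))
}

#' Two-set Venn accounting
#'
#' @param A,B \linkS4class{DEGSet}s or character vectors of gene ids.
#' @return named integer vector: \code{only_A}, \code{only_B},
#'   \code{shared}, \code{union} (\code{union = |A| + |B| - shared}).
#' @export
vennCounts2 <- function(A, B) {
    a <- if (is(A, "DEGSet")) geneIds(A) else unique(as.character(A))
    b <- if (is(B, "DEGSet")) geneIds(B) else unique(as.character(B))
    shared <- length(intersect(a, b))
    c(only_A = length(a) - shared, only_B = length(b) - shared,
      shared = shared, union = length(a) + length(b) - shared)
}

#' Biotype enrichment of a DEG set by chi-square
#'
#' Tests whether a biotype (e.g. lncRNA) is over-represented in a target
#' gene set relative to a background universe, via the 2x2 chi-square
#' with 1 df (no continuity correction by default, matching the reported
#' statistic style). When any expected cell is below 1 a warning is
#' issued and a Fisher exact p-value is reported alongside.
#'
#' @param target a \linkS4class{DEGSet} or character vector of gene ids,
#'   a subset of \code{names(background)}.
#' @param background named character vector: biotype per gene for the
#'   whole (post-filter) universe.
#' @param biotypeLabel biotype tested (default \code{"lncRNA"}).
#' @param correct apply Yates continuity correction (default FALSE).
#' @return an \linkS4class{EnrichmentResult}.
#' @export
biotypeEnrichment <- function(target, background, biotypeLabel = "lncRNA",
                              correct = FALSE) {
    tg <- if (is(target, "DEGSet")) geneIds(target)
          else unique(as.character(target))
    if (!all(tg %in% names(background)))
        stop("target genes missing from the background universe",
             call. = FALSE)
    isBio <- background == biotypeLabel
    if (!any(isBio) || all(isBio))
        stop("background must contain both biotype classes", call. = FALSE)
    inSet <- names(background) %in% tg
    tab <- table(inSet = factor(inSet, c(TRUE, FALSE)),
                 biotype = factor(isBio, c(TRUE, FALSE)))
    tab <- matrix(as.integer(tab), 2, 2,
                  dimnames = list(set = c("in_set", "background_only"),
                                  biotype = c(biotypeLabel, "other")))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    fisherP <- NA_real_
    if (any(expected < 1)) {
        warning("expected cell below 1; reporting Fisher exact p as well",
                call. = FALSE)
        fisherP <- stats::fisher.test(tab)$p.value
    }
    direction <- if (tab[1, 1] >= expected[1, 1]) "enriched" else "depleted"
    new("EnrichmentResult", table = tab,
        chi2 = unname(chi$statistic), p = unname(chi$p.value),
        direction = direction, fisherP = fisherP)
}
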