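#' @include AllClasses.R
NULL

#' Write a dataset to plain-text fixture files
#'
#' Emits four files into \code{directory}: \code{counts.tsv}
#' (featureCounts-style: a gene-id column followed by one integer column
#' per sample), \code{samples.csv}, \code{annotation.tsv} (gene id,
#' biotype) and, when ground truth is present, \code{truth.json}. The
#' files round-trip losslessly through \code{\link{readCounts}} /
#' \code{\link{readSamples}} / \code{\link{readFixture}}.
#'
#' @param dataset a \linkS4class{NutriSet}.
#' @param directory output directory (created if missing).
#' @return invisibly, the named vector of file paths written.
#' @export
writeFixture <- function(dataset, directory) {
    stopifnot(is(dataset, "NutriSet"))
    if (nrow(dataset) == 0L)
        stop("refusing to write an empty gene set", call. = FALSE)
    dir.create(directory, showWarnings = FALSE, recursive = TRUE)
    paths <- c(counts = file.path(directory, "counts.tsv"),
               samples = file.path(directory, "samples.csv"),
               annotation = file.path(directory, "annotation.tsv"))

    k <- as.data.frame(assay(dataset, "counts"))
    utils::write.table(cbind(Geneid = rownames(dataset), k),
                       paths["counts"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    sm <- as.data.frame(colData(dataset))
    utils::write.csv(cbind(sample_id = colnames(dataset), sm),
                     paths["samples"], quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(gene_id = rownames(dataset),
                   biotype = rowData(dataset)$biotype),
        paths["annotation"], sep = "\t", quote = FALSE, row.names = FALSE)

    truth <- metadata(dataset)$truth
    if (!is.null(truth)) {
        paths <- c(paths, truth = file.path(directory, "truth.json"))
        jsonlite::write_json(truth, paths["truth"], auto_unbox = FALSE,
                             digits = NA)
    }
    invisible(paths)
}

#' Read a count matrix with biotype annotation
#'
#' Accepts either a bare matrix layout (gene-id column + one integer
#' column per sample) or the featureCounts 7-column dialect
#' (Geneid/Chr/Start/End/Strand/Length followed by samples), whose
#' positional columns are dropped. Non-integer cells and duplicate gene
#' ids are rejected.
#'
#' @param tsv path to the tab-delimited count file.
#' @param annotation optional path to a two-column (gene_id, biotype)
#'   TSV; unannotated genes default to biotype "other".
#' @return a \linkS4class{NutriSet} (no sample metadata attached).
#' @export
readCounts <- function(tsv, annotation = NULL) {
    d <- utils::read.delim(tsv, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(d) < 2L)
        stop("count file needs a gene-id column and at least one sample",
             call. = FALSE)
    fcCols <- c("Chr", "Start", "End", "Strand", "Length")
    drop <- intersect(fcCols, colnames(d))
    if (length(drop)) d <- d[, setdiff(colnames(d), drop), drop = FALSE]
    ids <- as.character(d[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate gene ids in ", tsv, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "),
             call. = FALSE)
    k <- as.matrix(d[, -1L, drop = FALSE])
    if (!is.numeric(k) || anyNA(k))
        stop("non-numeric or missing count cells in ", tsv, call. = FALSE)
    bad <- which(k != round(k), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-integer count at gene '%s', sample '%s'",
                     ids[bad[1, 1]], colnames(k)[bad[1, 2]]),
             call. = FALSE)
    rownames(k) <- ids

    biotype <- rep("other", length(ids))
    if (!is.null(annotation)) {
        a <- utils::read.delim(annotation, stringsAsFactors = FALSE)
        m <- match(ids, a[[1L]])
        biotype[!is.na(m)] <- a[[2L]][m[!is.na(m)]]
    }
    NutriSet(k, biotype = biotype)
}

#' Read a sample metadata table
#'
#' @param csv path to a CSV with a \code{sample_id} column plus cage
#'   factors (stock, diet, colony, weight_mg, ...).
#' @return data.frame with sample ids as row names.
#' @export
readSamples <- function(csv) {
    s <- utils::read.csv(csv, stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(s))
        stop("samples file must contain a sample_id column", call. = FALSE)
    rownames(s) <- s$sample_id
    s[, setdiff(colnames(s), "sample_id"), drop = FALSE]
}

#' Read a full fixture directory back into a NutriSet
#'
#' @param directory a directory written by \code{\link{writeFixture}}.
#' @return a \linkS4class{NutriSet} with sample metadata, biotypes and
#'   (if present) ground truth reattached.
#' @export
readFixture <- function(directory) {
    x <- readCounts(file.path(directory, "counts.tsv"),
                    file.path(directory, "annotation.tsv"))
    samples <- readSamples(file.path(directory, "samples.csv"))
    samples <- samples[colnames(x), , drop = FALSE]
    truthPath <- file.path(directory, "truth.json")
    truth <- NULL
    if (file.exists(truthPath)) {
        truth <- jsonlite::read_json(truthPath, simplifyVector = TRUE)
        for (nm in c("latent_score_per_cage", "true_weights_mg",
                     "size_factors"))
            if (!is.null(truth[[nm]]))
                truth[[nm]] <- setNames(as.numeric(truth[[nm]]), colnames(x))
    }
    NutriSet(assay(x, "counts"), samples = samples, biotype = biotype(x),
             truth = truth)
}
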