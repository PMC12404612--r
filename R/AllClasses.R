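#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Container for a single-worm expression experiment
#'
#' `WormExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]:
#' the `"counts"` assay holds raw per-gene, per-worm read counts, `colData`
#' holds the per-worm phenotype/design table (biological replicate, binarized
#' parental age and early-life temperature, egg-laying onset, early brood),
#' and `rowData` optionally carries per-gene chromatin-domain/tissue
#' annotation.  A `"cpm"` assay is added by [cpmNormalize()].
#'
#' @slot .realized library sizes are stored in `metadata()$library_sizes`
#'   and are always the column sums of the counts assay.
#'
#' @seealso [WormExperiment()] for construction, [cpmNormalize()],
#'   [simulateStudy()].
#' @export
setClass("WormExperiment", contains = "SummarizedExperiment")

setValidity("WormExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "a 'counts' assay is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(cts)) || any(cts < 0))
            msg <- c(msg, "counts must be finite and non-negative")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"replicate" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'replicate' column")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "worm ids (colnames) must be unique")
    for (v in intersect(c("parental_age", "early_temp"), colnames(cd))) {
        x <- cd[[v]]
        if (!all(is.na(x) | x %in% c(0, 1)))
            msg <- c(msg, sprintf("'%s' must be binarized to 0/1", v))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a WormExperiment
#'
#' @param counts numeric matrix of raw counts, genes in rows, worms in
#'   columns.  Column names must match `phenotype$worm_id`.
#' @param phenotype data.frame with at least `worm_id` and `replicate`;
#'   typically also `parental_age`, `early_temp` (both 0/1), `elo_hours`
#'   and `early_brood`.
#' @param annotation optional per-gene data.frame with columns `gene`,
#'   `domain` (active/regulated/other) and `tissue` (soma/germline/other);
#'   matched into `rowData` by gene id.
#' @param truth optional ground-truth list from the simulator, kept in
#'   `metadata()$truth`.
#' @return a [WormExperiment-class] object.
#' @examples
#' cts <- matrix(rpois(20, 50), 4, 5,
#'               dimnames = list(paste0("g", 1:4), paste0("w", 1:5)))
#' ph <- data.frame(worm_id = paste0("w", 1:5), replicate = c(1, 1, 2, 2, 2))
#' we <- WormExperiment(cts, ph)
#' @export
WormExperiment <- function(counts, phenotype, annotation = NULL, truth = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("gene_%04d", seq_len(nrow(counts)))
    if (!"worm_id" %in% colnames(phenotype))
        stop("phenotype must contain a 'worm_id' column")
    if (anyDuplicated(phenotype$worm_id))
        stop("phenotype worm_id values must be unique")
    if (is.null(colnames(counts)))
        colnames(counts) <- phenotype$worm_id
    if (!identical(sort(colnames(counts)), sort(as.character(phenotype$worm_id))))
        stop("count matrix columns and phenotype worm_id do not match")
    phenotype <- phenotype[match(colnames(counts), phenotype$worm_id), ,
                           drop = FALSE]
    cd <- S4Vectors::DataFrame(phenotype, row.names = phenotype$worm_id)
    rd <- S4Vectors::DataFrame(gene = rownames(counts),
                               row.names = rownames(counts))
    if (!is.null(annotation)) {
        i <- match(rownames(counts), annotation$gene)
        rd$domain <- annotation$domain[i]
        rd$tissue <- annotation$tissue[i]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd, rowData = rd)
    md <- list(library_sizes = colSums(counts))
    if (!is.null(truth)) md$truth <- truth
    S4Vectors::metadata(se) <- md
    new("WormExperiment", se)
}

#' @describeIn WormExperiment raw count matrix accessor.
#' @param object,x a `WormExperiment`.
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "WormExperiment", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' CPM layer accessor
#'
#' Returns the counts-per-million assay computed by [cpmNormalize()].
#' @param x a [WormExperiment-class].
#' @return numeric matrix of CPM values (columns sum to 1e6).
#' @export
cpmValues <- function(x) {
    if (!"cpm" %in% SummarizedExperiment::assayNames(x))
        stop("no 'cpm' assay: run cpmNormalize() first")
    SummarizedExperiment::assay(x, "cpm")
}

#' Per-worm phenotype table accessor
#'
#' @param x a [WormExperiment-class].
#' @return base data.frame of the colData (one row per worm).
#' @export
phenotype <- function(x) {
    as.data.frame(SummarizedExperiment::colData(x))
}

#' Library sizes accessor
#'
#' Library sizes are the realized column sums of the counts assay.
#' @param x a [WormExperiment-class].
#' @return named numeric vector.
#' @export
libSizes <- function(x) {
    ls <- S4Vectors::metadata(x)$library_sizes
    if (is.null(ls)) ls <- colSums(counts(x))
    ls
}

#' Simulation ground truth accessor
#'
#' @param x a [WormExperiment-class] built by the simulator.
#' @return the ground-truth list, or NULL for real data.
#' @export
groundTruth <- function(x) S4Vectors::metadata(x)$truth

setMethod("show", "WormExperiment", function(object) {
    cat("WormExperiment:", nrow(object), "genes x", ncol(object), "worms\n")
    cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                           collapse = ", "), "\n")
    cd <- SummarizedExperiment::colData(object)
    cat("  phenotype columns:", paste(colnames(cd), collapse = ", "), "\n")
    if ("replicate" %in% colnames(cd))
        cat("  replicates:", length(unique(cd$replicate)), "\n")
    if (!is.null(groundTruth(object)))
        cat("  simulated (ground truth attached)\n")
})
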