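#' CPM-normalize a WormExperiment
#'
#' Adds a `"cpm"` assay with counts-per-million values,
#' `cpm[g, i] = counts[g, i] * 1e6 / library_size[i]`, computed with
#' [edgeR::cpm()].  By default library sizes are the plain column sums; with
#' `tmm = TRUE`, TMM effective library sizes from [edgeR::calcNormFactors()]
#' are used instead (off by default: the downstream models consume plain
#' CPM).
#'
#' @param x a [WormExperiment-class].
#' @param tmm logical; use TMM-adjusted effective library sizes.
#' @param minLibsize drop worms with library size below this gate
#'   (default 0, i.e. off; low-quality sample exclusion is normally done
#'   upstream of the count matrix).
#' @return `x` with a `"cpm"` assay.
#' @examples
#' we <- simulateStudy(simulationSpec(nWorms = 20, nReplicates = 2,
#'                                    nGenes = 50))
#' summary(colSums(cpmValues(we)))  # every column sums to 1e6
#' @export
cpmNormalize <- function(x, tmm = FALSE, minLibsize = 0) {
    cts <- counts(x)
    ls <- colSums(cts)
    if (any(ls == 0))
        stop("zero library size for worm(s): ",
             paste(colnames(cts)[ls == 0], collapse = ", "))
    if (minLibsize > 0 && any(ls < minLibsize))
        x <- x[, ls >= minLibsize]
    cts <- counts(x)
    if (tmm) {
        d <- edgeR::calcNormFactors(edgeR::DGEList(cts))
        cpm <- edgeR::cpm(d, log = FALSE)
    } else {
        cpm <- edgeR::cpm(cts, log = FALSE)
    }
    SummarizedExperiment::assay(x, "cpm") <- cpm
    md <- S4Vectors::metadata(x)
    md$library_sizes <- colSums(cts)
    S4Vectors::metadata(x) <- md
    x
}

#' Filter genes on CPM expression level
#'
#' Two rules mirror the two working gene sets of the analysis:
#' `"any_gt"` keeps genes with CPM strictly greater than `threshold` in at
#' least one library (used for the trait-association scan, where a gene may
#' be silent in some worms), and `"all_gt"` keeps genes strictly above
#' `threshold` in every library (the stricter set used for models that break
#' down with zero counts).  Inequalities are strict.
#'
#' @param x a CPM-normalized [WormExperiment-class].
#' @param rule `"any_gt"` or `"all_gt"`.
#' @param threshold CPM threshold.
#' @return an object of class `GeneSetFilter`: a list with `rule`,
#'   `threshold` and `genes` (character vector of kept gene ids).
#' @examples
#' we <- simulateStudy(simulationSpec(nWorms = 20, nReplicates = 2,
#'                                    nGenes = 50))
#' length(filterGenes(we, "any_gt", 10)$genes)
#' @export
filterGenes <- function(x, rule = c("any_gt", "all_gt"), threshold) {
    rule <- match.arg(rule)
    cpm <- cpmValues(x)
    keep <- switch(rule,
        any_gt = apply(cpm, 1, max) > threshold,
        all_gt = apply(cpm, 1, min) > threshold)
    structure(list(rule = rule, threshold = threshold,
                   genes = rownames(cpm)[keep]),
              class = "GeneSetFilter")
}

#' @export
print.GeneSetFilter <- function(x, ...) {
    cat(sprintf("GeneSetFilter: CPM %s %g (%s) -> %d genes\n",
                ">", x$threshold,
                if (x$rule == "any_gt") "in at least one library"
                else "across all libraries",
                length(x$genes)))
    invisible(x)
}

#' Mean-normalize and log2-transform CPM values for PCA
#'
#' For each gene, `log2((cpm + eps) / mean(cpm + eps))`: dividing by the
#' gene mean removes abundance differences between genes so principal
#' components reflect relative expression variation; the pseudocount `eps`
#' (default 0.5 CPM) guards genes with zeros.  The transform is invariant to
#' rescaling a gene's CPM by a constant (when `eps = 0`), and a constant
#' gene maps to all zeros.
#'
#' @param x a CPM-normalized [WormExperiment-class].
#' @param geneSet character vector of gene ids (e.g. from [filterGenes()]),
#'   or a `GeneSetFilter`.
#' @param eps pseudocount added to CPM before both steps.
#' @return numeric matrix, genes (rows) x worms (columns).
#' @export
logTransformForPca <- function(x, geneSet, eps = 0.5) {
    if (inherits(geneSet, "GeneSetFilter")) geneSet <- geneSet$genes
    if (length(geneSet) == 0) stop("empty gene set")
    cpm <- cpmValues(x)[geneSet, , drop = FALSE] + eps
    m <- rowMeans(cpm)
    if (any(m <= 0))
        stop("gene(s) with non-positive mean CPM + eps: ",
             paste(geneSet[m <= 0], collapse = ", "))
    log2(cpm / m)
}

## ---- readers / writers ------------------------------------------------

#' Read / write a counts matrix
#'
#' `readCounts` accepts either a TSV (genes in rows, header row of worm ids,
#' first column gene ids) or a MatrixMarket `.mtx` file with sidecar
#' `<stem>.genes.txt` / `<stem>.worms.txt` name files.  `writeCounts` mirrors
#' both formats, chosen by the file extension.
#'
#' @param path file path (`.tsv`/`.txt` or `.mtx`).
#' @return `readCounts`: integer matrix with dimnames.
#' @export
readCounts <- function(path) {
    if (grepl("\\.mtx$", path)) {
        m <- as.matrix(Matrix::readMM(path))
        stem <- sub("\\.mtx$", "", path)
        rownames(m) <- readLines(paste0(stem, ".genes.txt"))
        colnames(m) <- readLines(paste0(stem, ".worms.txt"))
        storage.mode(m) <- "double"
        return(m)
    }
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    m <- as.matrix(dt[, -1])
    rownames(m) <- dt[[1]]
    storage.mode(m) <- "double"
    m
}

#' @rdname readCounts
#' @param counts matrix to write.
#' @export
writeCounts <- function(counts, path) {
    if (grepl("\\.mtx$", path)) {
        Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
        stem <- sub("\\.mtx$", "", path)
        writeLines(rownames(counts), paste0(stem, ".genes.txt"))
        writeLines(colnames(counts), paste0(stem, ".worms.txt"))
    } else {
        dt <- data.table::data.table(gene = rownames(counts), counts)
        data.table::fwrite(dt, path, sep = "\t")
    }
    invisible(path)
}

#' Read / write the per-worm phenotype table
#'
#' CSV with columns `worm_id`, `replicate`, `parental_age`, `early_temp`,
#' `elo_hours`, `early_brood`.  Binarized columns are checked to contain
#' only 0/1.
#'
#' @param path CSV file path.
#' @return `readPhenotype`: data.frame.
#' @export
readPhenotype <- function(path) {
    ph <- as.data.frame(data.table::fread(path))
    need <- c("worm_id", "replicate")
    if (!all(need %in% colnames(ph)))
        stop("phenotype file must contain columns: ",
             paste(need, collapse = ", "))
    for (v in intersect(c("parental_age", "early_temp"), colnames(ph)))
        if (!all(is.na(ph[[v]]) | ph[[v]] %in% c(0, 1)))
            stop(sprintf("column '%s' must be binarized 0/1", v))
    ph
}

#' @rdname readPhenotype
#' @param phenotype data.frame to write.
#' @export
writePhenotype <- function(phenotype, path) {
    data.table::fwrite(phenotype, path)
    invisible(path)
}

#' Read / write a chromatin/tissue annotation table
#'
#' TSV with columns `gene`, `domain` (active/regulated/other) and `tissue`
#' (soma/germline/other).
#'
#' @param path TSV file path.
#' @return `readAnnotation`: data.frame.
#' @export
readAnnotation <- function(path) {
    ann <- as.data.frame(data.table::fread(path, sep = "\t"))
    need <- c("gene", "domain", "tissue")
    if (!all(need %in% colnames(ann)))
        stop("annotation file must contain columns: ",
             paste(need, collapse = ", "))
    bad <- setdiff(unique(ann$domain), c("active", "regulated", "other"))
    if (length(bad)) stop("unknown domain label(s): ",
                          paste(bad, collapse = ", "))
    ann
}

#' @rdname readAnnotation
#' @param annotation data.frame to write.
#' @export
writeAnnotation <- function(annotation, path) {
    data.table::fwrite(annotation, path, sep = "\t")
    invisible(path)
}

#' Read / write a per-site per-worm base-count table
#'
#' Pileup-like TSV with columns `worm_id`, `chrom`, `pos` (1-based),
#' `depth`, `A`, `C`, `G`, `T`.
#'
#' @param path TSV file path.
#' @return `readSiteCalls`: a `data.table`.
#' @export
readSiteCalls <- function(path) {
    dt <- data.table::fread(path, sep = "\t")
    need <- c("worm_id", "chrom", "pos", "depth", "A", "C", "G", "T")
    if (!all(need %in% colnames(dt)))
        stop("site-call file must contain columns: ",
             paste(need, collapse = ", "))
    dt
}

#' @rdname readSiteCalls
#' @param calls table to write.
#' @export
writeSiteCalls <- function(calls, path) {
    data.table::fwrite(calls, path, sep = "\t")
    invisible(path)
}

#' Build a WormExperiment from files on disk
#'
#' @param countsPath counts TSV or MatrixMarket file.
#' @param phenotypePath phenotype CSV.
#' @param annotationPath optional annotation TSV.
#' @return a [WormExperiment-class].
#' @export
readWormExperiment <- function(countsPath, phenotypePath,
                               annotationPath = NULL) {
    ann <- if (!is.null(annotationPath)) readAnnotation(annotationPath)
    WormExperiment(readCounts(countsPath), readPhenotype(phenotypePath),
                   annotation = ann)
}
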