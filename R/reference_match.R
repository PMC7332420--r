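#' Mean raw-count expression profile per cluster
#'
#' Entry (g, k) is the arithmetic mean raw UMI count of gene g over the
#' cells of cluster k.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{counts} and
#'   \code{cluster} labels.
#' @return Numeric matrix, genes x clusters.
#' @export
clusterMeanProfiles <- function(sce) {
    cl <- colData(sce)$cluster
    if (is.null(cl)) stop("run clusterCells first")
    cnt <- assay(sce, "counts")
    ks <- levels(factor(cl))
    prof <- vapply(ks, function(k)
        Matrix::rowMeans(cnt[, cl == k, drop = FALSE]), numeric(nrow(cnt)))
    rownames(prof) <- rownames(sce)
    prof
}

## shared detected-gene space: expressed in >= 1 bulk column or >= 1 profile
.sharedGenes <- function(profiles, bulk_values) {
    shared <- intersect(rownames(profiles), rownames(bulk_values))
    detected <- rowSums(bulk_values[shared, , drop = FALSE] > 0) > 0 |
        rowSums(profiles[shared, , drop = FALSE] > 0) > 0
    shared[detected]
}

#' Correlate cluster profiles with bulk reference profiles
#'
#' Pearson correlation between every cluster mean profile and every bulk
#' column, computed over the shared detected genes after an optional
#' \code{log1p} transform (default; raw RPKM/UMI correlations are dominated
#' by a handful of highly expressed genes). Zero-variance vectors yield
#' \code{NA}, never 0.
#'
#' @param profiles genes x clusters matrix from
#'   \code{\link{clusterMeanProfiles}}.
#' @param bulk a \linkS4class{BulkProfileSet}.
#' @param transform \code{"log1p"} (default) or \code{"raw"}.
#' @param min_genes minimum size of the shared gene space.
#' @return Clusters x bulk-columns correlation matrix with the gene count in
#'   \code{attr(, "n_genes")} and bulk labels in \code{attr(, "label")}.
#' @export
correlateClusterBulk <- function(profiles, bulk,
                                 transform = c("log1p", "raw"),
                                 min_genes = 100L) {
    transform <- match.arg(transform)
    bv <- assay(bulk)
    genes <- .sharedGenes(profiles, bv)
    if (length(genes) < min_genes)
        stop("only ", length(genes), " shared detected genes (need >= ",
             min_genes, ")")
    a <- profiles[genes, , drop = FALSE]
    b <- bv[genes, , drop = FALSE]
    if (transform == "log1p") { a <- log1p(a); b <- log1p(b) }
    keep_a <- apply(a, 2L, stats::sd) > 0
    keep_b <- apply(b, 2L, stats::sd) > 0
    r <- matrix(NA_real_, ncol(a), ncol(b),
                dimnames = list(colnames(a), colnames(b)))
    if (any(keep_a) && any(keep_b))
        r[keep_a, keep_b] <- stats::cor(a[, keep_a, drop = FALSE],
                                        b[, keep_b, drop = FALSE])
    attr(r, "n_genes") <- length(genes)
    attr(r, "label") <- colData(bulk)$label
    attr(r, "transform") <- transform
    r
}

#' Nominate the endosymbiotic cluster
#'
#' Returns the cluster whose mean Pearson correlation with the
#' alga-containing bulk replicates is highest. Ties are broken by the larger
#' margin (mean alga_pos r minus mean alga_neg r), then by the smaller
#' cluster id.
#'
#' @param cm correlation matrix from \code{\link{correlateClusterBulk}}.
#' @return List with \code{cluster} (id), \code{margin}, and the per-cluster
#'   mean correlations \code{mean_pos}, \code{mean_neg}.
#' @export
nominateEndosymbiotic <- function(cm) {
    label <- attr(cm, "label")
    pos <- which(label == "alga_pos")
    if (!length(pos)) stop("no alga_pos column in the correlation matrix")
    neg <- which(label == "alga_neg")
    mean_pos <- rowMeans(cm[, pos, drop = FALSE])
    mean_neg <- if (length(neg)) rowMeans(cm[, neg, drop = FALSE])
        else rep(0, nrow(cm))
    if (all(is.na(mean_pos))) stop("all correlations missing")
    margin <- mean_pos - mean_neg
    ord <- order(-mean_pos, -margin, seq_len(nrow(cm)))
    win <- ord[1L]
    list(cluster = rownames(cm)[win], margin = unname(margin[win]),
         mean_pos = mean_pos, mean_neg = mean_neg)
}

#' Per-cell correlation with bulk reference profiles
#'
#' Pearson correlation of every cell's normalized expression with every bulk
#' column over the shared detected gene space (log1p-transformed bulk side
#' when \code{transform = "log1p"}; the single-cell side uses the normalized
#' values as given). Cells with zero variance on the shared genes yield
#' \code{NA}.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{logcounts}.
#' @param bulk a \linkS4class{BulkProfileSet}.
#' @param cells cell identifiers (or indices) to use; default all.
#' @param transform \code{"log1p"} or \code{"raw"} for the bulk side.
#' @return Cells x bulk-columns matrix of correlations with bulk labels in
#'   \code{attr(, "label")}.
#' @export
perCellBulkCorrelation <- function(sce, bulk, cells = NULL,
                                   transform = c("log1p", "raw")) {
    transform <- match.arg(transform)
    if (is.null(cells)) cells <- colnames(sce)
    if (!length(cells)) stop("cells must be non-empty")
    x <- as.matrix(assay(sce, "logcounts")[, cells, drop = FALSE])
    bv <- assay(bulk)
    genes <- .sharedGenes(x, bv)
    if (!length(genes)) stop("no shared detected genes")
    a <- x[genes, , drop = FALSE]
    b <- bv[genes, , drop = FALSE]
    if (transform == "log1p") b <- log1p(b)
    keep_a <- apply(a, 2L, stats::sd) > 0
    keep_b <- apply(b, 2L, stats::sd) > 0
    r <- matrix(NA_real_, ncol(a), ncol(b),
                dimnames = list(colnames(a), colnames(b)))
    if (any(keep_a) && any(keep_b))
        r[keep_a, keep_b] <- stats::cor(a[, keep_a, drop = FALSE],
                                        b[, keep_b, drop = FALSE])
    attr(r, "label") <- colData(bulk)$label
    r
}
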