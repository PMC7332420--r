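#' Quality-control filtering of cells
#'
#' Removes cells with fewer than \code{min_umi} total UMIs or a
#' mitochondrial UMI fraction above \code{max_mito_frac}, then trims cells
#' in the top \code{top_quantile} of the UMI distribution computed on the
#' post-threshold population (outlier removal). Removal counts per rule are
#' recorded in \code{metadata(sce)$qc}.
#'
#' The two threshold rules are idempotent; the top-quantile trim is a
#' once-only outlier step (re-trimming a trimmed population would cut a new
#' top tail by construction).
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a \code{counts} assay
#'   and a logical \code{mito} column in \code{rowData}.
#' @param min_umi minimum total UMI per cell (cells below are excluded).
#' @param max_mito_frac maximum mitochondrial UMI fraction.
#' @param top_quantile upper quantile of total UMI trimmed after the
#'   threshold rules; 0 disables the trim.
#' @return The filtered \code{SingleCellExperiment}.
#' @examples
#' sim <- generateCells(simParams(n_genes = 300, n_cells_per_batch = 100,
#'                                n_type_markers = 8, n_dynamic_genes = 10))
#' qcFilterCells(sim$sce, min_umi = 50)
#' @export
qcFilterCells <- function(sce, min_umi = 400, max_mito_frac = 0.002,
                          top_quantile = 0.01) {
    if (!"mito" %in% colnames(rowData(sce)))
        stop("rowData(sce)$mito is required for the mitochondrial filter")
    cnt <- assay(sce, "counts")
    total <- Matrix::colSums(cnt)
    mito_frac <- Matrix::colSums(cnt[rowData(sce)$mito, , drop = FALSE]) /
        pmax(total, 1)
    low_umi <- total < min_umi
    high_mito <- mito_frac > max_mito_frac
    keep <- !low_umi & !high_mito
    n_top <- 0L
    if (top_quantile > 0 && any(keep)) {
        thr <- stats::quantile(total[keep], 1 - top_quantile, names = FALSE)
        top <- keep & total > thr
        n_top <- sum(top)
        keep <- keep & !top
    }
    if (!any(keep))
        stop("all cells removed by QC; check thresholds")
    out <- sce[, keep]
    metadata(out)$qc <- list(min_umi = min_umi,
                             max_mito_frac = max_mito_frac,
                             top_quantile = top_quantile,
                             removed_low_umi = sum(low_umi),
                             removed_high_mito = sum(high_mito & !low_umi),
                             removed_top_quantile = n_top)
    out
}

#' Log-normalize UMI counts
#'
#' Computes \code{ln(1 + scale * count / column_total)} per entry; a
#' scale-invariant transform (doubling all counts in a cell leaves the
#' normalized values unchanged). Stored as the \code{logcounts} assay.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a \code{counts} assay.
#' @param scale library-size scale factor.
#' @return \code{sce} with a \code{logcounts} assay added.
#' @examples
#' sim <- generateCells(simParams(n_genes = 300, n_cells_per_batch = 50,
#'                                n_type_markers = 8, n_dynamic_genes = 10))
#' normalizeLog(sim$sce)
#' @export
normalizeLog <- function(sce, scale = 1e4) {
    cnt <- assay(sce, "counts")
    total <- Matrix::colSums(cnt)
    if (any(total <= 0))
        stop("cells with zero total counts present; run qcFilterCells first")
    norm <- cnt %*% Matrix::Diagonal(x = scale / total)
    norm@x <- log1p(norm@x)  # zeros stay zero
    dimnames(norm) <- dimnames(cnt)
    SummarizedExperiment::assay(sce, "logcounts") <- norm
    sce
}

#' Select highly variable genes by binned dispersion
#'
#' Dispersion of a gene is the variance/mean ratio of its normalized
#' expression. Genes are grouped into 20 equal-frequency bins of mean
#' expression and the dispersion is z-scored within each bin (so selection is
#' not driven by the mean-dispersion trend); the \code{n_top} genes with the
#' highest z-scores are flagged. For very small gene sets (fewer than twice
#' the bin count) binning is skipped and raw dispersion is ranked directly.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{logcounts}.
#' @param n_top number of genes to flag.
#' @param n_bins number of equal-frequency mean bins.
#' @return \code{sce} with a logical \code{hvg} column in \code{rowData}.
#' @examples
#' sim <- generateCells(simParams(n_genes = 300, n_cells_per_batch = 50,
#'                                n_type_markers = 8, n_dynamic_genes = 10))
#' sce <- selectHVG(normalizeLog(sim$sce), n_top = 50)
#' sum(rowData(sce)$hvg)
#' @export
selectHVG <- function(sce, n_top = 1000L, n_bins = 20L) {
    x <- assay(sce, "logcounts")
    mu <- Matrix::rowMeans(x)
    v <- Matrix::rowMeans(x^2) - mu^2
    v <- v * ncol(x) / max(1L, ncol(x) - 1L)
    disp <- ifelse(mu > 0, v / mu, 0)
    informative <- which(v > 0 & mu > 0)
    if (length(informative) < n_top) {
        warning("fewer informative genes than n_top; flagging all ",
                length(informative))
        hvg <- logical(nrow(sce))
        hvg[informative] <- TRUE
        rowData(sce)$hvg <- hvg
        return(sce)
    }
    if (length(informative) < 2L * n_bins) {
        score <- disp[informative]
    } else {
        bins <- cut(rank(mu[informative], ties.method = "first"),
                    breaks = n_bins, labels = FALSE)
        score <- disp[informative]
        for (b in unique(bins)) {
            idx <- bins == b
            m <- mean(score[idx]); s <- stats::sd(score[idx])
            score[idx] <- if (is.na(s) || s == 0) 0 else (score[idx] - m) / s
        }
    }
    ord <- informative[order(-score, informative)]
    hvg <- logical(nrow(sce))
    hvg[ord[seq_len(n_top)]] <- TRUE
    rowData(sce)$hvg <- hvg
    sce
}

#' Joint embedding across batches
#'
#' Standardizes each highly variable gene within each batch (mean 0,
#' variance 1), pools the batches, and takes a truncated eigendecomposition
#' of the pooled matrix. This removes batch-scale differences (the dominant
#' batch effect between chemistries of different depth) before a common
#' principal component space is computed. Component signs are fixed by making
#' the largest-magnitude gene loading positive, so the embedding is
#' deterministic.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{logcounts},
#'   an \code{hvg} flag in \code{rowData} and a \code{batch} column in
#'   \code{colData}.
#' @param d number of dimensions (default 20).
#' @return \code{sce} with a \code{"PCA"} entry in \code{reducedDims};
#'   per-component variance explained is stored in
#'   \code{metadata(sce)$pca_var}.
#' @examples
#' sim <- generateCells(simParams(n_genes = 300, n_cells_per_batch = 80,
#'                                n_type_markers = 8, n_dynamic_genes = 10))
#' sce <- selectHVG(normalizeLog(sim$sce), n_top = 100)
#' sce <- jointEmbedding(sce, d = 5)
#' @export
jointEmbedding <- function(sce, d = 20L) {
    if (!"hvg" %in% colnames(rowData(sce)))
        stop("run selectHVG first")
    hvg <- rowData(sce)$hvg
    if (sum(hvg) < d)
        stop("d exceeds the number of highly variable genes")
    x <- t(as.matrix(assay(sce, "logcounts")[hvg, , drop = FALSE]))
    batch <- if ("batch" %in% colnames(colData(sce)))
        as.character(colData(sce)$batch) else rep("all", ncol(sce))
    for (b in unique(batch)) {
        idx <- batch == b
        xb <- x[idx, , drop = FALSE]
        mu <- colMeans(xb)
        sd <- apply(xb, 2L, stats::sd)
        sd[sd == 0 | is.na(sd)] <- 1
        x[idx, ] <- sweep(sweep(xb, 2L, mu), 2L, sd, "/")
    }
    cov <- crossprod(x) / max(1L, nrow(x) - 1L)
    eig <- eigen(cov, symmetric = TRUE)
    V <- eig$vectors[, seq_len(d), drop = FALSE]
    for (j in seq_len(d)) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    scores <- x %*% V
    colnames(scores) <- paste0("PC", seq_len(d))
    rownames(scores) <- colnames(sce)
    SingleCellExperiment::reducedDim(sce, "PCA") <- scores
    metadata(sce)$pca_var <- pmax(eig$values, 0)
    sce
}
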