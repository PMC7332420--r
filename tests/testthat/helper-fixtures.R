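## small generator settings shared by module tests: 300 genes, 2 x 150
## cells, a common (10%) "endosymbiotic" type so the subset has ~30 cells
smallParams <- function(seed = 101, ...) {
    args <- list(n_genes = 300L, n_cells_per_batch = 150L,
                 n_type_markers = 8L, n_dynamic_genes = 10L,
                 rare_type_freq = 0.10, seed = seed)
    override <- list(...)
    args[names(override)] <- override
    do.call(simParams, args)
}

## memoized small dataset, preprocessed up to the joint embedding
.cache <- new.env(parent = emptyenv())
smallData <- function() {
    if (is.null(.cache$small)) {
        sim <- generateCells(smallParams())
        sce <- qcFilterCells(sim$sce, min_umi = 100)
        sce <- normalizeLog(sce)
        sce <- selectHVG(sce, n_top = 100L)
        sce <- jointEmbedding(sce, d = 10L)
        bulk <- generateBulkReferences(smallParams(), sim$truth, sim$sce)
        .cache$small <- list(sim = sim, sce = sce, bulk = bulk)
    }
    .cache$small
}

## SingleCellExperiment from a dense counts matrix (plus optional layers)
sceFrom <- function(counts, spliced = NULL, unspliced = NULL,
                    mito = rep(FALSE, nrow(counts))) {
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
    assays <- list(counts = methods::as(counts, "CsparseMatrix"))
    if (!is.null(spliced)) {
        dimnames(spliced) <- dimnames(counts)
        assays$spliced <- methods::as(spliced, "CsparseMatrix")
    }
    if (!is.null(unspliced)) {
        dimnames(unspliced) <- dimnames(counts)
        assays$unspliced <- methods::as(unspliced, "CsparseMatrix")
    }
    SingleCellExperiment::SingleCellExperiment(
        assays = assays,
        rowData = S4Vectors::DataFrame(mito = mito,
                                       row.names = rownames(counts)))
}

## Trajectory with given pseudotime over given cell names
trajFrom <- function(pt, cells = names(pt)) {
    pt <- (pt - min(pt)) / (max(pt) - min(pt))
    new("Trajectory", cells = cells, coords = matrix(0, length(pt), 2),
        nodes = matrix(c(0, 0, 1, 1), 2, 2), lambda = pt,
        pseudotime = stats::setNames(pt, cells), orientation = 1L,
        confidence = 1, orderingGenes = character(), converged = TRUE)
}
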