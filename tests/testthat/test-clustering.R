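## embed two well-separated Gaussian blobs directly in a reduced dimension
blobSCE <- function(n = 25, sep = 20, d = 5, seed = 3) {
    set.seed(seed)
    coords <- rbind(matrix(rnorm(n * d), n, d),
                    matrix(rnorm(n * d), n, d) + sep)
    rownames(coords) <- sprintf("c%03d", seq_len(2 * n))
    sce <- sceFrom(matrix(1, 4, 2 * n))
    SingleCellExperiment::reducedDim(sce, "PCA") <- coords
    list(sce = sce, labels = rep(1:2, each = n))
}

test_that("well-separated blobs give exactly two matching clusters", {
    b <- blobSCE()
    out <- clusterCells(b$sce, n_neighbours = 15, seed = 1)
    cl <- colData(out)$cluster
    expect_identical(nlevels(cl), 2L)
    expect_equal(length(unique(cl[b$labels == 1])), 1L)
    expect_equal(length(unique(cl[b$labels == 2])), 1L)
})

test_that("clustering is deterministic given the seed", {
    b <- blobSCE(seed = 4)
    a1 <- colData(clusterCells(b$sce, seed = 42))$cluster
    a2 <- colData(clusterCells(b$sce, seed = 42))$cluster
    expect_identical(a1, a2)
})

test_that("a degenerate embedding collapses to one cluster with a warning", {
    sce <- sceFrom(matrix(1, 4, 30))
    SingleCellExperiment::reducedDim(sce, "PCA") <-
        matrix(1, 30, 3, dimnames = list(colnames(sce), NULL))
    expect_warning(out <- clusterCells(sce, n_neighbours = 5),
                   "degenerate")
    expect_identical(nlevels(colData(out)$cluster), 1L)
})

test_that("label transfer votes among nearest reference neighbours", {
    b <- blobSCE(seed = 5)
    ref <- clusterCells(b$sce, n_neighbours = 10, seed = 1)
    ## query cell coincident with a reference cell, k = 1
    q <- sceFrom(matrix(1, 4, 1))
    qc <- SingleCellExperiment::reducedDim(ref, "PCA")[3, , drop = FALSE]
    rownames(qc) <- colnames(q)
    SingleCellExperiment::reducedDim(q, "PCA") <- qc
    out <- transferLabels(ref, q, k = 1)
    expect_identical(as.character(colData(out)$cluster),
                     as.character(colData(ref)$cluster[3]))
    expect_equal(colData(out)$transfer_score, 1)
    ## single-cluster reference transfers that label to everything
    ref1 <- ref
    colData(ref1)$cluster <- factor(rep(1L, ncol(ref1)))
    out1 <- transferLabels(ref1, b$sce, k = 5)
    expect_true(all(colData(out1)$cluster == 1L))
    ## empty reference errors
    expect_error(transferLabels(ref[, 0], q), "empty reference")
})

test_that("transferred labels recover the endosymbiotic cells on synthetic data", {
    sd <- smallData()
    sce <- sd$sce
    batch <- colData(sce)$batch
    ref <- clusterCells(sce[, batch == "v2"], n_neighbours = 10, seed = 1)
    qry <- transferLabels(ref, sce[, batch == "v3"], k = 15)
    truth <- sd$sim$truth$cells
    ## the rare type must map onto a single reference cluster
    ref_endo <- names(which.max(table(
        colData(ref)$cluster[truth[colnames(ref), "type"] == 16])))
    q_endo <- truth[colnames(qry), "type"] == 16
    agree <- mean(colData(qry)$cluster[q_endo] == ref_endo)
    expect_gte(agree, 0.9)
})

test_that("marker statistics match their definitions on a toy", {
    ## cluster A = {5, 5}, rest = {0, 0, 0, 0}
    x <- matrix(c(5, 5, 0, 0, 0, 0,
                  1, 1, 1, 1, 1, 1), 2, 6, byrow = TRUE)
    sce <- sceFrom(matrix(1, 2, 6))
    rownames(sce) <- c("gA", "flat")
    dimnames(x) <- dimnames(sce)
    SummarizedExperiment::assay(sce, "logcounts") <- x
    colData(sce)$cluster <- factor(rep(c("A", "B"), c(2, 4)))
    mk <- computeMarkers(sce)
    a <- mk[mk$gene == "gA" & mk$cluster == "A", ]
    expect_equal(a$avg_logFC, log(6) - log(1), tolerance = 1e-12)
    expect_equal(a$specificity_within_cluster, 1)
    expect_equal(a$specificity_outside_cluster, 0)
    f <- mk[mk$gene == "flat" & mk$cluster == "A", ]
    expect_equal(f$avg_logFC, 0)
    expect_equal(f$specificity_within_cluster, 0)
    expect_equal(f$specificity_outside_cluster, 0)
    ## small clusters are flagged and reported with p = 1
    expect_true(all(mk$flag_small_cluster[mk$cluster == "A"]))
    expect_true(all(mk$p_val[mk$cluster == "A"] == 1))
})

test_that("Bonferroni correction matches brute force over all tests", {
    set.seed(6)
    x <- matrix(rnorm(5 * 40, sd = 1) + 2, 5, 40)
    sce <- sceFrom(matrix(1, 5, 40))
    dimnames(x) <- dimnames(sce)
    SummarizedExperiment::assay(sce, "logcounts") <- x
    colData(sce)$cluster <- factor(rep(1:2, each = 20))
    mk <- computeMarkers(sce)
    expect_equal(mk$p_val_adj, pmin(1, mk$p_val * nrow(mk)))
    ## p-values agree with a direct wilcox.test call
    i <- which(mk$gene == rownames(x)[1] & mk$cluster == "1")
    ref <- wilcox.test(x[1, 1:20], x[1, 21:40], exact = FALSE)$p.value
    expect_equal(mk$p_val[i], ref)
})

test_that("endosymbiotic markers outrank static genes on synthetic data", {
    sd <- smallData()
    sce <- clusterCells(sd$sce, seed = 1)
    cm <- correlateClusterBulk(clusterMeanProfiles(sce), sd$bulk,
                               min_genes = 50)
    nom <- nominateEndosymbiotic(cm)
    mk <- computeMarkers(sce, clusters = nom$cluster)
    top20 <- mk$gene[seq_len(20)]
    gt <- sd$sim$truth$genes
    program <- rownames(gt)[gt$module != "static" |
                                (!is.na(gt$marker_of) & gt$marker_of == 16)]
    expect_gte(sum(top20 %in% program), 15)
})
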