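## shared kNN graph builder: union of directed kNN edges, unweighted
.knnGraph <- function(coords, k) {
    k <- min(k, nrow(coords) - 1L)
    nn <- BiocNeighbors::findKNN(coords, k = k)
    edges <- cbind(rep(seq_len(nrow(coords)), k), as.vector(nn$index))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    igraph::simplify(g)
}

#' Graph-based clustering of cells
#'
#' Builds a k-nearest-neighbour graph on the joint embedding and partitions
#' it by Louvain modularity optimization. Cluster ids are renumbered by
#' decreasing size so that downstream references are stable.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a \code{"PCA"}
#'   reduced dimension.
#' @param n_neighbours neighbours for the kNN graph.
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed (community detection is seeded, hence
#'   deterministic).
#' @return \code{sce} with a \code{cluster} factor in \code{colData} and the
#'   parameters in \code{metadata(sce)$clustering}.
#' @examples
#' sim <- generateCells(simParams(n_genes = 300, n_cells_per_batch = 100,
#'                                n_type_markers = 8, n_dynamic_genes = 10))
#' sce <- jointEmbedding(selectHVG(normalizeLog(sim$sce), n_top = 100), d = 10)
#' sce <- clusterCells(sce, seed = 1)
#' table(colData(sce)$cluster)
#' @export
clusterCells <- function(sce, n_neighbours = 15L, resolution = 1.0,
                         seed = 0L) {
    coords <- SingleCellExperiment::reducedDim(sce, "PCA")
    if (nrow(coords) < n_neighbours + 1L)
        stop("need at least n_neighbours + 1 cells")
    if (all(apply(coords, 2L, function(z) max(z) - min(z)) < 1e-12)) {
        warning("degenerate embedding (all points identical); one cluster")
        cl <- rep(1L, nrow(coords))
    } else {
        g <- .knnGraph(coords, n_neighbours)
        set.seed(seed)
        memb <- igraph::membership(
            igraph::cluster_louvain(g, resolution = resolution))
        ord <- order(-tabulate(memb))  # ties broken by original id
        cl <- match(memb, ord)
    }
    colData(sce)$cluster <- factor(cl, levels = sort(unique(cl)))
    metadata(sce)$clustering <- list(n_neighbours = n_neighbours,
                                     resolution = resolution, seed = seed)
    sce
}

#' Transfer cluster labels from a reference to a query
#'
#' Each query cell receives the majority cluster label of its \code{k}
#' nearest reference cells in the shared embedding; ties are broken towards
#' the smaller cluster id. The vote fraction is attached as a transfer score.
#'
#' @param reference a clustered \linkS4class{SingleCellExperiment} with a
#'   \code{"PCA"} reduced dimension and \code{cluster} labels.
#' @param query a \code{SingleCellExperiment} embedded in the same basis.
#' @param k number of reference neighbours to poll.
#' @return \code{query} with \code{cluster} and \code{transfer_score}
#'   columns in \code{colData}.
#' @export
transferLabels <- function(reference, query, k = 15L) {
    ref_coords <- SingleCellExperiment::reducedDim(reference, "PCA")
    if (!nrow(ref_coords)) stop("empty reference")
    q_coords <- SingleCellExperiment::reducedDim(query, "PCA")
    stopifnot(ncol(ref_coords) == ncol(q_coords))
    labels <- as.integer(colData(reference)$cluster)
    k <- min(k, nrow(ref_coords))
    nn <- BiocNeighbors::queryKNN(ref_coords, q_coords, k = k)
    votes <- matrix(labels[nn$index], nrow = nrow(q_coords))
    pick <- apply(votes, 1L, function(v) {
        tab <- table(v)
        win <- tab[tab == max(tab)]
        id <- min(as.integer(names(win)))  # tie -> smaller cluster id
        c(id, max(tab) / length(v))
    })
    colData(query)$cluster <- factor(pick[1L, ])
    colData(query)$transfer_score <- pick[2L, ]
    query
}

#' Marker-gene statistics per cluster
#'
#' For every gene and cluster computes a two-sided Wilcoxon rank-sum test of
#' in-cluster versus all other cells on normalized expression, a Bonferroni
#' adjustment over all gene x cluster tests performed, the natural-log fold
#' change of average expression \code{ln(mean_in + 1) - ln(mean_out + 1)}
#' (pseudocount 1 stabilizes zero means), and two specificity fractions: the
#' fraction of in-cluster (respectively out-of-cluster) cells whose
#' expression strictly exceeds the gene's all-cell mean.
#'
#' Clusters with fewer than 3 cells are reported with p = 1 and flagged.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{logcounts}
#'   and \code{cluster} labels.
#' @param clusters clusters to test (default all).
#' @param genes genes to test (default all).
#' @return \code{data.frame} with columns \code{gene}, \code{cluster},
#'   \code{p_val}, \code{p_val_adj}, \code{avg_logFC},
#'   \code{specificity_within_cluster}, \code{specificity_outside_cluster},
#'   \code{flag_small_cluster}, sorted by adjusted p within cluster.
#' @export
computeMarkers <- function(sce, clusters = NULL, genes = NULL) {
    cl <- colData(sce)$cluster
    if (is.null(cl)) stop("run clusterCells first")
    if (nlevels(factor(cl)) < 2L) stop("need at least 2 clusters")
    x <- assay(sce, "logcounts")
    if (is.null(genes)) genes <- rownames(sce)
    if (is.null(clusters)) clusters <- levels(factor(cl))
    x <- as.matrix(x[genes, , drop = FALSE])
    gene_mean <- rowMeans(x)
    res <- lapply(clusters, function(k) {
        inc <- cl == k
        small <- sum(inc) < 3L
        mean_in <- rowMeans(x[, inc, drop = FALSE])
        mean_out <- rowMeans(x[, !inc, drop = FALSE])
        p <- if (small) rep(1, length(genes)) else
            vapply(seq_along(genes), function(i) {
                xi <- x[i, ]
                if (all(xi == xi[1L])) return(1)
                stats::wilcox.test(xi[inc], xi[!inc], exact = FALSE)$p.value
            }, numeric(1))
        spec_in <- rowMeans(x[, inc, drop = FALSE] > gene_mean)
        spec_out <- rowMeans(x[, !inc, drop = FALSE] > gene_mean)
        data.frame(gene = genes, cluster = k, p_val = p,
                   avg_logFC = log(mean_in + 1) - log(mean_out + 1),
                   specificity_within_cluster = spec_in,
                   specificity_outside_cluster = spec_out,
                   flag_small_cluster = small, row.names = NULL)
    })
    out <- do.call(rbind, res)
    out$p_val_adj <- stats::p.adjust(out$p_val, method = "bonferroni")
    out <- out[order(match(out$cluster, clusters), out$p_val_adj,
                     out$p_val), ]
    rownames(out) <- NULL
    out[, c("gene", "cluster", "p_val", "p_val_adj", "avg_logFC",
            "specificity_within_cluster", "specificity_outside_cluster",
            "flag_small_cluster")]
}

#' Write a marker table in the conventional column layout
#'
#' @param markers output of \code{\link{computeMarkers}}.
#' @param file output TSV path.
#' @return Invisibly, the written data frame.
#' @export
writeMarkerTable <- function(markers, file) {
    out <- data.frame(Gene_ID = markers$gene, Cluster = markers$cluster,
                      p_val_adj = markers$p_val_adj,
                      avg_logFC = markers$avg_logFC,
                      specificity_within_cluster =
                          markers$specificity_within_cluster,
                      specificity_outside_cluster =
                          markers$specificity_outside_cluster)
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(out)
}
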