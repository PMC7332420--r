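#' Run one ground-truth recovery experiment
#'
#' Generates a synthetic dataset with \code{\link{generateCells}}, runs the
#' full analysis chain (QC, normalization, embedding, clustering, bulk
#' reference nomination, ordering genes, principal-curve pseudotime,
#' velocity orientation, pseudotime differential expression, gene modules,
#' state segmentation), and scores every stage against the generator's
#' ground truth. This is the package's own end-to-end validation experiment;
#' the acceptance script and test suite aggregate it over seeds.
#'
#' @param seed integer seed defining the replicate.
#' @param params generator parameters (default \code{simParams(seed = seed)}).
#' @return List of metrics: \code{cluster_ari} (clustering vs true types),
#'   \code{nomination_correct} (nominated cluster is majority-endosymbiotic),
#'   \code{n_endo} (cells in the nominated cluster),
#'   \code{pseudotime_rho} (signed Spearman correlation of oriented
#'   pseudotime with truth), \code{orientation_correct},
#'   \code{state_ari} (segmentation vs true states),
#'   \code{state3_top_corr} (recovered state 3 has the maximal mean
#'   alga_pos correlation), \code{proportion_direction} (regeneration has
#'   the larger state-1+2 share), and \code{proportions} (the table).
#' @examples
#' \donttest{
#' m <- evaluateRecovery(1)
#' m$cluster_ari
#' }
#' @export
evaluateRecovery <- function(seed, params = simParams(seed = seed)) {
    sim <- generateCells(params)
    sce <- qcFilterCells(sim$sce)
    sce <- normalizeLog(sce)
    sce <- selectHVG(sce)
    sce <- jointEmbedding(sce)
    sce <- clusterCells(sce, seed = seed)
    truth <- sim$truth$cells[colnames(sce), ]
    endo_type <- params$n_types
    cluster_ari <- .ari(as.integer(colData(sce)$cluster), truth$type)

    bulk <- generateBulkReferences(params, sim$truth, sim$sce)
    cm <- correlateClusterBulk(clusterMeanProfiles(sce), bulk)
    nom <- nominateEndosymbiotic(cm)
    endo <- colnames(sce)[colData(sce)$cluster == nom$cluster]
    nomination_correct <- mean(truth[endo, "type"] == endo_type) > 0.5

    genes <- selectOrderingGenes(sce, endo)
    traj <- suppressWarnings(fitTrajectory(sce, endo, genes))
    vm <- fitGamma(sce, endo, coords = traj@coords)
    traj <- orientPseudotime(traj, vm)
    tt <- truth[endo, "pseudotime"]
    rho <- stats::cor(pseudotime(traj)[endo], tt, method = "spearman",
                      use = "complete.obs")

    de <- pseudotimeDETest(sce, traj, genes = genes)
    sig <- de$gene[de$significant]
    if (length(sig) < 10L) sig <- de$gene[order(de$q)][seq_len(50L)]
    if (length(sig) > 200L) sig <- de$gene[order(de$q)][seq_len(200L)]
    smg <- smoothCurves(sce, traj, sig)
    modules <- clusterGeneModules(smg, 3L)
    pc <- perCellBulkCorrelation(sce, bulk, endo)
    sm <- segmentStates(sce, traj, modules, pc, smg)
    state_ari <- .ari(stateLabels(sm), truth[endo, "state"])
    pos <- rowMeans(pc[, attr(pc, "label") == "alga_pos", drop = FALSE])
    by_state <- tapply(pos[names(stateLabels(sm))], stateLabels(sm), mean)
    conds <- stats::setNames(colData(sce)$condition, colnames(sce))
    props <- stateProportions(sm, conds)
    dir_ok <- if (all(c("regeneration", "homeostasis") %in% rownames(props)))
        sum(props["regeneration", 1:2]) > sum(props["homeostasis", 1:2])
    else NA
    list(cluster_ari = cluster_ari,
         nomination_correct = nomination_correct,
         n_endo = length(endo),
         pseudotime_rho = rho,
         orientation_correct = !is.na(rho) && rho > 0,
         state_ari = state_ari,
         state3_top_corr = unname(which.max(by_state) == 3L),
         proportion_direction = dir_ok,
         proportions = props)
}

## adjusted Rand index between two label vectors (NA pairs dropped)
.ari <- function(a, b) {
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    tab <- table(a, b)
    n <- sum(tab)
    sum_ij <- sum(choose(tab, 2))
    sum_a <- sum(choose(rowSums(tab), 2))
    sum_b <- sum(choose(colSums(tab), 2))
    expected <- sum_a * sum_b / choose(n, 2)
    mx <- (sum_a + sum_b) / 2
    if (mx == expected) return(0)
    (sum_ij - expected) / (mx - expected)
}
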