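#' Write a cell matrix as 10x-style MatrixMarket triplets
#'
#' Writes \code{matrix.mtx} (1-based MatrixMarket coordinate format),
#' \code{features.tsv} (gene id, symbol; tab-separated, no header),
#' \code{barcodes.tsv}, and, when present, the \code{spliced.mtx} and
#' \code{unspliced.mtx} layers sharing the feature/barcode files.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a \code{counts}
#'   assay.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write10x <- function(sce, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wm <- function(assay_name, file) {
        m <- methods::as(assay(sce, assay_name), "CsparseMatrix")
        Matrix::writeMM(m, file.path(dir, file))
    }
    wm("counts", "matrix.mtx")
    if ("spliced" %in% SummarizedExperiment::assayNames(sce))
        wm("spliced", "spliced.mtx")
    if ("unspliced" %in% SummarizedExperiment::assayNames(sce))
        wm("unspliced", "unspliced.mtx")
    rd <- rowData(sce)
    feat <- data.frame(id = rownames(sce),
                       symbol = if ("symbol" %in% colnames(rd)) rd$symbol
                                else rownames(sce))
    utils::write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
    invisible(dir)
}

#' Read a 10x-style MatrixMarket triplet directory
#'
#' Counterpart of \code{\link{write10x}}; the round trip is lossless.
#' Optional \code{spliced.mtx}/\code{unspliced.mtx} layers are attached when
#' present.
#'
#' @param dir directory with \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv}.
#' @return A \linkS4class{SingleCellExperiment}.
#' @export
read10x <- function(dir) {
    need <- c("matrix.mtx", "features.tsv", "barcodes.tsv")
    missing <- need[!file.exists(file.path(dir, need))]
    if (length(missing))
        stop("missing files in ", dir, ": ", paste(missing, collapse = ", "))
    rm_ <- function(f) {
        m <- tryCatch(Matrix::readMM(file.path(dir, f)),
                      error = function(e)
                          stop("malformed MatrixMarket file ", f, ": ",
                               conditionMessage(e)))
        methods::as(m, "CsparseMatrix")
    }
    counts <- rm_("matrix.mtx")
    feat <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                              header = FALSE, colClasses = "character")
    barcodes <- readLines(file.path(dir, "barcodes.tsv"))
    if (nrow(feat) != nrow(counts) || length(barcodes) != ncol(counts))
        stop("feature/barcode counts do not match the matrix dimensions")
    dimnames(counts) <- list(feat[[1L]], barcodes)
    assays <- list(counts = counts)
    for (layer in c("spliced", "unspliced")) {
        f <- paste0(layer, ".mtx")
        if (file.exists(file.path(dir, f))) {
            m <- rm_(f)
            if (!identical(dim(m), dim(counts)))
                stop("layer ", f, " dimensions do not match matrix.mtx")
            dimnames(m) <- dimnames(counts)
            assays[[layer]] <- m
        }
    }
    SingleCellExperiment(
        assays = assays,
        colData = DataFrame(barcode = barcodes, row.names = barcodes),
        rowData = DataFrame(gene_id = feat[[1L]],
                            symbol = if (ncol(feat) > 1L) feat[[2L]]
                                     else feat[[1L]],
                            mito = startsWith(feat[[1L]], "MT-"),
                            row.names = feat[[1L]]))
}

#' Write bulk reference profiles as a long-format TSV
#'
#' Columns: \code{gene_id}, \code{label}, \code{replicate}, \code{value}.
#'
#' @param bulk a \linkS4class{BulkProfileSet}.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writeBulkTSV <- function(bulk, file) {
    v <- assay(bulk)
    cd <- colData(bulk)
    long <- do.call(rbind, lapply(seq_len(ncol(v)), function(j)
        data.frame(gene_id = rownames(v), label = cd$label[j],
                   replicate = cd$replicate[j], value = v[, j])))
    utils::write.table(long, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read bulk reference profiles from a long-format TSV
#'
#' @param file TSV with columns \code{gene_id}, \code{label},
#'   \code{replicate}, \code{value}.
#' @return A \linkS4class{BulkProfileSet}.
#' @export
readBulkTSV <- function(file) {
    long <- utils::read.table(file, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    need <- c("gene_id", "label", "replicate", "value")
    if (!all(need %in% colnames(long)))
        stop("bulk TSV must have columns: ", paste(need, collapse = ", "))
    cols <- unique(long[, c("label", "replicate")])
    genes <- unique(long$gene_id)
    v <- matrix(NA_real_, length(genes), nrow(cols),
                dimnames = list(genes, NULL))
    for (j in seq_len(nrow(cols))) {
        sel <- long$label == cols$label[j] &
            long$replicate == cols$replicate[j]
        v[long$gene_id[sel], j] <- long$value[sel]
    }
    if (anyNA(v)) stop("incomplete bulk table: missing gene/column entries")
    BulkProfileSet(v, cols$label, cols$replicate)
}

## per-stage seeds derived from one global seed (kept below 2^31)
.stageSeed <- function(seed, stage) {
    stages <- c(simulate = 1L, qc = 2L, embed = 3L, cluster = 4L,
                markers = 5L, match = 6L, trajectory = 7L, velocity = 8L,
                states = 9L, kinetics = 10L)
    (as.integer(seed) %% 2000000L) * 1000L + stages[[stage]]
}

#' Default pipeline configuration
#'
#' All stage parameters with their defaults; \code{runPipeline} validates
#' user configuration against these keys (unknown keys are rejected).
#'
#' @return Named list of configuration defaults.
#' @export
defaultConfig <- function() {
    list(seed = 1L, out_dir = "symlineage_out",
         simulate = TRUE, sim = list(), counts_dir = NULL, bulk_file = NULL,
         min_umi = 400, max_mito_frac = 0.002, top_quantile = 0.01,
         norm_scale = 1e4, n_hvg = 1000L, n_dims = 20L,
         n_neighbours = 15L, resolution = 1.0,
         transform = "log1p", min_shared_genes = 100L,
         n_ordering_genes = 1000L, velocity_q = 0.05, velocity_k = 30L,
         de_df = 3L, de_sig_q = 0.01, n_modules = 3L, n_states = 5L,
         compute_markers = TRUE,
         kinetics = list(t_max = 19, dt = 0.05))
}

#' Run the full lineage analysis pipeline
#'
#' Chains simulate (optional) -> QC -> normalize -> HVG -> embed -> cluster
#' -> markers -> bulk match -> trajectory -> velocity -> states -> kinetics,
#' writing each stage's artifact as a TSV/JSON-free plain text file under
#' \code{out_dir} and returning all in-memory results. Stage seeds are
#' derived deterministically from the global seed, and the resolved
#' configuration is written beside the outputs.
#'
#' @param config named list overriding entries of \code{\link{defaultConfig}};
#'   unknown keys are an error.
#' @return Invisible list with the stage results (\code{sce}, \code{truth},
#'   \code{bulk}, \code{markers}, \code{nomination}, \code{trajectory},
#'   \code{velocity}, \code{states}, \code{proportions}, \code{chase}).
#' @export
runPipeline <- function(config = list()) {
    cfg <- defaultConfig()
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown))
        stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    cfg[names(config)] <- config
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(cfg, file.path(cfg$out_dir, "resolved_config.yaml"))

    if (isTRUE(cfg$simulate)) {
        sp <- do.call(simParams, c(cfg$sim,
                                   list(seed = .stageSeed(cfg$seed,
                                                          "simulate"))))
        sim <- generateCells(sp)
        sce <- sim$sce
        truth <- sim$truth
        bulk <- generateBulkReferences(sp, truth, sce)
    } else {
        if (is.null(cfg$counts_dir) || is.null(cfg$bulk_file))
            stop("counts_dir and bulk_file are required when simulate=FALSE")
        sce <- read10x(cfg$counts_dir)
        truth <- NULL
        bulk <- readBulkTSV(cfg$bulk_file)
    }

    sce <- qcFilterCells(sce, cfg$min_umi, cfg$max_mito_frac,
                         cfg$top_quantile)
    sce <- normalizeLog(sce, cfg$norm_scale)
    sce <- selectHVG(sce, cfg$n_hvg)
    sce <- jointEmbedding(sce, cfg$n_dims)
    sce <- clusterCells(sce, cfg$n_neighbours, cfg$resolution,
                        seed = .stageSeed(cfg$seed, "cluster"))

    profiles <- clusterMeanProfiles(sce)
    cm <- correlateClusterBulk(profiles, bulk, cfg$transform,
                               cfg$min_shared_genes)
    nom <- nominateEndosymbiotic(cm)
    endo_cells <- colnames(sce)[colData(sce)$cluster == nom$cluster]

    markers <- if (isTRUE(cfg$compute_markers))
        computeMarkers(sce, clusters = nom$cluster) else NULL

    genes <- selectOrderingGenes(sce, endo_cells,
                                 n_genes = cfg$n_ordering_genes)
    traj <- fitTrajectory(sce, endo_cells, genes)
    vm <- fitGamma(sce, endo_cells, coords = traj@coords,
                   q = cfg$velocity_q, k_smooth = cfg$velocity_k)
    traj <- orientPseudotime(traj, vm)

    de <- pseudotimeDETest(sce, traj, df = cfg$de_df, genes = genes,
                           sig_q = cfg$de_sig_q)
    sig <- de$gene[de$significant]
    if (length(sig) < cfg$n_modules) sig <- de$gene[order(de$q)][1:50]
    sm_grid <- smoothCurves(sce, traj, sig)
    modules <- clusterGeneModules(sm_grid, cfg$n_modules)
    pc <- perCellBulkCorrelation(sce, bulk, endo_cells, cfg$transform)
    states <- segmentStates(sce, traj, modules, pc, sm_grid,
                            K = cfg$n_states)
    conds <- stats::setNames(colData(sce)$condition, colnames(sce))
    props <- stateProportions(states, conds)

    chase <- simulatePulseChase(kineticModel(), t_max = cfg$kinetics$t_max,
                                dt = cfg$kinetics$dt)

    ## ---- artifacts --------------------------------------------------------
    wt <- function(df, f) utils::write.table(
        df, file.path(cfg$out_dir, f), sep = "\t", quote = FALSE,
        row.names = FALSE)
    wt(data.frame(cell = names(pseudotime(traj)),
                  pseudotime = unname(pseudotime(traj)),
                  state = unname(stateLabels(states)[names(pseudotime(traj))]),
                  condition = conds[names(pseudotime(traj))]),
       "states.tsv")
    wt(data.frame(gene = names(gammaHat(vm)),
                  gamma = unname(gammaHat(vm))), "velocity.tsv")
    wt(as.data.frame.matrix(props), "state_proportions.tsv")
    wt(data.frame(gene = names(modules), module = unname(modules)),
       "gene_modules.tsv")
    if (!is.null(markers))
        writeMarkerTable(markers, file.path(cfg$out_dir, "markers.tsv"))
    wt(data.frame(time = chase@time,
                  labelled_alga_fraction = labelledAlgaFraction(chase),
                  alga_fraction = algaFraction(chase)), "pulse_chase.tsv")

    invisible(list(sce = sce, truth = truth, bulk = bulk,
                   correlation = cm, nomination = nom, markers = markers,
                   trajectory = traj, velocity = vm, de = de,
                   modules = modules, states = states, proportions = props,
                   chase = chase, config = cfg))
}
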