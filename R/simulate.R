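#' Parameters for the synthetic coral scRNA-seq generator
#'
#' Bundles and validates all generator settings. Defaults emulate the study
#' conditions of a soft-coral cell atlas: 16 cell types of which one rare
#' (~1.5%) endosymbiotic type carries a latent five-state linear trajectory;
#' two sequencing batches with median UMI targets of 801 (v2-like chemistry)
#' and 2,027 (v3-like); regeneration enriched for early lineage states and
#' homeostasis for late ones; and spliced/unspliced layers drawn from a
#' two-stage transcription/splicing/degradation kinetic model.
#'
#' The kinetic model runs in "kinetic time" tau = t * time_scale where t is
#' pseudotime in [0, 1], with the splicing rate beta fixed at 1 per kinetic
#' unit so that the per-gene degradation rate gamma equals the steady-state
#' slope of unspliced on spliced expression.
#'
#' @param n_genes number of genes.
#' @param n_types number of cell types; the last type is the endosymbiotic one.
#' @param rare_type_freq frequency of the endosymbiotic type in (0, 1).
#' @param n_cells_per_batch cells drawn per batch.
#' @param batch_depth_medians named numeric, target median UMI per batch.
#' @param batch_conditions named character, condition of each batch
#'   (\code{"regeneration"} or \code{"homeostasis"}).
#' @param state_mix named list of 5-simplex state proportions per condition.
#' @param n_dynamic_genes trajectory-responsive genes per module
#'   (early/mid/late).
#' @param n_type_markers dedicated marker genes per cell type.
#' @param type_marker_fold expression fold change of a marker in its type.
#' @param alpha_on peak transcription-rate multiplier of dynamic genes
#'   relative to their basal rate.
#' @param beta splicing rate per kinetic time unit (fixed convention: 1).
#' @param gamma_meanlog,gamma_sdlog log-normal parameters of the per-gene
#'   degradation rate gamma (per kinetic time unit).
#' @param time_scale kinetic time units spanned by pseudotime [0, 1].
#' @param dispersion negative-binomial overdispersion (NB size = 1/dispersion).
#' @param depth_sdlog log-normal spread of per-cell library size within batch.
#' @param n_mito number of genes flagged as mitochondrial ("MT-" prefix).
#' @param mito_frac expected fraction of counts from mitochondrial genes.
#' @param seed integer seed.
#' @return A validated list of class \code{"SimParams"}.
#' @examples
#' p <- simParams(n_genes = 200, n_cells_per_batch = 50)
#' @export
simParams <- function(n_genes = 2000L, n_types = 16L, rare_type_freq = 0.015,
                      n_cells_per_batch = 3000L,
                      batch_depth_medians = c(v2 = 801, v3 = 2027),
                      batch_conditions = c(v2 = "homeostasis",
                                           v3 = "regeneration"),
                      state_mix = list(
                          regeneration = c(0.25, 0.35, 0.25, 0.10, 0.05),
                          homeostasis  = c(0.05, 0.15, 0.45, 0.20, 0.15)),
                      n_dynamic_genes = 60L, n_type_markers = 40L,
                      type_marker_fold = 6, alpha_on = 6, beta = 1,
                      gamma_meanlog = log(0.5), gamma_sdlog = 0.4,
                      time_scale = 25, dispersion = 0.5,
                      depth_sdlog = 0.35, n_mito = 10L, mito_frac = 0.0005,
                      seed = 1L) {
    p <- list(n_genes = as.integer(n_genes), n_types = as.integer(n_types),
              rare_type_freq = rare_type_freq,
              n_cells_per_batch = as.integer(n_cells_per_batch),
              batch_depth_medians = batch_depth_medians,
              batch_conditions = batch_conditions, state_mix = state_mix,
              n_dynamic_genes = as.integer(n_dynamic_genes),
              n_type_markers = as.integer(n_type_markers),
              type_marker_fold = type_marker_fold, alpha_on = alpha_on,
              beta = beta, gamma_meanlog = gamma_meanlog,
              gamma_sdlog = gamma_sdlog, time_scale = time_scale,
              dispersion = dispersion, depth_sdlog = depth_sdlog,
              n_mito = as.integer(n_mito), mito_frac = mito_frac,
              seed = as.integer(seed))
    if (p$n_genes < 1L || p$n_types < 2L || p$n_cells_per_batch < 1L)
        stop("dimensions must be positive")
    if (p$rare_type_freq <= 0 || p$rare_type_freq >= 1)
        stop("rare_type_freq must be in (0, 1)")
    if (length(batch_depth_medians) < 1L ||
        !identical(names(batch_depth_medians), names(batch_conditions)))
        stop("batch_depth_medians and batch_conditions must share batch names")
    if (!all(batch_conditions %in% names(state_mix)))
        stop("every batch condition needs an entry in state_mix")
    for (mx in state_mix) {
        if (length(mx) != 5L || any(mx < 0) || abs(sum(mx) - 1) > 1e-9)
            stop("state_mix entries must be 5-simplex vectors summing to 1")
    }
    if (p$alpha_on <= 0 || p$beta <= 0 || p$time_scale <= 0 ||
        p$dispersion <= 0)
        stop("rates and dispersion must be strictly positive")
    reserved <- p$n_types * p$n_type_markers + 3L * p$n_dynamic_genes +
        p$n_mito
    if (reserved > p$n_genes)
        stop("n_genes too small for the requested marker/dynamic/mito genes")
    class(p) <- "SimParams"
    p
}

## state-wise transcription-rate multipliers: each dynamic module is
## preferentially transcribed in its home states (early: 1-2, mid: 3,
## late: 4-5), with a geometric-mean shoulder in the adjacent state.
.alphaMultipliers <- function(alpha_on) {
    sh <- sqrt(alpha_on)
    rbind(early = c(alpha_on, sh, 1, 1, 1),
          mid   = c(1, sh, alpha_on, sh, 1),
          late  = c(1, 1, 1, sh, alpha_on))
}

## alpha(t) for a "switch" gene: plateaus at the state level within each
## state, connected by linear ramps of half-width `ramp` across the state
## boundaries. Plateaus make the states detectable as expression change
## points along pseudotime.
.alphaSwitch <- function(t, module, alpha_on, ramp = 0.04) {
    lv <- .alphaMultipliers(alpha_on)[module, ]
    out <- lv[pmin(pmax(ceiling(t * 5), 1L), 5L)]
    for (b in 1:4) {
        x <- b / 5
        in_ramp <- t > x - ramp & t < x + ramp
        if (any(in_ramp)) {
            w <- (t[in_ramp] - (x - ramp)) / (2 * ramp)
            out[in_ramp] <- lv[b] * (1 - w) + lv[b + 1L] * w
        }
    }
    out
}

## alpha(t) for a "graded" gene: smooth Gaussian activation peaking in the
## module's home region. Graded genes carry the continuous maturation
## gradient that makes within-state ordering (and sustained RNA-velocity
## disequilibrium) possible.
.alphaGraded <- function(t, module, alpha_on, width = 0.18) {
    peak <- c(early = 0.1, mid = 0.5, late = 0.9)[module]
    1 + (alpha_on - 1) * exp(-0.5 * ((t - peak) / width)^2)
}

## real lineage transcriptomes mix both kinds; kind is per gene
.alphaProfile <- function(t, module, alpha_on, kind = "switch") {
    if (kind == "graded") .alphaGraded(t, module, alpha_on)
    else .alphaSwitch(t, module, alpha_on)
}

#' Expected unspliced/spliced surfaces of the dynamic genes
#'
#' Integrates du/dtau = alpha(tau) - beta u, ds/dtau = beta u - gamma s for
#' every dynamic gene over pseudotime [0, 1] (tau = t * time_scale), starting
#' from the steady state of the initial transcription rate. Surfaces are
#' scaled so that the basal total expression (u + s) of gene g equals
#' \code{lambda[g]}.
#'
#' @param gamma numeric, per-gene degradation rates.
#' @param module character, \code{"early"}/\code{"mid"}/\code{"late"} per gene.
#' @param lambda numeric, basal relative expression per gene.
#' @param params a \code{\link{simParams}} object.
#' @param kind character per gene, \code{"graded"} (smooth activation bump)
#'   or \code{"switch"} (state-plateau program).
#' @param n_grid number of pseudotime grid points.
#' @return List with \code{t} (grid), and genes x grid matrices \code{u},
#'   \code{s}.
#' @examples
#' p <- simParams(n_genes = 200, n_cells_per_batch = 50)
#' g <- dynamicExpectationGrid(c(0.5, 0.8), c("early", "late"), c(1, 1), p)
#' @export
dynamicExpectationGrid <- function(gamma, module, lambda, params,
                                   kind = rep("switch", length(gamma)),
                                   n_grid = 201L) {
    tgrid <- seq(0, 1, length.out = n_grid)
    G <- length(gamma)
    beta <- params$beta
    ## basal alpha so that basal u + s = lambda at steady state:
    ## u_ss = a/beta, s_ss = a/gamma  =>  a = lambda / (1/beta + 1/gamma)
    a0 <- lambda / (1 / beta + 1 / gamma)
    amp <- t(vapply(seq_len(G), function(i)
        .alphaProfile(tgrid, module[i], alpha_on = params$alpha_on,
                      kind = kind[i]),
        numeric(n_grid)))
    alpha <- a0 * amp
    u <- matrix(0, G, n_grid)
    s <- matrix(0, G, n_grid)
    u[, 1] <- alpha[, 1] / beta
    s[, 1] <- alpha[, 1] / gamma
    h <- params$time_scale / (n_grid - 1L)  # kinetic-time step
    for (j in seq_len(n_grid - 1L)) {
        ## RK4 with alpha interpolated linearly between grid points
        a1 <- alpha[, j]; a2 <- alpha[, j + 1L]; am <- (a1 + a2) / 2
        uj <- u[, j]; sj <- s[, j]
        f <- function(a, uu, ss) list(du = a - beta * uu,
                                      ds = beta * uu - gamma * ss)
        k1 <- f(a1, uj, sj)
        k2 <- f(am, uj + h / 2 * k1$du, sj + h / 2 * k1$ds)
        k3 <- f(am, uj + h / 2 * k2$du, sj + h / 2 * k2$ds)
        k4 <- f(a2, uj + h * k3$du, sj + h * k3$ds)
        u[, j + 1L] <- uj + h / 6 * (k1$du + 2 * k2$du + 2 * k3$du + k4$du)
        s[, j + 1L] <- sj + h / 6 * (k1$ds + 2 * k2$ds + 2 * k3$ds + k4$ds)
    }
    list(t = tgrid, u = u, s = s)
}

#' Generate a synthetic coral cell atlas with ground truth
#'
#' Draws a multi-batch UMI count matrix with spliced and unspliced layers
#' (convention: total = spliced + unspliced, a velocyto-style intron/exon
#' partition) plus per-cell and per-gene ground truth. Counts are negative
#' binomial (Gamma-Poisson) around expected expression; library sizes are
#' log-normal within batch and calibrated so the expected per-batch median
#' UMI hits the batch target. Cells of the rare endosymbiotic type are placed
#' on a latent five-state trajectory with state mixtures depending on
#' condition, and their dynamic genes follow the two-stage kinetic model.
#'
#' @param params a \code{\link{simParams}} object.
#' @return List with \code{sce}, a \linkS4class{SingleCellExperiment}
#'   (assays \code{counts}, \code{spliced}, \code{unspliced}; colData
#'   \code{barcode}, \code{batch}, \code{condition}), and \code{truth}, a
#'   list of \code{cells} and \code{genes} \code{DataFrame}s.
#' @examples
#' sim <- generateCells(simParams(n_genes = 300, n_cells_per_batch = 80,
#'                                n_type_markers = 8, n_dynamic_genes = 10))
#' sim$sce
#' @export
generateCells <- function(params) {
    stopifnot(inherits(params, "SimParams"))
    set.seed(params$seed)
    ng <- params$n_genes
    nt <- params$n_types

    ## ---- gene table -------------------------------------------------------
    gene_id <- sprintf("gene%05d", seq_len(ng))
    mito <- seq_len(params$n_mito)
    gene_id[mito] <- sprintf("MT-gene%05d", mito)
    lambda <- stats::rlnorm(ng, meanlog = 0, sdlog = 1)
    ## calibrate mitochondrial share of the expected transcriptome
    lambda[mito] <- lambda[mito] / sum(lambda[mito]) *
        params$mito_frac * sum(lambda[-mito])
    gamma <- stats::rlnorm(ng, params$gamma_meanlog, params$gamma_sdlog)

    pool <- setdiff(seq_len(ng), mito)
    marker_sets <- vector("list", nt)
    for (k in seq_len(nt)) {
        marker_sets[[k]] <- sample(pool, params$n_type_markers)
        pool <- setdiff(pool, marker_sets[[k]])
    }
    modules <- c("early", "mid", "late")
    dyn_sets <- stats::setNames(vector("list", 3L), modules)
    for (m in modules) {
        dyn_sets[[m]] <- sample(pool, params$n_dynamic_genes)
        pool <- setdiff(pool, dyn_sets[[m]])
    }
    dyn_idx <- unlist(dyn_sets, use.names = FALSE)
    dyn_module <- rep(modules, each = params$n_dynamic_genes)
    ## half of each module graded (continuous maturation), half switch-like
    ## (state-plateau program), as in real lineage transcriptomes
    dyn_kind <- rep(rep_len(c("graded", "switch"), params$n_dynamic_genes),
                    3L)

    gene_module <- rep("static", ng)
    gene_module[dyn_idx] <- dyn_module
    gene_kind <- rep(NA_character_, ng)
    gene_kind[dyn_idx] <- dyn_kind
    marker_of <- rep(NA_integer_, ng)
    for (k in seq_len(nt)) marker_of[marker_sets[[k]]] <- k

    surf <- dynamicExpectationGrid(gamma[dyn_idx], dyn_module,
                                   lambda[dyn_idx], params, kind = dyn_kind)

    ## ---- cell table -------------------------------------------------------
    batches <- names(params$batch_depth_medians)
    nb <- length(batches)
    n_total <- params$n_cells_per_batch * nb
    batch <- rep(batches, each = params$n_cells_per_batch)
    condition <- params$batch_conditions[batch]
    type_probs <- c(rep((1 - params$rare_type_freq) / (nt - 1L), nt - 1L),
                    params$rare_type_freq)
    type <- sample.int(nt, n_total, replace = TRUE, prob = type_probs)
    endo <- which(type == nt)
    state <- rep(NA_integer_, n_total)
    true_t <- rep(NA_real_, n_total)
    for (i in endo) {
        mx <- params$state_mix[[condition[i]]]
        s <- sample.int(5L, 1L, prob = mx)
        state[i] <- s
        true_t[i] <- stats::runif(1L, (s - 1L) / 5, s / 5)
    }

    ## ---- expected expression ---------------------------------------------
    rho <- matrix(lambda, ng, n_total)            # relative expression
    ushare <- matrix(gamma / (params$beta + gamma), ng, n_total)
    for (k in seq_len(nt)) {
        cells_k <- which(type == k)
        rho[marker_sets[[k]], cells_k] <-
            rho[marker_sets[[k]], cells_k] * params$type_marker_fold
    }
    if (length(endo)) {
        ## dynamic genes in endosymbiotic cells follow the kinetic surfaces
        gi <- findInterval(true_t[endo], surf$t, all.inside = TRUE)
        w <- (true_t[endo] - surf$t[gi]) / diff(surf$t)[1]
        uE <- surf$u[, gi] * rep(1 - w, each = length(dyn_idx)) +
            surf$u[, gi + 1L] * rep(w, each = length(dyn_idx))
        sE <- surf$s[, gi] * rep(1 - w, each = length(dyn_idx)) +
            surf$s[, gi + 1L] * rep(w, each = length(dyn_idx))
        rho[dyn_idx, endo] <- uE + sE
        ushare[dyn_idx, endo] <- uE / (uE + sE)
    }

    ## ---- depth calibration and sampling ----------------------------------
    depth <- numeric(n_total)
    for (b in batches) {
        cells_b <- which(batch == b)
        f <- stats::rlnorm(length(cells_b), 0, params$depth_sdlog)
        depth[cells_b] <- params$batch_depth_medians[[b]] * f /
            stats::median(f)
    }
    mu <- rho * rep(depth / colSums(rho), each = ng)
    size <- 1 / params$dispersion
    spliced <- matrix(stats::rnbinom(ng * n_total, size = size,
                                     mu = mu * (1 - ushare)), ng, n_total)
    unspliced <- matrix(stats::rnbinom(ng * n_total, size = size,
                                       mu = mu * ushare), ng, n_total)
    counts <- spliced + unspliced

    barcode <- sprintf("%s-cell%05d", batch, seq_len(n_total))
    dimnames(counts) <- dimnames(spliced) <- dimnames(unspliced) <-
        list(gene_id, barcode)
    asS <- function(m) methods::as(m, "CsparseMatrix")
    sce <- SingleCellExperiment(
        assays = list(counts = asS(counts), spliced = asS(spliced),
                      unspliced = asS(unspliced)),
        colData = DataFrame(barcode = barcode, batch = batch,
                            condition = unname(condition),
                            row.names = barcode),
        rowData = DataFrame(gene_id = gene_id, symbol = gene_id,
                            mito = seq_len(ng) %in% mito,
                            row.names = gene_id))
    truth <- list(
        cells = DataFrame(barcode = barcode, type = type, state = state,
                          pseudotime = true_t, condition = unname(condition),
                          batch = batch, row.names = barcode),
        genes = DataFrame(gene_id = gene_id, module = gene_module,
                          kind = gene_kind, marker_of = marker_of,
                          gamma_true = gamma, row.names = gene_id))
    list(sce = sce, truth = truth)
}

#' Generate bulk reference profiles from sorted synthetic populations
#'
#' Emulates bulk RNA-seq of FACS-sorted alga-containing and alga-free cells.
#' The alga-containing profile is a weighted mixture of the state-2/3/4
#' pseudo-bulk profiles (weight peaking at state 3); the alga-free profile
#' mixes all non-endosymbiotic cell types with a contamination fraction of
#' state-1/5 cells. Profiles are scaled to counts-per-million (an RPKM-like
#' positive scale) and multiplied by per-gene log-normal replicate noise.
#'
#' @param params a \code{\link{simParams}} object (supplies the seed).
#' @param truth ground truth from \code{\link{generateCells}}.
#' @param sce the matching \linkS4class{SingleCellExperiment}.
#' @param state_weights weights over states 2, 3, 4 for the positive profile.
#' @param contamination fraction of state-1/5 signal in the negative profile.
#' @param noise_sdlog log-normal replicate noise (0 gives exact mixtures).
#' @param n_replicates replicates per label.
#' @return A \linkS4class{BulkProfileSet} with \code{n_replicates} columns
#'   per label.
#' @examples
#' sim <- generateCells(simParams(n_genes = 300, n_cells_per_batch = 200,
#'                                n_type_markers = 8, n_dynamic_genes = 10,
#'                                rare_type_freq = 0.1))
#' generateBulkReferences(simParams(n_genes = 300), sim$truth, sim$sce)
#' @export
generateBulkReferences <- function(params, truth, sce,
                                   state_weights = c(0.2, 0.6, 0.2),
                                   contamination = 0.1, noise_sdlog = 0.2,
                                   n_replicates = 2L) {
    stopifnot(inherits(params, "SimParams"))
    ct <- truth$cells
    if (!identical(rownames(ct), colnames(sce)))
        stop("truth and counts are not aligned")
    endo <- which(ct$type == max(ct$type))
    if (!length(endo) || all(is.na(ct$state)))
        stop("no endosymbiotic cells in truth; cannot build references")
    set.seed(params$seed + 1L)
    cnt <- assay(sce, "counts")
    cpm <- function(x) x / sum(x) * 1e6
    stateBulk <- function(s) {
        idx <- which(!is.na(ct$state) & ct$state == s)
        if (!length(idx)) return(NULL)
        cpm(Matrix::rowMeans(cnt[, idx, drop = FALSE]))
    }
    pos_states <- 2:4
    pbs <- lapply(pos_states, stateBulk)
    keep <- !vapply(pbs, is.null, logical(1))
    if (!any(keep)) stop("no cells in states 2-4; cannot build references")
    if (!all(keep)) warning("empty states among 2-4; weights renormalized")
    w <- state_weights[keep] / sum(state_weights[keep])
    pos_mean <- Reduce(`+`, Map(`*`, pbs[keep], w))

    other <- which(ct$type != max(ct$type))
    neg_core <- cpm(Matrix::rowMeans(cnt[, other, drop = FALSE]))
    edge <- which(!is.na(ct$state) & ct$state %in% c(1L, 5L))
    neg_mean <- if (length(edge)) {
        (1 - contamination) * neg_core +
            contamination * cpm(Matrix::rowMeans(cnt[, edge, drop = FALSE]))
    } else neg_core

    ng <- nrow(cnt)
    reps <- function(mean_prof) vapply(seq_len(n_replicates), function(r)
        mean_prof * stats::rlnorm(ng, 0, noise_sdlog), numeric(ng))
    values <- cbind(reps(pos_mean), reps(neg_mean))
    rownames(values) <- rownames(cnt)
    BulkProfileSet(values,
                   label = rep(c("alga_pos", "alga_neg"),
                               each = n_replicates),
                   replicate = rep(seq_len(n_replicates), 2L))
}
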