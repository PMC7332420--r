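## negative-binomial Pearson residuals of raw counts over a cell subset
## (cells x genes). The null model is a constant gene rate times the cell
## library size, so depth differences between chemistries are handled
## exactly; theta is a fixed moderate overdispersion (residuals are
## insensitive to it at shallow depth). Residuals are clipped at
## +/- sqrt(n cells), the standard guard against single-cell leverage.
.pearsonResiduals <- function(sce, cells, genes, theta = 10) {
    y <- as.matrix(assay(sce, "counts")[genes, cells, drop = FALSE])
    N <- Matrix::colSums(assay(sce, "counts")[, cells, drop = FALSE])
    pi_g <- rowSums(y) / sum(N)
    mu <- outer(pi_g, N)
    pr <- (y - mu) / sqrt(mu + mu^2 / theta)
    pr[!is.finite(pr)] <- 0
    clip <- sqrt(length(cells))
    t(pmin(pmax(pr, -clip), clip))
}

## PCA of centred Pearson residuals over a cell subset, with the
## component-sign convention of jointEmbedding. Genes enter with their
## natural residual variance, so trajectory-responsive genes dominate the
## leading components.
.subsetPCA <- function(sce, cells, genes, d, theta = 10) {
    x <- .pearsonResiduals(sce, cells, genes, theta)
    x <- scale(x, center = TRUE, scale = FALSE)
    x[, !is.finite(colSums(x))] <- 0
    cov <- crossprod(x) / max(1L, nrow(x) - 1L)
    eig <- eigen(cov, symmetric = TRUE)
    d <- min(d, ncol(x))
    V <- eig$vectors[, seq_len(d), drop = FALSE]
    for (j in seq_len(d)) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    scores <- x %*% V
    dimnames(scores) <- list(cells, paste0("PC", seq_len(d)))
    scores
}

#' Select trajectory ordering genes by subcluster contrast
#'
#' Subclusters the endosymbiotic subset with hierarchical modularity
#' community detection on a kNN graph built in a subset-specific principal
#' component space of Pearson residuals, requesting \code{n_request} groups
#' and accepting the realized number. Genes are then ranked by a one-way
#' Kruskal-Wallis rank test of their Pearson residuals across subclusters
#' and the top \code{n_genes} by p-value (ties by statistic) are returned.
#' If only one subcluster is realized, genes are ranked by dispersion
#' instead, with a warning.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{counts} and
#'   \code{logcounts}.
#' @param cells identifiers of the endosymbiotic subset (>= 30 cells).
#' @param n_request subclusters requested from the dendrogram cut.
#' @param n_genes number of ordering genes to return.
#' @param n_neighbours neighbours for the subcluster kNN graph.
#' @param d dimensions of the subcluster reduction.
#' @return Character vector of ordering genes; the realized subcluster
#'   labels are attached as \code{attr(, "subclusters")}.
#' @export
selectOrderingGenes <- function(sce, cells, n_request = 4L, n_genes = 1000L,
                                n_neighbours = 10L, d = 10L) {
    if (length(cells) < 30L) stop("need at least 30 cells")
    red_genes <- if ("hvg" %in% colnames(rowData(sce)) &&
                     any(rowData(sce)$hvg))
        rownames(sce)[rowData(sce)$hvg] else rownames(sce)
    coords <- .subsetPCA(sce, cells, red_genes, d)
    g <- .knnGraph(coords, n_neighbours)
    fg <- igraph::cluster_fast_greedy(g)
    memb <- tryCatch(igraph::cut_at(fg, no = n_request),
                     error = function(e) igraph::membership(fg))
    memb <- as.integer(memb)
    x <- t(.pearsonResiduals(sce, cells, rownames(sce)))
    if (length(unique(memb)) < 2L) {
        warning("single subcluster realized; ranking genes by dispersion")
        lx <- as.matrix(assay(sce, "logcounts")[, cells, drop = FALSE])
        mu <- rowMeans(lx)
        disp <- ifelse(mu > 0, apply(lx, 1L, stats::var) / mu, 0)
        ord <- order(-disp)
    } else {
        kw <- t(vapply(seq_len(nrow(x)), function(i) {
            xi <- x[i, ]
            if (all(xi == xi[1L])) return(c(0, 1))
            h <- stats::kruskal.test(xi, factor(memb))
            c(h$statistic, h$p.value)
        }, numeric(2)))
        ord <- order(kw[, 2L], -kw[, 1L])
    }
    out <- rownames(x)[ord[seq_len(min(n_genes, nrow(x)))]]
    attr(out, "subclusters") <- stats::setNames(memb, cells)
    out
}

#' Two-dimensional reduction of a cell subset on ordering genes
#'
#' Principal component scores (first two) of the centred negative-binomial
#' Pearson residuals of the ordering genes -- the coordinate space in which
#' the principal curve is fitted. The residual null model (constant gene
#' rate times library size) absorbs the sequencing-depth effect that
#' separates batches of different chemistry, without touching composition
#' differences between conditions. Genes keep their natural residual
#' variance so trajectory-responsive genes dominate.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{counts}.
#' @param cells cell subset.
#' @param genes ordering genes.
#' @return Cells x 2 score matrix.
#' @export
reduceForTrajectory <- function(sce, cells, genes) {
    .subsetPCA(sce, cells, genes, 2L)
}

## project points onto a polyline; returns arc-length positions and the
## projected points
.projectPolyline <- function(points, nodes) {
    nseg <- nrow(nodes) - 1L
    a <- nodes[-nrow(nodes), , drop = FALSE]
    d <- nodes[-1L, , drop = FALSE] - a
    len2 <- pmax(rowSums(d^2), 1e-300)
    seg_start <- c(0, cumsum(sqrt(rowSums(d^2))))
    n <- nrow(points)
    lambda <- numeric(n)
    proj <- matrix(0, n, ncol(points))
    for (i in seq_len(n)) {
        p <- points[i, ]
        tt <- (sweep(a, 2L, p, function(x, y) y - x) * d)
        tt <- pmin(pmax(rowSums(tt) / len2, 0), 1)
        cand <- a + d * tt
        dist2 <- rowSums(sweep(cand, 2L, p)^2)
        j <- which.min(dist2)
        lambda[i] <- seg_start[j] + tt[j] * sqrt(len2[j])
        proj[i, ] <- cand[j, ]
    }
    list(lambda = lambda, proj = proj)
}

#' Fit a principal curve through 2-D coordinates
#'
#' Iterative principal-curve procedure: initialize arc positions by the
#' first principal component, smooth each coordinate against arc length
#' (lowess), rebuild the polyline on an even arc grid, re-project the points,
#' and repeat until the mean projection displacement falls below \code{tol}.
#' Pseudotime is the min-max scaled arc length of each cell's projection.
#' Collinear points are a fixed point of the procedure (recovered exactly in
#' one iteration), and duplicated points leave the curve unchanged.
#'
#' @param coords cells x 2 coordinate matrix (rownames are cell ids).
#' @param max_iter maximum iterations.
#' @param tol convergence threshold on the mean projection displacement,
#'   relative to the coordinate scale.
#' @param n_nodes number of polyline nodes.
#' @param smooth_f lowess smoother span (fraction of points in each local fit).
#' @return An unoriented \linkS4class{Trajectory}.
#' @examples
#' xy <- cbind(seq(0, 1, length.out = 40), 0)
#' rownames(xy) <- paste0("c", 1:40)
#' fitPrincipalCurve(xy)
#' @export
fitPrincipalCurve <- function(coords, max_iter = 50L, tol = 1e-4,
                              n_nodes = 100L, smooth_f = 0.5) {
    if (nrow(coords) < 10L) stop("need at least 10 cells")
    if (ncol(coords) != 2L) stop("coords must be 2-D")
    cells <- rownames(coords)
    if (is.null(cells)) cells <- as.character(seq_len(nrow(coords)))
    ctr <- colMeans(coords)
    xc <- sweep(coords, 2L, ctr)
    v1 <- eigen(crossprod(xc), symmetric = TRUE)$vectors[, 1L]
    lambda <- as.vector(xc %*% v1)
    scale0 <- max(apply(coords, 2L, function(z) max(z) - min(z)), 1e-12)
    proj_old <- NULL
    converged <- FALSE
    nodes <- NULL
    for (iter in seq_len(max_iter)) {
        ord <- order(lambda)
        lo <- lambda[ord]
        ## smooth each coordinate against current arc position
        fit <- vapply(1:2, function(j)
            stats::lowess(lo, coords[ord, j], f = smooth_f)$y,
            numeric(length(lo)))
        ## resample the smoothed path on an even grid of arc positions
        grid <- seq(lo[1L], lo[length(lo)], length.out = n_nodes)
        nodes <- vapply(1:2, function(j)
            stats::approx(lo, fit[, j], xout = grid, ties = mean)$y,
            numeric(n_nodes))
        nodes <- nodes[!duplicated(nodes[, 1L]) |
                           !duplicated(nodes[, 2L]), , drop = FALSE]
        if (nrow(nodes) < 2L)
            nodes <- rbind(nodes, nodes + 1e-9)
        pr <- .projectPolyline(coords, nodes)
        lambda <- pr$lambda
        if (!is.null(proj_old)) {
            disp <- mean(sqrt(rowSums((pr$proj - proj_old)^2))) / scale0
            if (disp < tol) { converged <- TRUE }
        }
        proj_old <- pr$proj
        if (converged) break
    }
    rng <- range(lambda)
    pt <- if (diff(rng) > 0) (lambda - rng[1L]) / diff(rng)
          else rep(0, length(lambda))
    if (!converged)
        warning("principal curve did not converge in ", max_iter,
                " iterations; returning best iterate")
    new("Trajectory", cells = cells, coords = unname(coords), nodes = nodes,
        lambda = lambda, pseudotime = stats::setNames(pt, cells),
        orientation = NA_integer_, confidence = NA_real_,
        orderingGenes = character(), converged = converged)
}

#' Fit a refined principal-curve trajectory for a cell subset
#'
#' Convenience wrapper around \code{\link{reduceForTrajectory}} and
#' \code{\link{fitPrincipalCurve}} with an ordering-gene refinement: after an
#' initial reduction, genes are re-ranked by an F-test of a natural-spline
#' fit against the provisional ordering (on Pearson residuals, within the
#' ordering genes) and the reduction is rebuilt from the top \code{refine_n}
#' genes; the curve is then fitted once on the refined space. Refinement
#' sharpens the 2-D space when many ordering genes carry no trajectory
#' signal.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{logcounts}.
#' @param cells cell subset.
#' @param genes ordering genes from \code{\link{selectOrderingGenes}}.
#' @param refine_rounds refinement iterations (0 disables).
#' @param refine_n genes kept per refinement round.
#' @param ... passed to \code{\link{fitPrincipalCurve}}.
#' @return A \linkS4class{Trajectory} (unoriented) whose \code{coords} are
#'   the final reduction; the genes of the final reduction are in
#'   \code{orderingGenes}.
#' @export
fitTrajectory <- function(sce, cells, genes, refine_rounds = 2L,
                          refine_n = 300L, ...) {
    coords <- reduceForTrajectory(sce, cells, genes)
    use <- genes
    if (refine_rounds > 0L && length(genes) > refine_n) {
        xr <- .pearsonResiduals(sce, cells, genes)
        n <- length(cells)
        rss0 <- colSums(scale(xr, scale = FALSE)^2)
        for (r in seq_len(refine_rounds)) {
            ## provisional ordering: first component of the current
            ## reduction (robust against curve folding in noisy clouds)
            pt <- rank(coords[, 1L]) / n
            B <- splines::ns(pt, df = 3L)
            fit <- stats::lm.fit(cbind(1, B), xr)
            rss1 <- colSums(fit$residuals^2)
            Fst <- ((rss0 - rss1) / 3) / (rss1 / pmax(n - 5L, 1L))
            use <- genes[order(-Fst)[seq_len(refine_n)]]
            coords <- reduceForTrajectory(sce, cells, use)
        }
    }
    traj <- fitPrincipalCurve(coords, ...)
    traj@orderingGenes <- use
    traj
}

## kNN pooling of a genes x cells matrix in an embedding (self included)
.knnPool <- function(mat, coords, k) {
    k <- min(k, nrow(coords) - 1L)
    nn <- BiocNeighbors::findKNN(coords, k = k)
    idx <- cbind(seq_len(nrow(coords)), nn$index)
    out <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
    for (i in seq_len(ncol(mat)))
        out[, i] <- Matrix::rowMeans(mat[, idx[i, ], drop = FALSE])
    out
}

#' Fit per-gene degradation ratios from spliced/unspliced layers
#'
#' Steady-state velocity model: for each gene, the degradation ratio
#' \eqn{\hat\gamma} is the slope of a zero-intercept regression of
#' (smoothed) unspliced on spliced expression restricted to cells in the
#' extreme spliced quantiles (below q or above 1-q), where the steady-state
#' assumption is most defensible. The residual velocity is
#' \eqn{v = u - \hat\gamma s} for every cell. Layers are pooled over
#' \code{k_smooth} nearest neighbours in the embedding before fitting.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{spliced} and
#'   \code{unspliced} assays.
#' @param cells cell subset to fit on.
#' @param coords cells x d embedding used for neighbour smoothing (defaults
#'   to the \code{"PCA"} reduced dimension restricted to \code{cells}).
#' @param q extreme-quantile fraction.
#' @param k_smooth neighbours for layer pooling; 0 disables smoothing.
#' @param min_detect minimum fraction of subset cells with spliced signal.
#' @return A \linkS4class{VelocityModel} over the genes passing the filter.
#' @export
fitGamma <- function(sce, cells, coords = NULL, q = 0.05, k_smooth = 30L,
                     min_detect = 0.05) {
    if (!all(c("spliced", "unspliced") %in%
             SummarizedExperiment::assayNames(sce)))
        stop("spliced and unspliced assays are required")
    s <- as.matrix(assay(sce, "spliced")[, cells, drop = FALSE])
    u <- as.matrix(assay(sce, "unspliced")[, cells, drop = FALSE])
    detected <- rowMeans(s > 0) >= min_detect & rowSums(s) > 0
    s <- s[detected, , drop = FALSE]
    u <- u[detected, , drop = FALSE]
    if (!nrow(s)) stop("no genes pass the expression filter")
    if (k_smooth > 0L) {
        if (is.null(coords))
            coords <- SingleCellExperiment::reducedDim(sce, "PCA")[cells, ,
                                                                   drop = FALSE]
        s <- .knnPool(s, coords, k_smooth)
        u <- .knnPool(u, coords, k_smooth)
    }
    gam <- vapply(seq_len(nrow(s)), function(i) {
        si <- s[i, ]; ui <- u[i, ]
        qs <- stats::quantile(si, c(q, 1 - q), names = FALSE)
        ext <- si <= qs[1L] | si >= qs[2L]
        denom <- sum(si[ext]^2)
        if (denom == 0) return(NA_real_)
        sum(ui[ext] * si[ext]) / denom
    }, numeric(1))
    ok <- is.finite(gam)
    s <- s[ok, , drop = FALSE]; u <- u[ok, , drop = FALSE]
    gam <- stats::setNames(gam[ok], rownames(s))
    v <- u - gam * s
    new("VelocityModel", gamma = gam, velocity = v, smoothedSpliced = s,
        smoothedUnspliced = u, q = q)
}

#' Orient pseudotime by RNA velocity
#'
#' Bins cells along pseudotime, computes the expression centroid (smoothed
#' spliced layer of the velocity genes) per bin, and takes the local
#' pseudotime gradient at a cell as the difference between the neighbouring
#' bin centroids. Each cell's velocity vector is projected onto its local
#' gradient; if the mean projection over cells is negative the pseudotime
#' axis is flipped. The magnitude of the mean projection is reported as the
#' orientation confidence.
#'
#' For the projection the per-gene velocity is recomputed with a ratio slope
#' (sum of unspliced over sum of spliced), not the extreme-quantile
#' regression slope: the projection statistic is sensitive to slope
#' attenuation bias (which creates a spurious component aligned with the
#' expression gradient), and the ratio estimator is attenuation-free. The
#' extreme-quantile \eqn{\hat\gamma} of the \linkS4class{VelocityModel} is
#' unaffected.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param vm a \linkS4class{VelocityModel} sharing cells with \code{traj}.
#' @param n_bins pseudotime bins for the expression centroids.
#' @return The oriented \linkS4class{Trajectory}.
#' @export
orientPseudotime <- function(traj, vm, n_bins = 10L) {
    cells <- intersect(traj@cells, colnames(vm@velocity))
    if (!length(cells)) stop("no shared cells between trajectory and velocity")
    pt <- traj@pseudotime[cells]
    expr <- vm@smoothedSpliced[, cells, drop = FALSE]
    uex <- vm@smoothedUnspliced[, cells, drop = FALSE]
    slope <- rowSums(uex) / pmax(rowSums(expr), 1e-300)
    vel <- uex - slope * expr
    bins <- pmin(pmax(findInterval(pt, seq(0, 1, length.out = n_bins + 1L),
                                   all.inside = TRUE), 1L), n_bins)
    present <- sort(unique(bins))
    centroids <- vapply(present, function(b)
        rowMeans(expr[, bins == b, drop = FALSE]), numeric(nrow(expr)))
    pos <- match(bins, present)
    proj <- vapply(seq_along(cells), function(i) {
        p <- pos[i]
        lo <- max(p - 1L, 1L); hi <- min(p + 1L, length(present))
        grad <- centroids[, hi] - centroids[, lo]
        sum(vel[, i] * grad)
    }, numeric(1))
    m <- mean(proj)
    if (m == 0) {
        warning("orientation undetermined (zero mean projection); ",
                "keeping input order")
        traj@orientation <- NA_integer_
        traj@confidence <- 0
        return(traj)
    }
    sign <- if (m < 0) -1L else 1L
    if (sign < 0L) traj@pseudotime <- 1 - traj@pseudotime
    traj@orientation <- sign
    traj@confidence <- abs(m)
    traj
}
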