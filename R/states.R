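## negative-binomial spline fit of one gene against pseudotime.
## theta is estimated once (full model), then both nested models are refit
## as fixed-theta GLMs so their deviances are directly comparable.
.nbSplineLRT <- function(y, t, offset, df) {
    if (all(y == y[1L]))
        return(list(stat = 0, p = 1, flag = FALSE, fit = NULL))
    basis <- splines::ns(t, df = df)
    full0 <- tryCatch(
        suppressWarnings(MASS::glm.nb(y ~ basis + offset(offset))),
        error = function(e) NULL)
    if (is.null(full0))
        return(list(stat = 0, p = 1, flag = TRUE, fit = NULL))
    fam <- MASS::negative.binomial(theta = full0$theta)
    null <- tryCatch(suppressWarnings(
        stats::glm(y ~ 1 + offset(offset), family = fam)),
        error = function(e) NULL)
    if (is.null(null))
        return(list(stat = 0, p = 1, flag = TRUE, fit = NULL))
    ## full0's deviance is evaluated at the same theta, so the two
    ## deviances are directly comparable
    stat <- max(null$deviance - full0$deviance, 0)
    list(stat = stat, p = stats::pchisq(stat, df, lower.tail = FALSE),
         flag = FALSE, fit = full0)
}

#' Likelihood-ratio test for pseudotime-dependent expression
#'
#' Per gene, fits a negative-binomial regression of raw counts on a natural
#' cubic spline of pseudotime (default 3 degrees of freedom) with a
#' log-library-size offset, against an intercept-only null. The
#' likelihood-ratio statistic is referred to a chi-squared distribution with
#' \code{df} degrees of freedom; q-values are Benjamini-Hochberg.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{counts}.
#' @param traj an oriented \linkS4class{Trajectory} (>= 30 cells).
#' @param df spline degrees of freedom.
#' @param genes genes to test (default all).
#' @param sig_q significance threshold on the q-value.
#' @param size_factors per-cell library sizes used as the model offset
#'   (default: total counts of the full matrix).
#' @return \code{data.frame} with \code{gene}, \code{stat}, \code{p},
#'   \code{q}, \code{significant}, and \code{flag_no_fit} for genes whose
#'   fits did not converge (reported with p = 1).
#' @export
pseudotimeDETest <- function(sce, traj, df = 3L, genes = NULL,
                             sig_q = 0.01, size_factors = NULL) {
    cells <- traj@cells
    if (length(cells) < 30L) stop("need at least 30 cells")
    if (is.null(genes)) genes <- rownames(sce)
    y <- as.matrix(assay(sce, "counts")[genes, cells, drop = FALSE])
    t <- traj@pseudotime[cells]
    if (is.null(size_factors))
        size_factors <- Matrix::colSums(assay(sce, "counts")[, cells,
                                                             drop = FALSE])
    off <- log(pmax(size_factors, 1))
    off <- off - mean(off)
    res <- lapply(seq_along(genes), function(i) {
        yi <- y[i, ]
        ## genes with almost no signal cannot reach significance; skip the fit
        if (sum(yi > 0) < 3L)
            return(list(stat = 0, p = 1, flag = FALSE, fit = NULL))
        .nbSplineLRT(yi, t, off, df)
    })
    stat <- vapply(res, `[[`, numeric(1), "stat")
    p <- vapply(res, `[[`, numeric(1), "p")
    q <- stats::p.adjust(p, method = "BH")
    data.frame(gene = genes, stat = stat, p = p, q = q,
               significant = q < sig_q,
               flag_no_fit = vapply(res, `[[`, logical(1), "flag"),
               row.names = NULL)
}

#' Smoothed expression curves on an even pseudotime grid
#'
#' Evaluates the fitted negative-binomial spline mean of each gene on an
#' even pseudotime grid (at the average library size) and scales each row to
#' a maximum of 1, giving relative expression curves. All-zero genes yield
#' an all-zero row and are flagged in \code{attr(, "all_zero")}.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{counts}.
#' @param traj an oriented \linkS4class{Trajectory}.
#' @param genes genes to smooth (typically the significant ones).
#' @param grid number of grid points.
#' @param df spline degrees of freedom.
#' @param size_factors per-cell library sizes used as the model offset.
#' @return Genes x grid matrix of relative expression in [0, 1].
#' @export
smoothCurves <- function(sce, traj, genes, grid = 100L, df = 3L,
                         size_factors = NULL) {
    cells <- traj@cells
    y <- as.matrix(assay(sce, "counts")[genes, cells, drop = FALSE])
    t <- traj@pseudotime[cells]
    if (is.null(size_factors))
        size_factors <- Matrix::colSums(assay(sce, "counts")[, cells,
                                                             drop = FALSE])
    off <- log(pmax(size_factors, 1))
    off <- off - mean(off)
    tg <- seq(0, 1, length.out = grid)
    out <- matrix(0, length(genes), grid,
                  dimnames = list(genes, sprintf("t%03d", seq_len(grid))))
    all_zero <- logical(length(genes))
    basis <- splines::ns(t, df = df)
    for (i in seq_along(genes)) {
        yi <- y[i, ]
        if (all(yi == 0)) { all_zero[i] <- TRUE; next }
        fit <- .nbSplineLRT(yi, t, off, df)$fit
        mu <- if (is.null(fit)) {
            ## fall back to a Poisson spline fit (constant or hard genes)
            pf <- tryCatch(suppressWarnings(
                stats::glm(yi ~ basis + offset(off), family = stats::poisson())),
                error = function(e) NULL)
            if (is.null(pf)) rep(mean(yi), grid)
            else as.vector(exp(cbind(1, stats::predict(basis, tg)) %*%
                                   stats::coef(pf)))
        } else {
            as.vector(exp(cbind(1, stats::predict(basis, tg)) %*%
                              stats::coef(fit)))
        }
        mx <- max(mu)
        out[i, ] <- if (mx > 0) mu / mx else 0
    }
    attr(out, "all_zero") <- all_zero
    attr(out, "grid_t") <- tg
    out
}

#' Cluster smoothed expression curves into gene modules
#'
#' Agglomerative (average-linkage) hierarchical clustering of the smoothed
#' curves under correlation distance, cut to \code{n_modules}. Module ids
#' are renumbered by the grid position of the module mean-profile peak, so
#' module 1 peaks earliest.
#'
#' @param smoothed genes x grid matrix from \code{\link{smoothCurves}}.
#' @param n_modules number of modules.
#' @return Named integer vector, gene -> module id.
#' @export
clusterGeneModules <- function(smoothed, n_modules = 3L) {
    if (nrow(smoothed) < n_modules)
        stop("need at least n_modules genes")
    if (n_modules == 1L)
        return(stats::setNames(rep(1L, nrow(smoothed)), rownames(smoothed)))
    cr <- suppressWarnings(stats::cor(t(smoothed)))
    cr[!is.finite(cr)] <- 0  # constant rows: maximal distance to all
    hc <- stats::hclust(stats::as.dist(1 - cr), method = "average")
    memb <- stats::cutree(hc, k = n_modules)
    peak <- vapply(seq_len(n_modules), function(m)
        which.max(colMeans(smoothed[memb == m, , drop = FALSE])),
        numeric(1))
    relabel <- match(seq_len(n_modules), order(peak))
    stats::setNames(relabel[memb], rownames(smoothed))
}

#' Exact least-squares change-point segmentation
#'
#' Partitions the rows of an ordered feature matrix into \code{K} contiguous
#' segments minimizing the total within-segment sum of squared deviations
#' from the segment means, by exact dynamic programming. Ties in the primary
#' cost (within numerical tolerance) are broken towards equal segment sizes
#' (secondary cost: squared deviation of segment lengths from n/K).
#'
#' @param x n x p matrix of ordered observations (rows in sequence order).
#' @param K number of segments.
#' @return Integer vector of segment labels (1..K) per row; the last row
#'   index of each segment is attached as \code{attr(, "boundaries")}.
#' @examples
#' changepointSegments(cbind(c(0, 0, 0, 1, 1, 1)), K = 2)
#' @export
changepointSegments <- function(x, K) {
    x <- as.matrix(x)
    n <- nrow(x)
    if (n < 2L * K) stop("need at least 2K observations")
    S1 <- apply(x, 2L, cumsum)                       # n x p prefix sums
    S2 <- cumsum(rowSums(x^2))
    segcost <- function(i, j) {                      # rows i..j inclusive
        s1 <- S1[j, ] - if (i > 1L) S1[i - 1L, ] else 0
        s2 <- S2[j] - if (i > 1L) S2[i - 1L] else 0
        s2 - sum(s1^2) / (j - i + 1L)
    }
    ideal <- n / K
    seglen <- function(i, j) (j - i + 1L - ideal)^2
    INF <- Inf
    cost <- matrix(INF, K, n)      # primary
    cost2 <- matrix(INF, K, n)     # secondary (tie-break)
    back <- matrix(0L, K, n)
    for (j in seq_len(n)) {
        cost[1L, j] <- segcost(1L, j)
        cost2[1L, j] <- seglen(1L, j)
    }
    eps <- 1e-9
    for (k in 2:K) {
        for (j in k:n) {
            best <- INF; best2 <- INF; bi <- 0L
            for (i in (k - 1L):(j - 1L)) {
                c1 <- cost[k - 1L, i] + segcost(i + 1L, j)
                c2 <- cost2[k - 1L, i] + seglen(i + 1L, j)
                if (!is.finite(best)) {
                    best <- c1; best2 <- c2; bi <- i
                    next
                }
                tolr <- eps * (1 + abs(best))
                if (c1 < best - tolr ||
                    (abs(c1 - best) <= tolr && c2 < best2)) {
                    best <- min(c1, best); best2 <- c2; bi <- i
                }
            }
            cost[k, j] <- best; cost2[k, j] <- best2; back[k, j] <- bi
        }
    }
    bounds <- integer(K)
    bounds[K] <- n
    j <- n
    for (k in K:2) {
        j <- back[k, j]
        bounds[k - 1L] <- j
    }
    labels <- rep(seq_len(K), times = diff(c(0L, bounds)))
    attr(labels, "boundaries") <- bounds
    labels
}

#' Segment a trajectory into lineage states
#'
#' Builds per-cell features (mean Pearson residual of each gene module, plus
#' the mean alga_pos and alga_neg bulk correlations, each standardized to
#' unit variance so neither block dominates), orders cells by oriented
#' pseudotime, and places K-1 cut points by exact least-squares change-point
#' segmentation. States are numbered 1..K in pseudotime order.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{counts}.
#' @param traj an oriented \linkS4class{Trajectory}.
#' @param modules gene module assignment from
#'   \code{\link{clusterGeneModules}}.
#' @param percell_corr per-cell bulk correlations from
#'   \code{\link{perCellBulkCorrelation}} (rows must cover the trajectory
#'   cells).
#' @param smoothed smoothed grid from \code{\link{smoothCurves}} (stored in
#'   the result).
#' @param K number of states.
#' @return A \linkS4class{StateModel}.
#' @export
segmentStates <- function(sce, traj, modules, percell_corr,
                          smoothed = matrix(0, 0, 0), K = 5L) {
    cells <- traj@cells
    if (length(cells) < 2L * K)
        stop("need at least 2K cells")
    if (is.na(traj@orientation))
        warning("trajectory is unoriented; states follow the raw axis")
    x <- t(.pearsonResiduals(sce, cells, names(modules)))
    feat <- vapply(sort(unique(modules)), function(m)
        colMeans(x[modules == m, , drop = FALSE]), numeric(length(cells)))
    colnames(feat) <- paste0("module", sort(unique(modules)))
    label <- attr(percell_corr, "label")
    pc <- percell_corr[cells, , drop = FALSE]
    add <- cbind(
        alga_pos_r = rowMeans(pc[, label == "alga_pos", drop = FALSE],
                              na.rm = TRUE),
        alga_neg_r = rowMeans(pc[, label == "alga_neg", drop = FALSE],
                              na.rm = TRUE))
    add[!is.finite(add)] <- 0
    feat <- cbind(feat, add)
    feat <- apply(feat, 2L, function(z) {
        s <- stats::sd(z)
        if (is.na(s) || s == 0) z - mean(z) else (z - mean(z)) / s
    })
    pt <- traj@pseudotime[cells]
    ord <- order(pt, cells)
    labels <- changepointSegments(feat[ord, , drop = FALSE], K)
    states <- integer(length(cells))
    states[ord] <- labels
    names(states) <- cells
    bounds <- attr(labels, "boundaries")
    pts <- pt[ord]
    cuts <- vapply(bounds[-K], function(b) (pts[b] + pts[b + 1L]) / 2,
                   numeric(1))
    ## strictly increasing cuts even under tied pseudotime
    cuts <- cummax(cuts + seq_along(cuts) * 1e-12)
    new("StateModel", cuts = unname(cuts), states = states,
        K = as.integer(K), modules = modules, smoothed = smoothed,
        features = feat)
}

#' State composition per condition
#'
#' @param sm a \linkS4class{StateModel}.
#' @param conditions named character vector (cell -> condition) covering the
#'   segmented cells.
#' @return Matrix of proportions, conditions x states (rows sum to 1), with
#'   cell counts in \code{attr(, "counts")}. Conditions with zero cells are
#'   omitted with a warning.
#' @export
stateProportions <- function(sm, conditions) {
    cells <- names(sm@states)
    cond <- conditions[cells]
    if (any(is.na(cond))) stop("every segmented cell needs a condition")
    tab <- table(condition = cond, state = factor(sm@states,
                                                  levels = seq_len(sm@K)))
    empty <- rowSums(tab) == 0
    if (any(empty)) {
        warning("conditions with zero cells omitted: ",
                paste(rownames(tab)[empty], collapse = ", "))
        tab <- tab[!empty, , drop = FALSE]
    }
    prop <- sweep(unclass(tab), 1L, rowSums(tab), "/")
    attr(prop, "counts") <- unclass(tab)
    prop
}
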