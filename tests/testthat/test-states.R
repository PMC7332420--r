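test_that("the DP change-point equals exhaustive search", {
    ## stated example: single cut between positions 3 and 4
    lab <- changepointSegments(cbind(c(0, 0, 0, 1, 1, 1)), K = 2)
    expect_identical(as.integer(lab), c(1L, 1L, 1L, 2L, 2L, 2L))
    ## random multivariate cases up to n = 50
    set.seed(20)
    for (rep in 1:8) {
        n <- sample(10:50, 1)
        K <- sample(2:4, 1)
        x <- matrix(rnorm(n * 2), n, 2) +
            rep(rnorm(K, sd = 3)[rep_len(seq_len(K), n)], 2)
        expect_identical(as.integer(changepointSegments(x, K)),
                         as.integer(bruteSegments(x, K)))
    }
})

test_that("constant features fall back to equal-sized segments", {
    lab <- changepointSegments(matrix(1, 20, 3), K = 5)
    expect_identical(as.integer(table(lab)), rep(4L, 5))
    ## too few observations error
    expect_error(changepointSegments(matrix(1, 5, 1), K = 3), "at least 2K")
})

test_that("the pseudotime LRT behaves at the boundaries", {
    set.seed(21)
    n <- 60
    cells <- sprintf("c%03d", seq_len(n))
    pt <- stats::setNames(sort(runif(n)), cells)
    counts <- rbind(rep(3, n),                       # constant
                    rpois(n, 5),                     # null
                    rpois(n, exp(1 + 2 * pt)))       # strong signal
    colnames(counts) <- cells
    sce <- sceFrom(counts)
    tr <- trajFrom(pt)
    de <- pseudotimeDETest(sce, tr, size_factors = rep(100, n))
    expect_equal(de$stat[1], 0)   # nested models coincide
    expect_equal(de$p[1], 1)
    expect_lt(de$p[3], 1e-6)
    expect_gt(de$p[2], 0.001)
    ## cell floor
    expect_error(pseudotimeDETest(sce[, 1:10], trajFrom(pt[1:10])),
                 "at least 30")
})

test_that("smoothed curves are row-scaled spline means on the grid", {
    set.seed(22)
    n <- 60
    cells <- sprintf("c%03d", seq_len(n))
    pt <- stats::setNames(sort(runif(n)), cells)
    counts <- rbind(rep(4, n),                       # constant positive
                    rep(0, n),                       # all zero
                    rpois(n, exp(2 - 3 * pt)))       # early-declining
    colnames(counts) <- cells
    sce <- sceFrom(counts)
    tr <- trajFrom(pt)
    sm <- smoothCurves(sce, tr, rownames(sce), grid = 100L,
                       size_factors = rep(100, n))
    expect_equal(unname(sm[1, ]), rep(1, 100), tolerance = 1e-6)
    expect_equal(unname(sm[2, ]), rep(0, 100))
    expect_true(attr(sm, "all_zero")[2])
    ## early gene peaks in the first third of the grid
    expect_lte(which.max(sm[3, ]), 33)
    ## grid = 2 evaluates the fitted means at pseudotime 0 and 1
    sm2 <- smoothCurves(sce, tr, rownames(sce)[3], grid = 2L,
                        size_factors = rep(100, n))
    expect_identical(ncol(sm2), 2L)
    expect_equal(unname(sm2[1, 1]), 1)   # early gene: max at t = 0
})

test_that("gene modules partition by curve shape and order by peak", {
    grid <- 30
    early <- matrix(rep(c(rep(1, 10), rep(0, 20)), 4), 4, grid, byrow = TRUE)
    mid <- matrix(rep(c(rep(0, 10), rep(1, 10), rep(0, 10)), 3), 3, grid,
                  byrow = TRUE)
    late <- matrix(rep(c(rep(0, 20), rep(1, 10)), 5), 5, grid, byrow = TRUE)
    sm <- rbind(early, mid, late)
    rownames(sm) <- sprintf("g%02d", seq_len(nrow(sm)))
    mods <- clusterGeneModules(sm, 3L)
    expect_identical(unname(mods), rep(1:3, c(4, 3, 5)))
    ## n_modules = 1 puts everything together
    expect_true(all(clusterGeneModules(sm, 1L) == 1L))
    expect_error(clusterGeneModules(sm[1:2, ], 3L), "at least")
})

test_that("state segmentation recovers planted blocks and proportions count", {
    set.seed(23)
    n <- 50
    cells <- sprintf("c%03d", seq_len(n))
    state <- rep(1:5, each = 10)
    pt <- stats::setNames((seq_len(n) - 0.5) / n, cells)
    ## counts jump by state for three gene blocks
    lv <- rbind(c(9, 5, 1, 1, 1), c(1, 5, 9, 5, 1), c(1, 1, 1, 5, 9))
    counts <- do.call(rbind, lapply(1:3, function(m)
        matrix(rpois(8 * n, rep(20 * lv[m, state], each = 8)), 8, n)))
    counts <- rbind(counts, matrix(rpois(6 * n, 10), 6, n))
    colnames(counts) <- cells
    sce <- normalizeLog(sceFrom(counts))
    tr <- trajFrom(pt)
    modules <- stats::setNames(rep(c(1:3, 3L), c(8, 8, 8, 6)),
                               rownames(sce))[1:24]
    pc <- matrix(rnorm(n * 2, sd = 0.01), n, 2,
                 dimnames = list(cells, NULL))
    attr(pc, "label") <- c("alga_pos", "alga_neg")
    sm <- segmentStates(sce, tr, modules, pc, K = 5L)
    expect_gte(symLineage:::.ari(stateLabels(sm), state), 0.9)
    expect_true(all(diff(stateCuts(sm)) > 0))
    ## proportions: counting and permutation invariance
    conds <- stats::setNames(rep(c("a", "b"), c(30, 20)), cells)
    pr <- stateProportions(sm, conds)
    expect_equal(rowSums(pr), c(a = 1, b = 1))
    pr2 <- stateProportions(sm, conds[sample(n)])
    expect_equal(pr, pr2)
    ## the stated toy: states (1,1,2) in one condition
    sm2 <- sm
    sm2@states <- stats::setNames(c(1L, 1L, 2L), cells[1:3])
    pr3 <- stateProportions(sm2, stats::setNames(rep("x", 3), cells[1:3]))
    expect_equal(unname(pr3[1, ]), c(2 / 3, 1 / 3, 0, 0, 0))
})

test_that("segmentation is stable to small pseudotime jitter", {
    set.seed(24)
    n <- 50
    cells <- sprintf("c%03d", seq_len(n))
    state <- rep(1:5, each = 10)
    pt <- stats::setNames((seq_len(n) - 0.5) / n, cells)
    lv <- rbind(c(9, 5, 1, 1, 1), c(1, 5, 9, 5, 1), c(1, 1, 1, 5, 9))
    counts <- do.call(rbind, lapply(1:3, function(m)
        matrix(rpois(8 * n, rep(20 * lv[m, state], each = 8)), 8, n)))
    colnames(counts) <- cells
    sce <- normalizeLog(sceFrom(counts))
    modules <- stats::setNames(rep(1:3, each = 8), rownames(sce))
    pc <- matrix(rnorm(n * 2, sd = 0.01), n, 2,
                 dimnames = list(cells, NULL))
    attr(pc, "label") <- c("alga_pos", "alga_neg")
    s0 <- stateLabels(segmentStates(sce, trajFrom(pt), modules, pc, K = 5L))
    ptj <- pt + rnorm(n, 0, 0.01)
    ptj <- stats::setNames((ptj - min(ptj)) / diff(range(ptj)), cells)
    s1 <- stateLabels(segmentStates(sce, trajFrom(ptj), modules, pc, K = 5L))
    expect_gte(mean(s0[cells] == s1[cells]), 0.9)
})

test_that("the internal ARI matches the reference implementation", {
    set.seed(25)
    for (i in 1:5) {
        a <- sample(1:4, 40, replace = TRUE)
        b <- sample(1:3, 40, replace = TRUE)
        expect_equal(symLineage:::.ari(a, b),
                     mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
})
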