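test_that("generation is byte-identical under a fixed seed", {
    a <- generateCells(smallParams(seed = 7))
    b <- generateCells(smallParams(seed = 7))
    expect_identical(assay(a$sce, "counts"), assay(b$sce, "counts"))
    expect_identical(assay(a$sce, "spliced"), assay(b$sce, "spliced"))
    expect_identical(as.data.frame(a$truth$cells),
                     as.data.frame(b$truth$cells))
    d <- generateCells(smallParams(seed = 8))
    expect_false(identical(assay(a$sce, "counts"), assay(d$sce, "counts")))
})

test_that("counts are non-negative integers and layers partition the total", {
    sim <- generateCells(smallParams(seed = 7))
    cnt <- as.matrix(assay(sim$sce, "counts"))
    expect_true(all(cnt >= 0))
    expect_true(all(cnt == round(cnt)))
    expect_equal(cnt, as.matrix(assay(sim$sce, "spliced")) +
                          as.matrix(assay(sim$sce, "unspliced")))
})

test_that("the rare endosymbiotic type lands in the binomial central band", {
    ## defaults-scale type draw at desk size: 10,000 cells, p = 0.015
    p <- simParams(n_genes = 120L, n_cells_per_batch = 5000L,
                   n_type_markers = 4L, n_dynamic_genes = 5L,
                   rare_type_freq = 0.015, seed = 11)
    sim <- generateCells(p)
    n_endo <- sum(sim$truth$cells$type == p$n_types)
    band <- qbinom(c(0.005, 0.995), 10000L, 0.015)
    expect_gte(n_endo, band[1])
    expect_lte(n_endo, band[2])
    ## states only on endosymbiotic cells; pseudotime ordered by state
    ct <- sim$truth$cells
    expect_true(all(is.na(ct$state[ct$type != p$n_types])))
    expect_true(all(!is.na(ct$state[ct$type == p$n_types])))
    sm <- tapply(ct$pseudotime, ct$state, mean)
    expect_true(all(diff(sm) > 0))
})

test_that("realized endosymbiotic fraction tracks the target over seeds", {
    hits <- vapply(1:20, function(s) {
        sim <- generateCells(smallParams(seed = 300 + s,
                                         rare_type_freq = 0.10))
        f <- mean(sim$truth$cells$type == 16L)
        se <- sqrt(0.10 * 0.90 / 300)
        abs(f - 0.10) < 3 * se
    }, logical(1))
    expect_gte(sum(hits), 19L)
})

test_that("per-batch median UMI is within 25% of its target", {
    sim <- generateCells(smallParams(seed = 7))
    tot <- Matrix::colSums(assay(sim$sce, "counts"))
    batch <- colData(sim$sce)$batch
    for (b in unique(batch)) {
        med <- median(tot[batch == b])
        target <- smallParams()$batch_depth_medians[[b]]
        expect_lt(abs(med - target) / target, 0.25)
    }
})

test_that("steady state of the two-stage model gives u = gamma * s", {
    ## constant alpha (alpha_on = 1): the surface stays at its fixed point
    p <- smallParams(alpha_on = 1)
    g <- c(0.3, 0.8, 1.5)
    surf <- dynamicExpectationGrid(g, c("early", "mid", "late"),
                                   c(1, 2, 0.5), p)
    expect_equal(surf$u, g * surf$s, tolerance = 1e-8)
    ## expected steady-state velocity is zero
    expect_equal(max(abs(surf$u - g * surf$s)), 0, tolerance = 1e-8)
})

test_that("expectation surfaces honour the module timing", {
    p <- smallParams()
    g <- rep(0.5, 6)
    mod <- rep(c("early", "late"), each = 3)
    surf <- dynamicExpectationGrid(g, mod, rep(1, 6), p,
                                   kind = rep(c("graded", "switch"), 3))
    tot <- surf$u + surf$s
    i01 <- which.min(abs(surf$t - 0.1))
    i09 <- which.min(abs(surf$t - 0.9))
    early <- mod == "early"
    expect_true(all(tot[early, i01] > tot[early, i09]))
    expect_true(all(tot[!early, i09] > tot[!early, i01]))
})

test_that("mitochondrial genes are flagged and parameter errors are caught", {
    sim <- generateCells(smallParams(seed = 7))
    expect_identical(which(rowData(sim$sce)$mito), 1:10)
    expect_true(all(startsWith(rownames(sim$sce)[1:10], "MT-")))
    expect_error(simParams(n_genes = -5), "positive")
    expect_error(simParams(state_mix = list(
        regeneration = c(0.5, 0.5, 0.2, 0, 0),
        homeostasis = c(0.2, 0.2, 0.2, 0.2, 0.2))), "simplex")
    expect_error(simParams(rare_type_freq = 1.2), "rare_type_freq")
})

test_that("bulk references: construction, degenerate mixture, replicates", {
    sd <- smallData()
    bulk <- sd$bulk
    expect_s4_class(bulk, "BulkProfileSet")
    expect_identical(ncol(bulk), 4L)
    expect_true(all(assay(bulk) >= 0))

    ## noise 0 and pure state-3 weights reproduce the state-3 pseudo-bulk
    sim <- sd$sim
    exact <- generateBulkReferences(smallParams(), sim$truth, sim$sce,
                                    state_weights = c(0, 1, 0),
                                    noise_sdlog = 0)
    cnt <- assay(sim$sce, "counts")
    s3 <- !is.na(sim$truth$cells$state) & sim$truth$cells$state == 3L
    pb <- Matrix::rowMeans(cnt[, s3])
    pb <- pb / sum(pb) * 1e6
    pos_cols <- which(colData(exact)$label == "alga_pos")
    expect_equal(unname(assay(exact)[, pos_cols[1]]), unname(pb),
                 tolerance = 1e-12)

    ## replicate agreement beats cross-label agreement
    lv <- log1p(assay(bulk))
    lab <- colData(bulk)$label
    pos <- which(lab == "alga_pos"); neg <- which(lab == "alga_neg")
    expect_gt(cor(lv[, pos[1]], lv[, pos[2]]), cor(lv[, pos[1]], lv[, neg[1]]))

    ## no endosymbiotic cells -> generation error
    truth2 <- sim$truth
    truth2$cells$state <- NA_integer_
    expect_error(generateBulkReferences(smallParams(), truth2, sim$sce),
                 "endosymbiotic|states")
})
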