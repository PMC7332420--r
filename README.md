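# symLineage

Corals host their dinoflagellate algae inside a specialized cell type, and
the identity and life history of those endosymbiotic host cells can be read
out from single-cell RNA-seq. `symLineage` implements, as a tested and
reusable R package, the inference chain by which the endosymbiotic cell type
of the soft coral *Xenia* sp. is identified and resolved into five lineage
states:

1. **QC and embedding** — UMI/mitochondrial filtering (UMI ≥ 400, mito
   fraction ≤ 0.2%, top-1% outlier trim), log-normalization, top-1,000
   dispersion-ranked variable genes, and a 20-dimensional joint embedding of
   batches with per-batch gene standardization.
2. **Clustering and markers** — kNN-graph Louvain clustering, k-nearest
   label transfer between conditions, and per-cluster marker statistics:
   Wilcoxon rank-sum p (Bonferroni-adjusted over all gene × cluster tests),
   `avg_logFC = ln(mean_in + 1) − ln(mean_out + 1)`, and the two specificity
   fractions (share of in-/out-of-cluster cells above the gene's all-cell
   mean).
3. **Reference matching** — Pearson correlation of cluster mean UMI profiles
   against bulk RNA-seq of FACS-sorted alga-containing (`alga_pos`) and
   alga-free (`alga_neg`) cells (log1p scale); the endosymbiotic cluster is
   the `alga_pos` argmax.
4. **Pseudotime and RNA velocity** — ordering genes from a subcluster
   Kruskal–Wallis contrast, a principal curve fitted in a 2-D Pearson-residual
   reduction, and axis orientation from steady-state RNA velocity
   (`v = u − γ̂·s`, with γ̂ the zero-intercept slope of unspliced on spliced
   expression over the extreme spliced quantiles).
5. **Five lineage states** — negative-binomial spline likelihood-ratio tests
   along pseudotime, smoothed relative-expression curves, hierarchical gene
   modules, and exact dynamic-programming change-point segmentation of the
   trajectory into K = 5 states, with per-condition state proportions.
6. **Pulse-chase kinetics** — a 10-compartment linear ODE model (5 states ×
   labelled/unlabelled) of EdU pulse-chase label dynamics through the
   lineage: progenitor → uptake → mature alga-containing → loss.

A seeded synthetic-data generator (`generateCells`, `generateBulkReferences`)
emulates the statistical structure of the study — 16 cell types with one
rare (~1.5%) endosymbiotic type, v2/v3 chemistry batches with median UMI
801/2,027, condition-dependent state mixtures, spliced/unspliced layers from
a two-stage kinetic model — and returns ground truth so every stage can be
scored.

## Worked example

```r
library(symLineage)
library(SingleCellExperiment)

sim  <- generateCells(simParams(seed = 1))
sce  <- qcFilterCells(sim$sce)               # atlas-style QC rules
ncol(sce)
#> [1] 5692
sce  <- jointEmbedding(selectHVG(normalizeLog(sce)))
sce  <- clusterCells(sce, seed = 1)
nlevels(colData(sce)$cluster)
#> [1] 16

bulk <- generateBulkReferences(simParams(seed = 1), sim$truth, sim$sce)
nom  <- nominateEndosymbiotic(
    correlateClusterBulk(clusterMeanProfiles(sce), bulk))
nom$cluster; round(nom$margin, 3)
#> [1] "16"
#> [1] 0.028

endo  <- colnames(sce)[colData(sce)$cluster == nom$cluster]
length(endo)
#> [1] 85
genes <- selectOrderingGenes(sce, endo)
traj  <- fitTrajectory(sce, endo, genes)
vm    <- fitGamma(sce, endo, coords = traj@coords)
traj  <- orientPseudotime(traj, vm)
cor(pseudotime(traj)[endo], sim$truth$cells[endo, "pseudotime"],
    method = "spearman", use = "complete.obs")
#> [1] 0.977

de  <- pseudotimeDETest(sce, traj, genes = genes)
sig <- de$gene[de$significant]
sm  <- segmentStates(sce, traj,
                     clusterGeneModules(smoothCurves(sce, traj, sig)),
                     perCellBulkCorrelation(sce, bulk, endo))
stateProportions(sm, setNames(colData(sce)$condition, colnames(sce)))
```

The 16 planted types are recovered as 16 clusters, the rare (85-cell)
endosymbiotic type is nominated by its bulk correlation, and the oriented
pseudotime tracks the generator's truth at Spearman 0.98, running from the
pre-endosymbiotic progenitor state towards the post-endosymbiotic state;
the regeneration condition is enriched for states 1–2 and homeostasis for
states 3–5. The companion kinetic model reproduces the pulse-chase
narrative:

```r
chase <- simulatePulseChase(kineticModel(), t_max = 19)
peakTime(chase)
#> [1] 11.95
```

The labelled alga-containing fraction rises after the day-3/4 pulse, peaks
around day 12, then declines, while the total alga-containing fraction
plateaus — the signature of a progenitor → uptake → mature → loss chain.

`runPipeline()` chains all stages from a single configuration list and
writes TSV artifacts plus the resolved configuration.

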