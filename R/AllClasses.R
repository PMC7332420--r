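#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SingleCellExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData colData<- rowData<-
NULL

#' Bulk reference expression profiles from sorted cell populations
#'
#' A \linkS4class{SummarizedExperiment} holding per-gene expression on an
#' RPKM-like positive scale for FACS-sorted bulk samples. Each column is one
#' replicate of either the alga-containing (\code{alga_pos}) or alga-free
#' (\code{alga_neg}) population.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}; columns carry
#'   \code{label} (one of \code{"alga_pos"}, \code{"alga_neg"}) and
#'   \code{replicate} in \code{colData}.
#' @export
setClass("BulkProfileSet", contains = "SummarizedExperiment")

setValidity("BulkProfileSet", function(object) {
    cd <- colData(object)
    if (!all(c("label", "replicate") %in% colnames(cd)))
        return("colData must contain 'label' and 'replicate'")
    if (!all(cd$label %in% c("alga_pos", "alga_neg")))
        return("labels must be 'alga_pos' or 'alga_neg'")
    if (!all(c("alga_pos", "alga_neg") %in% cd$label))
        return("need at least one replicate per label")
    m <- assay(object)
    if (any(m < 0)) return("expression values must be non-negative")
    TRUE
})

#' Construct a BulkProfileSet
#'
#' @param values numeric matrix, genes x samples, RPKM-scale (non-negative).
#' @param label character vector per column, \code{"alga_pos"}/\code{"alga_neg"}.
#' @param replicate replicate identifier per column.
#' @return A \linkS4class{BulkProfileSet}.
#' @examples
#' m <- matrix(abs(rnorm(40)), 10,
#'             dimnames = list(paste0("g", 1:10), NULL))
#' BulkProfileSet(m, rep(c("alga_pos", "alga_neg"), each = 2), c(1, 2, 1, 2))
#' @export
BulkProfileSet <- function(values, label, replicate) {
    colnames(values) <- paste(label, replicate, sep = "_")
    new("BulkProfileSet",
        SummarizedExperiment(assays = list(rpkm = values),
                             colData = DataFrame(label = label,
                                                 replicate = replicate)))
}

#' One-dimensional lineage ordering from a fitted principal curve
#'
#' Holds the 2-D coordinates used for fitting, the polyline nodes of the
#' fitted curve, the per-cell arc-length projections, and the resulting
#' pseudotime (min-max scaled to [0, 1]). \code{orientation} is \code{NA}
#' until \code{\link{orientPseudotime}} fixes the direction of progression.
#'
#' @slot cells character, cell identifiers.
#' @slot coords numeric matrix (cells x 2), reduced coordinates.
#' @slot nodes numeric matrix, ordered curve nodes (a simple polyline).
#' @slot lambda numeric, per-cell arc length of the projection.
#' @slot pseudotime numeric in [0, 1], named by cell.
#' @slot orientation integer, +1/-1 once oriented, NA before.
#' @slot confidence numeric, mean velocity projection magnitude (orientation
#'   evidence); NA before orientation.
#' @slot orderingGenes character, genes used to build \code{coords}.
#' @slot converged logical, principal-curve convergence flag.
#' @export
setClass("Trajectory", representation(
    cells = "character", coords = "matrix", nodes = "matrix",
    lambda = "numeric", pseudotime = "numeric", orientation = "integer",
    confidence = "numeric", orderingGenes = "character",
    converged = "logical"))

setValidity("Trajectory", function(object) {
    n <- length(object@cells)
    if (nrow(object@coords) != n || length(object@pseudotime) != n)
        return("coords/pseudotime must match the number of cells")
    pt <- object@pseudotime
    if (any(!is.finite(pt)) || any(pt < 0) || any(pt > 1))
        return("pseudotime must lie in [0, 1]")
    if (n > 1 && (abs(min(pt)) > 1e-8 || abs(max(pt) - 1) > 1e-8))
        return("pseudotime must span [0, 1] after min-max scaling")
    TRUE
})

#' Steady-state RNA velocity fit
#'
#' Per-gene degradation ratio \eqn{\hat\gamma} (slope of unspliced on spliced
#' under the steady-state assumption) and per-cell residual velocities
#' \eqn{v = u - \hat\gamma s} computed on neighbour-smoothed layers.
#'
#' @slot gamma named numeric, per-gene slope (>= 0).
#' @slot velocity numeric matrix (genes x cells) of residual velocities.
#' @slot smoothedSpliced,smoothedUnspliced numeric matrices (genes x cells),
#'   kNN-pooled layers used for the fit.
#' @slot q numeric, extreme-quantile fraction used for the slope fit.
#' @export
setClass("VelocityModel", representation(
    gamma = "numeric", velocity = "matrix",
    smoothedSpliced = "matrix", smoothedUnspliced = "matrix",
    q = "numeric"))

setValidity("VelocityModel", function(object) {
    if (any(object@gamma < 0)) return("gamma estimates must be non-negative")
    if (!identical(dim(object@velocity), dim(object@smoothedSpliced)))
        return("velocity and smoothed layers must share dimensions")
    TRUE
})

#' Five-state segmentation of a lineage trajectory
#'
#' Pseudotime cut points, per-cell state labels (1..K in pseudotime order),
#' gene modules from hierarchical clustering of smoothed expression curves,
#' and the row-scaled smoothed expression grid.
#'
#' @slot cuts numeric, K-1 strictly increasing cut points in (0, 1).
#' @slot states named integer, per-cell state in 1..K.
#' @slot K integer, number of states.
#' @slot modules named integer, gene -> module id (ordered early to late).
#' @slot smoothed numeric matrix (genes x grid), rows scaled to max 1.
#' @slot features numeric matrix (cells x features) used for segmentation.
#' @export
setClass("StateModel", representation(
    cuts = "numeric", states = "integer", K = "integer",
    modules = "integer", smoothed = "matrix", features = "matrix"))

setValidity("StateModel", function(object) {
    if (length(object@cuts) != object@K - 1L)
        return("need K-1 cut points")
    if (is.unsorted(object@cuts, strictly = TRUE))
        return("cut points must be strictly increasing")
    if (any(object@states < 1L | object@states > object@K))
        return("states must lie in 1..K")
    TRUE
})

#' Compartmental model of lineage progression under a nucleotide pulse
#'
#' Linear chain of five lineage states with proliferation entry into state 1,
#' exit from state 5, and an EdU pulse window during which entering cells are
#' labelled. Units: rates per day, times in days.
#'
#' @slot rates numeric(4), progression rates k12, k23, k34, k45 (per day).
#' @slot entryRate numeric, proliferation entry into state 1 (cells/day).
#' @slot exitRate numeric, exit from state 5 (per day).
#' @slot pulseWindow numeric(2), label pulse [t_on, t_off] in days.
#' @slot labelEfficiency numeric in (0, 1].
#' @slot algaStates integer, states counted as alga-containing.
#' @slot init numeric(5), initial (unlabelled) state occupancies.
#' @export
setClass("KineticModel", representation(
    rates = "numeric", entryRate = "numeric", exitRate = "numeric",
    pulseWindow = "numeric", labelEfficiency = "numeric",
    algaStates = "integer", init = "numeric"))

setValidity("KineticModel", function(object) {
    if (length(object@rates) != 4L || any(object@rates < 0))
        return("need 4 non-negative progression rates")
    if (object@entryRate < 0 || object@exitRate < 0)
        return("entry/exit rates must be non-negative")
    pw <- object@pulseWindow
    if (length(pw) != 2L || pw[1] >= pw[2])
        return("pulse window must satisfy t_on < t_off")
    le <- object@labelEfficiency
    if (le <= 0 || le > 1) return("label efficiency must be in (0, 1]")
    if (!all(object@algaStates %in% 1:5))
        return("alga states must be a subset of 1..5")
    if (length(object@init) != 5L || any(object@init < 0))
        return("init must be 5 non-negative occupancies")
    TRUE
})

#' Construct a KineticModel
#'
#' Defaults place the label pulse on regeneration days 3-4 and set the
#' progression rates so the mean transit time from state 1 to state 3 is
#' about 9 days (1/k12 + 1/k23 = 9).
#'
#' @param rates progression rates k12, k23, k34, k45 per day.
#' @param entryRate proliferation entry into state 1, cells/day.
#' @param exitRate exit from state 5, per day.
#' @param pulseWindow label pulse window in days.
#' @param labelEfficiency fraction of entering cells labelled during the pulse.
#' @param algaStates states counted as alga-containing.
#' @param init initial state occupancies (unlabelled).
#' @return A \linkS4class{KineticModel}.
#' @examples
#' kineticModel()
#' @export
kineticModel <- function(rates = c(k12 = 2/9, k23 = 2/9, k34 = 0.15,
                                   k45 = 0.12),
                         entryRate = 0.5, exitRate = 0.15,
                         pulseWindow = c(3, 4), labelEfficiency = 0.8,
                         algaStates = 2:4,
                         init = c(8, 1, 0.6, 0.3, 0.1)) {
    new("KineticModel", rates = unname(rates), entryRate = entryRate,
        exitRate = exitRate, pulseWindow = pulseWindow,
        labelEfficiency = labelEfficiency,
        algaStates = as.integer(algaStates), init = init)
}

#' Time course of labelled and unlabelled state occupancies
#'
#' @slot time numeric grid in days.
#' @slot labelled,unlabelled numeric matrices (time x 5 states).
#' @export
setClass("ChaseSeries", representation(
    time = "numeric", labelled = "matrix", unlabelled = "matrix"))

setValidity("ChaseSeries", function(object) {
    if (nrow(object@labelled) != length(object@time) ||
        nrow(object@unlabelled) != length(object@time))
        return("occupancy matrices must match the time grid")
    if (min(object@labelled, object@unlabelled) < -1e-9)
        return("occupancies must be non-negative")
    TRUE
})
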