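#' Per-cell pseudotime of a trajectory
#'
#' @param x a \linkS4class{Trajectory}.
#' @return Named numeric vector in [0, 1].
#' @export
setGeneric("pseudotime", function(x) standardGeneric("pseudotime"))

#' @rdname pseudotime
#' @export
setMethod("pseudotime", "Trajectory", function(x) x@pseudotime)

#' Orientation sign of a trajectory
#'
#' @param x a \linkS4class{Trajectory}.
#' @return +1L or -1L once oriented, otherwise NA.
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @rdname orientation
#' @export
setMethod("orientation", "Trajectory", function(x) x@orientation)

#' Fitted curve nodes of a trajectory
#'
#' @param x a \linkS4class{Trajectory}.
#' @return Numeric matrix of ordered polyline nodes.
#' @export
setGeneric("curveNodes", function(x) standardGeneric("curveNodes"))

#' @rdname curveNodes
#' @export
setMethod("curveNodes", "Trajectory", function(x) x@nodes)

#' Per-gene degradation ratio estimates
#'
#' @param x a \linkS4class{VelocityModel}.
#' @return Named numeric vector of slopes.
#' @export
setGeneric("gammaHat", function(x) standardGeneric("gammaHat"))

#' @rdname gammaHat
#' @export
setMethod("gammaHat", "VelocityModel", function(x) x@gamma)

#' Residual velocities of a velocity model
#'
#' @param x a \linkS4class{VelocityModel}.
#' @return Genes x cells matrix of residual velocities u - gamma * s.
#' @export
setGeneric("velocities", function(x) standardGeneric("velocities"))

#' @rdname velocities
#' @export
setMethod("velocities", "VelocityModel", function(x) x@velocity)

#' Per-cell lineage state labels
#'
#' @param x a \linkS4class{StateModel}.
#' @return Named integer vector of states (1..K, early to late).
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname stateLabels
#' @export
setMethod("stateLabels", "StateModel", function(x) x@states)

#' Pseudotime cut points between states
#'
#' @param x a \linkS4class{StateModel}.
#' @return Numeric vector of K-1 strictly increasing cut points in (0, 1).
#' @export
setGeneric("stateCuts", function(x) standardGeneric("stateCuts"))

#' @rdname stateCuts
#' @export
setMethod("stateCuts", "StateModel", function(x) x@cuts)

#' Gene module assignments
#'
#' @param x a \linkS4class{StateModel}.
#' @return Named integer vector, gene -> module id (ordered early to late).
#' @export
setGeneric("geneModules", function(x) standardGeneric("geneModules"))

#' @rdname geneModules
#' @export
setMethod("geneModules", "StateModel", function(x) x@modules)

#' Fraction of alga-containing cells that carry the label
#'
#' @param x a \linkS4class{ChaseSeries}.
#' @param algaStates integer, states counted as alga-containing.
#' @return Numeric vector along the time grid.
#' @export
setGeneric("labelledAlgaFraction",
           function(x, algaStates = 2:4) standardGeneric("labelledAlgaFraction"))

#' @rdname labelledAlgaFraction
#' @export
setMethod("labelledAlgaFraction", "ChaseSeries", function(x, algaStates = 2:4) {
    lab <- rowSums(x@labelled[, algaStates, drop = FALSE])
    tot <- lab + rowSums(x@unlabelled[, algaStates, drop = FALSE])
    ifelse(tot > 0, lab / tot, NA_real_)
})

#' Fraction of all cells that are alga-containing
#'
#' @param x a \linkS4class{ChaseSeries}.
#' @param algaStates integer, states counted as alga-containing.
#' @return Numeric vector along the time grid.
#' @export
setGeneric("algaFraction",
           function(x, algaStates = 2:4) standardGeneric("algaFraction"))

#' @rdname algaFraction
#' @export
setMethod("algaFraction", "ChaseSeries", function(x, algaStates = 2:4) {
    tot <- rowSums(x@labelled) + rowSums(x@unlabelled)
    alga <- rowSums(x@labelled[, algaStates, drop = FALSE]) +
        rowSums(x@unlabelled[, algaStates, drop = FALSE])
    ifelse(tot > 0, alga / tot, NA_real_)
})

setMethod("show", "Trajectory", function(object) {
    cat("Trajectory with", length(object@cells), "cells\n")
    cat("  curve nodes:", nrow(object@nodes),
        "| converged:", object@converged, "\n")
    ori <- if (is.na(object@orientation)) "unoriented"
           else sprintf("%+d (confidence %.3g)", object@orientation,
                        object@confidence)
    cat("  orientation:", ori, "\n")
})

setMethod("show", "VelocityModel", function(object) {
    cat("VelocityModel:", nrow(object@velocity), "genes x",
        ncol(object@velocity), "cells\n")
    cat(sprintf("  gamma median %.3g | extreme-quantile q = %.2g\n",
                stats::median(object@gamma), object@q))
})

setMethod("show", "StateModel", function(object) {
    cat("StateModel with", object@K, "states over",
        length(object@states), "cells\n")
    cat("  cuts:", paste(sprintf("%.3f", object@cuts), collapse = ", "), "\n")
    print(table(state = object@states))
})

setMethod("show", "KineticModel", function(object) {
    cat("KineticModel (linear 5-state chain)\n")
    cat("  progression rates/day:",
        paste(sprintf("%.3g", object@rates), collapse = ", "), "\n")
    cat(sprintf("  entry %.3g/day, exit %.3g/day, pulse [%g, %g] d, label eff %.2g\n",
                object@entryRate, object@exitRate, object@pulseWindow[1],
                object@pulseWindow[2], object@labelEfficiency))
})

setMethod("show", "ChaseSeries", function(object) {
    cat("ChaseSeries:", length(object@time), "time points over",
        sprintf("[%g, %g] days\n", min(object@time), max(object@time)))
})
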