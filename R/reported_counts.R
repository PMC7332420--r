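#' Published cell counts of the coral single-cell atlas
#'
#' Cell counts reported for the Xenia sp. single-cell study this package's
#' methods are modelled on: per-cluster cell numbers of the 16-cluster atlas
#' and its total; the endosymbiotic lineage total with its five-state
#' partition and its three ordering subclusters; and the two cnidocyte
#' subclusters with their parent cluster total. Shipped as plain text under
#' \code{inst/extdata}.
#'
#' Note the endosymbiotic lineage total (382) pools regeneration and
#' non-regeneration samples, whereas the per-cluster atlas counts cover the
#' non-regeneration atlas (cluster 16: 185 cells); the two totals are
#' internally consistent but not equal.
#'
#' @return \code{data.frame} with columns \code{category}, \code{item},
#'   \code{count}.
#' @examples
#' head(reportedCellCounts())
#' @export
reportedCellCounts <- function() {
    utils::read.table(system.file("extdata", "reported_cell_counts.tsv",
                                  package = "symLineage"),
                      sep = "\t", header = TRUE,
                      colClasses = c("character", "character", "integer"))
}

#' Arithmetic consistency of the published cell counts
#'
#' Checks that every reported partition sums to its reported total: the 16
#' per-cluster counts against the atlas total, the five lineage states and
#' the three ordering subclusters against the endosymbiotic total, and the
#' two cnidocyte subclusters against their parent cluster count.
#'
#' @param counts output of \code{\link{reportedCellCounts}}.
#' @return \code{data.frame} with columns \code{check}, \code{sum},
#'   \code{total}, \code{consistent}.
#' @examples
#' checkCountConsistency()
#' @export
checkCountConsistency <- function(counts = reportedCellCounts()) {
    pick <- function(cat, item = NULL) {
        sel <- counts$category == cat
        if (!is.null(item)) sel <- sel & counts$item == item
        counts$count[sel]
    }
    checks <- list(
        clusters_vs_atlas_total =
            c(sum(pick("cluster")), pick("atlas", "total")),
        states_vs_endosymbiotic_total =
            c(sum(pick("state")), pick("endosymbiotic", "total")),
        ordering_subclusters_vs_endosymbiotic_total =
            c(sum(pick("ordering_subcluster")),
              pick("endosymbiotic", "total")),
        cnidocyte_subclusters_vs_cluster_total =
            c(sum(pick("cnidocyte_subcluster")),
              pick("cnidocyte", "total")),
        cnidocyte_total_vs_cluster_11 =
            c(pick("cnidocyte", "total"), pick("cluster", "11")))
    data.frame(check = names(checks),
               sum = vapply(checks, `[`, integer(1), 1L),
               total = vapply(checks, `[`, integer(1), 2L),
               consistent = vapply(checks, function(x) x[1L] == x[2L],
                                   logical(1)),
               row.names = NULL)
}
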