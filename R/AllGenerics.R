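#' @name accessors
#' @title Accessors for SpotCast classes
#' @description Slot accessors; user code should prefer these over `@`.
#' @param object a SpotCast S4 object.
#' @return The requested component: `exprValues` the expression matrix,
#'   `spotCoords` the coordinate matrix, `cellLabels` the per-cell factor,
#'   `profileMatrix` the centroid matrix, `parentMap` the row-to-parent
#'   mapping, `transferMatrix` the fitted Y matrix, `pairMatrix` /
#'   `pairWeights` the spot pair index matrix and weights, and the
#'   [TransferFit-class] accessors the corresponding fit components.
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("spotCoords", function(object) standardGeneric("spotCoords"))
#' @rdname accessors
#' @export
setGeneric("cellLabels", function(object) standardGeneric("cellLabels"))
#' @rdname accessors
#' @export
setGeneric("profileMatrix", function(object) standardGeneric("profileMatrix"))
#' @rdname accessors
#' @export
setGeneric("parentMap", function(object) standardGeneric("parentMap"))
#' @rdname accessors
#' @export
setGeneric("transferMatrix", function(object) standardGeneric("transferMatrix"))
#' @rdname accessors
#' @export
setGeneric("pairMatrix", function(object) standardGeneric("pairMatrix"))
#' @rdname accessors
#' @export
setGeneric("pairWeights", function(object) standardGeneric("pairWeights"))

#' Spot sizes of a transfer map
#'
#' The estimated number of cells per spot, i.e. the column sums of the
#' transfer matrix. Always 1 for single-cell resolution fits; within
#' `[1, capacity]` in general.
#'
#' @param object a [TransferMap-class] or [TransferFit-class].
#' @return Named numeric vector over spots.
#' @export
setGeneric("spotSizes", function(object) standardGeneric("spotSizes"))

#' Relative abundances of a transfer map
#'
#' Column-normalises the transfer matrix so each spot's composition sums
#' to one.
#'
#' @param object a [TransferMap-class] or [TransferFit-class].
#' @return Column-stochastic matrix with the same dimnames as the
#'   transfer matrix.
#' @export
setGeneric("relativeAbundance",
           function(object) standardGeneric("relativeAbundance"))

#' Hard labels of a transfer map
#'
#' Assigns each spot the population with the largest abundance; ties are
#' broken towards the smallest row index. Intended for single-cell
#' resolution fits.
#'
#' @param object a [TransferMap-class] or [TransferFit-class].
#' @return Named character vector of population labels, one per spot.
#' @export
setGeneric("hardLabels", function(object) standardGeneric("hardLabels"))

#' Collapse a sub-cluster transfer map to populations
#'
#' Sums the rows of a sub-cluster level transfer map within each parent
#' population. Column sums (spot sizes) are unchanged.
#'
#' @param object a [TransferMap-class] (or plain matrix) over
#'   sub-clusters.
#' @param parent named character vector mapping rows to parent
#'   populations; taken from the object when omitted.
#' @return A [TransferMap-class] (or matrix) over parent populations.
#' @export
setGeneric("collapseMap",
           function(object, parent = NULL) standardGeneric("collapseMap"))

#' @rdname accessors
#' @export
setGeneric("populationMap", function(object) standardGeneric("populationMap"))
#' @rdname accessors
#' @export
setGeneric("subclusterMap", function(object) standardGeneric("subclusterMap"))
#' @rdname accessors
#' @export
setGeneric("refProfiles", function(object) standardGeneric("refProfiles"))
#' @rdname accessors
#' @export
setGeneric("pairSet", function(object) standardGeneric("pairSet"))
#' @rdname accessors
#' @export
setGeneric("effectiveConfig", function(object) standardGeneric("effectiveConfig"))
#' @rdname accessors
#' @export
setGeneric("solveTrace", function(object) standardGeneric("solveTrace"))
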