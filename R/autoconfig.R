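#' Infer the per-spot capacity bound
#'
#' Single-cell resolution always has capacity 1. For multicell
#' resolution, the capacity reflects the platform: 20 for Visium (spots
#' hold 1-10 cells on average) and 200 for Spatial Transcriptomics
#' (spots hold up to 200 cells). Otherwise an explicit `capacity` wins,
#' or `totalCells / numSpots` when the expected total cell count of the
#' section is known. No automatic estimation of the total cell count is
#' provided: multicell data without a platform, capacity, or total count
#' is an error.
#'
#' @param mode `"high"` (single-cell resolution) or `"low"` (multicell).
#' @param platform optional `"visium"`, `"st"`, or `"other"`.
#' @param capacity optional explicit per-spot bound (overrides the
#'   platform value).
#' @param totalCells optional expected total cell count of the section.
#' @param numSpots number of spots (needed for the `totalCells`
#'   fallback).
#' @return The capacity, a single number >= 1.
#' @export
inferCapacity <- function(mode = c("high", "low"), platform = NULL,
                          capacity = NULL, totalCells = NULL,
                          numSpots = NULL) {
  mode <- match.arg(mode)
  if (mode == "high") return(1)
  if (!is.null(capacity)) {
    stopifnot(capacity >= 1)
    return(as.numeric(capacity))
  }
  if (!is.null(platform) && platform %in% c("visium", "st"))
    return(switch(platform, visium = 20, st = 200))
  if (!is.null(totalCells)) {
    stopifnot(!is.null(numSpots), numSpots >= 1)
    return(max(1, totalCells / numSpots))
  }
  stop("multicell-resolution data needs a capacity: give `platform` ",
       "('visium' or 'st'), an explicit `capacity`, or `totalCells` ",
       "(automatic estimation of the section's total cell count is not ",
       "provided)")
}

#' Infer the objective penalty weights from the data dimensions
#'
#' The weights are set so that all active objectives contribute roughly
#' equally: the spot term is bounded by the number of spots `|I|`, the
#' population and gene terms by the number of (sub-)populations `|C|`
#' and shared genes `|G|`, and the base-2 spatial term by
#' `capacity * |P|`. Single-cell resolution: `lambdaC = 0.5 |I|/|C|`,
#' `lambdaG = 1.25 |I|/|G|`, `lambdaS = 0.5 |I|/|P|`. Multicell:
#' `lambdaC = 0.6 |I|/|C|`, `lambdaG = 1.5 |I|/|G|`,
#' `lambdaS = 0.4 |I|/(n |P|)`. With an abundance prior,
#' `lambdaA = |I|/N = 1/n` (the prior is scaled to total `N = n |I|`);
#' without one the abundance objective is off (`lambdaA = 0`). An empty
#' pair set turns the spatial term off.
#'
#' @param numSpots,numPops,numGenes,numPairs counts `|I|`, `|C|`, `|G|`,
#'   `|P|` (populations after any sub-clustering).
#' @param capacity per-spot capacity `n`.
#' @param mode `"high"` or `"low"`.
#' @param hasPrior whether an abundance prior is supplied.
#' @param theta optional sparsity override; default [inferTheta()].
#' @return Weight list as from [objectiveWeights()], with `nbar` fixed
#'   to the capacity.
#' @export
inferWeights <- function(numSpots, numPops, numGenes, numPairs = 0,
                         capacity = 1, mode = c("high", "low"),
                         hasPrior = FALSE, theta = NULL) {
  mode <- match.arg(mode)
  stopifnot(numSpots >= 1, numPops >= 1, numGenes >= 1)
  if (mode == "high") {
    lambdaC <- 0.5 * numSpots / numPops
    lambdaG <- 1.25 * numSpots / numGenes
    lambdaS <- if (numPairs > 0) 0.5 * numSpots / numPairs else 0
  } else {
    lambdaC <- 0.6 * numSpots / numPops
    lambdaG <- 1.5 * numSpots / numGenes
    lambdaS <- if (numPairs > 0) 0.4 * numSpots / (capacity * numPairs) else 0
  }
  lambdaA <- if (hasPrior) 1 / capacity else 0
  if (is.null(theta)) theta <- inferTheta(mode)
  objectiveWeights(lambdaC = lambdaC, lambdaG = lambdaG, lambdaS = lambdaS,
                   lambdaA = lambdaA, theta = theta, nbar = capacity)
}

#' Infer the sparsity parameter
#'
#' 0.6 for single-cell resolution (favouring pure, one-population
#' spots), 0.4 for multicell resolution (allowing mixed compositions).
#' An explicit user value always wins over inference.
#'
#' @param mode `"high"` or `"low"`.
#' @return The sparsity parameter theta.
#' @export
inferTheta <- function(mode = c("high", "low")) {
  switch(match.arg(mode), high = 0.6, low = 0.4)
}
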