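#' Fit the full annotation transfer pipeline
#'
#' Orchestrates the whole method: sub-clusters the reference populations
#' ([subclusterReference()]), matches gene identifiers ([alignGenes()]),
#' builds the adjacent expression-similar spot pairs
#' ([buildSpatialGraph()]), infers all hyperparameters from the data
#' ([inferCapacity()], [inferWeights()], [inferTheta()]), runs the
#' Frank-Wolfe solver ([solveTransferModel()]), and collapses the
#' sub-cluster map to populations ([collapseMap()]).
#'
#' Expression values are consumed as provided — the model works with raw
#' counts as well as continuous intensities and never log- or
#' library-size-normalises internally (set `scaleTotals = TRUE` for an
#' optional per-row total-count scaling).
#'
#' @param ref a [ReferenceData-class].
#' @param spatial a [SpatialData-class].
#' @param mode `"high"` for single-cell resolution spots, `"low"` for
#'   multicell spots.
#' @param platform optional `"visium"` or `"st"` (sets the capacity for
#'   multicell data).
#' @param capacity optional explicit per-spot capacity bound.
#' @param totalCells optional expected total cell count (capacity
#'   fallback `totalCells / numSpots`).
#' @param prior optional named nonnegative vector of expected relative
#'   population abundances; internally rescaled so it sums to
#'   `capacity * numSpots`. An empty or NULL prior turns the abundance
#'   objective off.
#' @param theta optional sparsity override (default [inferTheta()]).
#' @param kappa sub-clusters per population (default 10; 1 disables
#'   sub-clustering).
#' @param minFraction sub-cluster outlier filter (default 0.01).
#' @param lambdaC,lambdaG,lambdaS,lambdaA optional overrides of the
#'   inferred penalty weights.
#' @param dBar,wBar optional overrides of the spatial graph thresholds.
#' @param scaleTotals scale each cell/spot row to the mean total first
#'   (off by default).
#' @param seed integer seed (sub-clustering restarts).
#' @param settings solver settings from [solverSettings()].
#' @return A [TransferFit-class]; see [populationMap()], [spotSizes()],
#'   [hardLabels()], [relativeAbundance()], [transferFeatures()].
#' @examples
#' spec <- simulationSpec(numPopulations = 4, genesTotal = 40,
#'                        cellsPerPopulation = 30, gridSide = 8,
#'                        numSpots = 64, seed = 1)
#' ref <- makeReference(spec)
#' hs <- makeHighresSpatial(spec)
#' fit <- fitTransfer(ref, hs$spatial, mode = "high", kappa = 1)
#' mean(hardLabels(fit) == as.character(hs$truth@labels))
#' @export
fitTransfer <- function(ref, spatial, mode = c("high", "low"),
                        platform = NULL, capacity = NULL,
                        totalCells = NULL, prior = NULL, theta = NULL,
                        kappa = 10, minFraction = 0.01,
                        lambdaC = NULL, lambdaG = NULL, lambdaS = NULL,
                        lambdaA = NULL, dBar = NULL, wBar = NULL,
                        scaleTotals = FALSE, seed = 0L,
                        settings = solverSettings()) {
  mode <- match.arg(mode)
  stopifnot(is(ref, "ReferenceData"), is(spatial, "SpatialData"))
  if (scaleTotals) {
    ref <- ReferenceData(.scaleRows(exprValues(ref)), cellLabels(ref))
    spatial <- SpatialData(.scaleRows(exprValues(spatial)),
                           spotCoords(spatial))
  }
  profiles <- subclusterReference(ref, kappa = kappa,
                                  minFraction = minFraction, seed = seed)
  genes <- alignGenes(ref, spatial)
  pairs <- buildSpatialGraph(spatial, dBar = dBar, wBar = wBar)
  I <- nrow(exprValues(spatial))
  n <- inferCapacity(mode, platform, capacity, totalCells, I)
  weights <- inferWeights(I, nrow(profileMatrix(profiles)),
                          length(genes$shared), nrow(pairMatrix(pairs)),
                          n, mode, hasPrior = length(prior) > 0,
                          theta = theta)
  if (!is.null(lambdaC)) weights$lambdaC <- lambdaC
  if (!is.null(lambdaG)) weights$lambdaG <- lambdaG
  if (!is.null(lambdaS)) weights$lambdaS <- lambdaS
  if (!is.null(lambdaA)) weights$lambdaA <- lambdaA
  scaledPrior <- NULL
  if (weights$lambdaA > 0) {
    pops <- unique(parentMap(profiles))
    missing <- setdiff(pops, names(prior))
    if (length(missing))
      stop("prior lacks populations: ", paste(missing, collapse = ", "))
    scaledPrior <- prior[pops] / sum(prior[pops]) * n * I
  }
  XS <- exprValues(spatial)[, genes$shared, drop = FALSE]
  XR <- profileMatrix(profiles)[, genes$shared, drop = FALSE]
  sol <- solveTransferModel(XS, XR, weights, capacity = n, pairs = pairs,
                            prior = scaledPrior,
                            parent = parentMap(profiles),
                            settings = settings)
  popMap <- collapseMap(sol$map)
  cfg <- list(mode = mode, platform = platform, capacity = n,
              theta = weights$theta, lambdaC = weights$lambdaC,
              lambdaG = weights$lambdaG, lambdaS = weights$lambdaS,
              lambdaA = weights$lambdaA, kappa = as.integer(kappa),
              minFraction = minFraction, dBar = pairs@dBar,
              wBar = pairs@wBar, numPairs = nrow(pairMatrix(pairs)),
              numSpots = I, numSharedGenes = length(genes$shared),
              numSubclusters = nrow(profileMatrix(profiles)),
              prior = scaledPrior, scaleTotals = scaleTotals,
              seed = as.integer(seed), maxIters = settings$maxIters,
              tol = settings$tol, stepRule = settings$stepRule)
  new("TransferFit", populationMap = popMap, subclusterMap = sol$map,
      profiles = profiles, pairs = pairs, config = cfg,
      trace = sol$trace)
}

.scaleRows <- function(m) {
  tot <- rowSums(m)
  tot[tot == 0] <- 1
  m / tot * mean(rowSums(m))
}

#' Transfer per-population features onto spots
#'
#' Projects any per-(sub-)population feature table — typically centroids
#' of genes measured in the reference but missing from the spatial panel
#' — onto the spots: `predicted[i, f] = sum_c Yhat[c, i] * F[c, f]`.
#' `Yhat` is the column-normalised map when `normalize` is on (the
#' default for single-cell resolution, where columns are membership
#' probabilities) and the raw abundances otherwise (the default for
#' multicell resolution, where predicted features scale with spot size).
#'
#' @param map a [TransferMap-class] or [TransferFit-class] (the
#'   sub-cluster map of a fit is used, matching the resolution at which
#'   profiles were transferred).
#' @param featureTable numeric matrix, (sub-)populations by features;
#'   rows must match the map's rows.
#' @param normalize logical; default depends on the capacity as
#'   described above.
#' @return Spots-by-features matrix.
#' @export
transferFeatures <- function(map, featureTable, normalize = NULL) {
  if (is(map, "TransferFit")) map <- subclusterMap(map)
  featureTable <- as.matrix(featureTable)
  Y <- transferMatrix(map)
  if (!identical(rownames(featureTable), rownames(Y)))
    stop("feature table rows must match the transfer map rows")
  if (is.null(normalize)) normalize <- all(map@capacity == 1)
  Yhat <- if (normalize) relativeAbundance(map) else Y
  crossprod(Yhat, featureTable)
}
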