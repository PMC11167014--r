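#' @rdname accessors
#' @aliases exprValues,ReferenceData-method
setMethod("exprValues", "ReferenceData", function(object) object@expr)
#' @rdname accessors
#' @aliases exprValues,SpatialData-method
setMethod("exprValues", "SpatialData", function(object) object@expr)
#' @rdname accessors
#' @aliases spotCoords,SpatialData-method
setMethod("spotCoords", "SpatialData", function(object) object@coords)
#' @rdname accessors
#' @aliases cellLabels,ReferenceData-method
setMethod("cellLabels", "ReferenceData", function(object) object@labels)
#' @rdname accessors
#' @aliases profileMatrix,ReferenceProfiles-method
setMethod("profileMatrix", "ReferenceProfiles", function(object) object@profiles)
#' @rdname accessors
#' @aliases parentMap,ReferenceProfiles-method
setMethod("parentMap", "ReferenceProfiles", function(object) object@parent)
#' @rdname accessors
#' @aliases parentMap,TransferMap-method
setMethod("parentMap", "TransferMap", function(object) object@parent)
#' @rdname accessors
#' @aliases transferMatrix,TransferMap-method
setMethod("transferMatrix", "TransferMap", function(object) object@Y)
#' @rdname accessors
#' @aliases pairMatrix,SpatialPairSet-method
setMethod("pairMatrix", "SpatialPairSet", function(object) object@pairs)
#' @rdname accessors
#' @aliases pairWeights,SpatialPairSet-method
setMethod("pairWeights", "SpatialPairSet", function(object) object@weights)

#' @rdname spotSizes
#' @aliases spotSizes,TransferMap-method
setMethod("spotSizes", "TransferMap", function(object) colSums(object@Y))

#' @rdname relativeAbundance
#' @aliases relativeAbundance,TransferMap-method
setMethod("relativeAbundance", "TransferMap", function(object) {
  cs <- colSums(object@Y)
  if (any(cs <= 0)) stop("column sums must be positive")
  sweep(object@Y, 2L, cs, "/")
})

#' @rdname hardLabels
#' @aliases hardLabels,TransferMap-method
setMethod("hardLabels", "TransferMap", function(object) {
  Y <- object@Y
  # max.col with ties.method = "first" breaks ties towards the lowest index
  idx <- max.col(t(Y), ties.method = "first")
  setNames(rownames(Y)[idx], colnames(Y))
})

#' @rdname collapseMap
#' @aliases collapseMap,TransferMap-method
setMethod("collapseMap", "TransferMap", function(object, parent = NULL) {
  if (is.null(parent)) parent <- object@parent
  Yc <- .collapseRows(object@Y, parent)
  TransferMap(Yc, capacity = object@capacity)
})

#' @rdname collapseMap
#' @aliases collapseMap,matrix-method
setMethod("collapseMap", "matrix", function(object, parent = NULL) {
  if (is.null(parent)) stop("a parent mapping is required for matrices")
  .collapseRows(object, parent)
})

.collapseRows <- function(Y, parent) {
  if (is.null(names(parent))) stop("parent must be a named vector")
  orphan <- setdiff(rownames(Y), names(parent))
  if (length(orphan))
    stop("rows without a parent population: ",
         paste(orphan, collapse = ", "))
  grp <- factor(parent[rownames(Y)], levels = unique(parent[rownames(Y)]))
  out <- rowsum(Y, grp, reorder = FALSE)
  rownames(out) <- levels(grp)
  out
}

#' @rdname accessors
#' @aliases populationMap,TransferFit-method
setMethod("populationMap", "TransferFit", function(object) object@populationMap)
#' @rdname accessors
#' @aliases subclusterMap,TransferFit-method
setMethod("subclusterMap", "TransferFit", function(object) object@subclusterMap)
#' @rdname accessors
#' @aliases refProfiles,TransferFit-method
setMethod("refProfiles", "TransferFit", function(object) object@profiles)
#' @rdname accessors
#' @aliases pairSet,TransferFit-method
setMethod("pairSet", "TransferFit", function(object) object@pairs)
#' @rdname accessors
#' @aliases effectiveConfig,TransferFit-method
setMethod("effectiveConfig", "TransferFit", function(object) object@config)
#' @rdname accessors
#' @aliases solveTrace,TransferFit-method
setMethod("solveTrace", "TransferFit", function(object) object@trace)
#' @rdname spotSizes
#' @aliases spotSizes,TransferFit-method
setMethod("spotSizes", "TransferFit",
          function(object) spotSizes(object@populationMap))
#' @rdname relativeAbundance
#' @aliases relativeAbundance,TransferFit-method
setMethod("relativeAbundance", "TransferFit",
          function(object) relativeAbundance(object@populationMap))
#' @rdname hardLabels
#' @aliases hardLabels,TransferFit-method
setMethod("hardLabels", "TransferFit",
          function(object) hardLabels(object@populationMap))

setMethod("show", "ReferenceData", function(object) {
  cat(sprintf("ReferenceData: %d cells x %d genes, %d categories\n",
              nrow(object@expr), ncol(object@expr), nlevels(object@labels)))
  cat("categories:", paste(head(levels(object@labels), 8L), collapse = ", "),
      if (nlevels(object@labels) > 8L) "..." else "", "\n")
})

setMethod("show", "SpatialData", function(object) {
  cat(sprintf("SpatialData: %d spots x %d genes, %dD coordinates\n",
              nrow(object@expr), ncol(object@expr), ncol(object@coords)))
})

setMethod("show", "ReferenceProfiles", function(object) {
  cat(sprintf(
    "ReferenceProfiles: %d profiles x %d genes (%d populations, kappa = %d)\n",
    nrow(object@profiles), ncol(object@profiles),
    length(unique(object@parent)), object@kappa))
})

setMethod("show", "SpatialPairSet", function(object) {
  cat(sprintf(
    "SpatialPairSet: %d pairs (dBar = %.4g, wBar = %.4g)\n",
    nrow(object@pairs), object@dBar, object@wBar))
})

setMethod("show", "TransferMap", function(object) {
  cat(sprintf("TransferMap: %d (sub-)populations x %d spots\n",
              nrow(object@Y), ncol(object@Y)))
  sz <- spotSizes(object)
  cat(sprintf("spot sizes: min %.3g, median %.3g, max %.3g (capacity %s)\n",
              min(sz), median(sz), max(sz),
              paste(format(unique(object@capacity)), collapse = "/")))
})

setMethod("show", "TransferFit", function(object) {
  cat("TransferFit\n")
  cat(sprintf(" populations: %d, sub-clusters: %d, spots: %d\n",
              nrow(object@populationMap@Y), nrow(object@subclusterMap@Y),
              ncol(object@populationMap@Y)))
  cfg <- object@config
  cat(sprintf(" mode: %s, capacity: %s, theta: %.3g\n",
              cfg$mode, format(cfg$capacity), cfg$theta))
  cat(sprintf(" lambdaC %.4g, lambdaG %.4g, lambdaS %.4g, lambdaA %.4g, |P| = %d\n",
              cfg$lambdaC, cfg$lambdaG, cfg$lambdaS, cfg$lambdaA, cfg$numPairs))
  cat(sprintf(" solver: %d iterations, final objective %.6g\n",
              nrow(object@trace),
              if (nrow(object@trace)) object@trace$objective[nrow(object@trace)]
              else NA_real_))
})

setMethod("show", "SyntheticTruth", function(object) {
  if (length(object@labels))
    cat(sprintf("SyntheticTruth: %d labelled single-cell spots\n",
                length(object@labels)))
  else
    cat(sprintf("SyntheticTruth: %d tiles, %d populations\n",
                ncol(object@composition), nrow(object@composition)))
})
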