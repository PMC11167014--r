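#' Annotated single-cell reference data
#'
#' Holds a cells-by-genes nonnegative expression matrix together with one
#' categorical annotation (e.g. cell type or layer) per cell. Works with
#' raw counts as well as continuous intensities; values are consumed as
#' provided.
#'
#' @slot expr numeric matrix, cells in rows, genes in columns, with unique
#'   row and column names.
#' @slot labels factor of length `nrow(expr)`; every level has at least one
#'   cell.
#' @aliases ReferenceData-class
#' @seealso [ReferenceData()], [computeCentroids()], [subclusterReference()]
#' @exportClass ReferenceData
setClass("ReferenceData", slots = c(expr = "matrix", labels = "factor"))

#' Spatially resolved expression data
#'
#' A spots-by-genes nonnegative expression matrix paired with 2D or 3D
#' spot coordinates. A "spot" is a single cell for high-resolution
#' platforms (MERFISH, osmFISH, ISS) or a multicell capture area for
#' low-resolution platforms (Visium, Spatial Transcriptomics).
#' Coordinates are used as-is, in the file's units; only relative
#' distances matter downstream.
#'
#' @slot expr numeric matrix, spots in rows, genes in columns.
#' @slot coords numeric matrix with one row per spot and 2 or 3 columns.
#' @aliases SpatialData-class
#' @seealso [SpatialData()], [buildSpatialGraph()], [fitTransfer()]
#' @exportClass SpatialData
setClass("SpatialData", slots = c(expr = "matrix", coords = "matrix"))

#' Centroid profiles of reference (sub-)populations
#'
#' Mean expression profiles of reference populations, possibly refined
#' into sub-clusters to capture within-population heterogeneity. Profiles
#' are stored over all reference genes; model fitting restricts them to
#' the genes shared with the spatial data, while feature transfer can use
#' the reference-exclusive genes.
#'
#' @slot profiles numeric matrix, (sub-)populations in rows, genes in
#'   columns; each row is the mean over its member cells.
#' @slot parent named character vector mapping each row of `profiles` to
#'   its parent population.
#' @slot memberCounts named numeric vector of member cells per row.
#' @slot kappa integer, the number of sub-clusters requested per
#'   population (1 means plain per-population centroids).
#' @aliases ReferenceProfiles-class
#' @seealso [computeCentroids()], [subclusterReference()]
#' @exportClass ReferenceProfiles
setClass("ReferenceProfiles",
  slots = c(profiles = "matrix", parent = "character",
            memberCounts = "numeric", kappa = "integer"))

#' Adjacent, expression-similar spot pairs
#'
#' The set of spot pairs that are both spatially adjacent (within distance
#' `dBar`) and similar in expression (cosine similarity over the full
#' spatial gene set at least `wBar`), with their similarity weights.
#' These pairs receive the Jensen-Shannon smoothing penalty during
#' fitting.
#'
#' @slot pairs integer matrix with two columns (i, j), i < j, indexing
#'   spots.
#' @slot weights numeric vector of cosine similarities, one per pair.
#' @slot dBar numeric distance threshold used.
#' @slot wBar numeric similarity cutoff used.
#' @aliases SpatialPairSet-class
#' @seealso [buildSpatialGraph()], [termSpatial()]
#' @exportClass SpatialPairSet
setClass("SpatialPairSet",
  slots = c(pairs = "matrix", weights = "numeric",
            dBar = "numeric", wBar = "numeric"))

#' Transfer map of (sub-)populations onto spots
#'
#' Nonnegative matrix `Y` with one row per reference (sub-)population and
#' one column per spot. Column sums lie between 1 and the per-spot
#' capacity; for single-cell resolution (capacity 1) each column is a
#' membership probability vector, for multicell resolution column entries
#' are absolute cell abundances and the column sum estimates the spot
#' size.
#'
#' @slot Y numeric matrix, (sub-)populations by spots, elementwise >= 0.
#' @slot capacity numeric vector of per-spot upper bounds (length 1 or
#'   one per spot).
#' @slot parent named character vector mapping rows to parent populations
#'   (identity when rows are populations).
#' @aliases TransferMap-class
#' @seealso [spotSizes()], [relativeAbundance()], [hardLabels()],
#'   [collapseMap()], [writeTransferMap()]
#' @exportClass TransferMap
setClass("TransferMap",
  slots = c(Y = "matrix", capacity = "numeric", parent = "character"))

#' Result of a full transfer fit
#'
#' Bundles the population-level transfer map with the sub-cluster map it
#' was collapsed from, the reference profiles, the spatial pair set, the
#' effective configuration (all inferred and overridden hyperparameters),
#' and the solver trace.
#'
#' @slot populationMap [TransferMap-class] over parent populations.
#' @slot subclusterMap [TransferMap-class] over sub-clusters (equal to the
#'   population map when `kappa = 1`).
#' @slot profiles [ReferenceProfiles-class] used for the fit.
#' @slot pairs [SpatialPairSet-class] used for the spatial penalty.
#' @slot config list of effective parameters (lambdas, theta, capacity,
#'   dBar, wBar, pair count, seed, ...).
#' @slot trace data.frame with one row per Frank-Wolfe iteration
#'   (objective, step size, duality gap).
#' @aliases TransferFit-class
#' @seealso [fitTransfer()]
#' @exportClass TransferFit
setClass("TransferFit",
  slots = c(populationMap = "TransferMap", subclusterMap = "TransferMap",
            profiles = "ReferenceProfiles", pairs = "SpatialPairSet",
            config = "list", trace = "data.frame"))

#' Ground truth bookkeeping for synthetic benchmarks
#'
#' Records what the synthetic generator knows: per-spot population labels
#' for single-cell resolution data, and per-tile composition counts and
#' cell counts after pooling to multicell resolution.
#'
#' @slot labels factor of per-spot population labels (single-cell
#'   resolution; empty after pooling).
#' @slot composition numeric matrix, populations by tiles, of member-cell
#'   counts per population (zero columns for single-cell resolution).
#' @slot cellCount numeric vector of cells per tile.
#' @slot members list mapping each tile to the indices of its member
#'   cells.
#' @aliases SyntheticTruth-class
#' @seealso [makeHighresSpatial()], [poolToLowres()]
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  slots = c(labels = "factor", composition = "matrix",
            cellCount = "numeric", members = "list"))

.checkExprMatrix <- function(x, what = "expr") {
  if (!is.numeric(x)) return(sprintf("%s must be numeric", what))
  if (anyNA(x)) return(sprintf("%s contains missing values", what))
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    return(sprintf("%s contains a negative value at row %d, column %d",
                   what, bad[1L], bad[2L]))
  }
  if (is.null(rownames(x)) || is.null(colnames(x)))
    return(sprintf("%s must have row and column names", what))
  if (anyDuplicated(rownames(x))) return("duplicated row identifiers")
  if (anyDuplicated(colnames(x))) return("duplicated gene identifiers")
  TRUE
}

setValidity("ReferenceData", function(object) {
  msg <- .checkExprMatrix(object@expr)
  if (!isTRUE(msg)) return(msg)
  if (length(object@labels) != nrow(object@expr))
    return("one label per cell is required")
  if (anyNA(object@labels)) return("labels contain missing values")
  if (any(table(object@labels) < 1L) || nlevels(object@labels) < 1L)
    return("every category must have at least one cell")
  TRUE
})

setValidity("SpatialData", function(object) {
  msg <- .checkExprMatrix(object@expr)
  if (!isTRUE(msg)) return(msg)
  if (nrow(object@coords) != nrow(object@expr))
    return("number of coordinate rows must equal the number of spots")
  if (!ncol(object@coords) %in% c(2L, 3L))
    return("coordinates must have 2 or 3 columns")
  if (!all(is.finite(object@coords)))
    return("coordinates must be finite")
  TRUE
})

setValidity("ReferenceProfiles", function(object) {
  msg <- .checkExprMatrix(object@profiles, "profiles")
  if (!isTRUE(msg)) return(msg)
  if (length(object@parent) != nrow(object@profiles) ||
      !identical(names(object@parent), rownames(object@profiles)))
    return("parent must be named by the profile rows")
  if (length(object@memberCounts) != nrow(object@profiles))
    return("memberCounts must have one entry per profile row")
  if (any(object@memberCounts < 1)) return("memberCounts must be >= 1")
  if (object@kappa < 1L) return("kappa must be >= 1")
  TRUE
})

setValidity("SpatialPairSet", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns")
  if (nrow(p) != length(object@weights))
    return("one weight per pair is required")
  if (nrow(p) > 0L) {
    if (any(p[, 1L] >= p[, 2L])) return("pairs must satisfy i < j")
    if (anyDuplicated(p)) return("duplicated pairs")
  }
  TRUE
})

setValidity("TransferMap", function(object) {
  Y <- object@Y
  if (anyNA(Y) || any(Y < 0)) return("Y must be nonnegative")
  if (is.null(rownames(Y)) || (ncol(Y) > 0L && is.null(colnames(Y))))
    return("Y must carry (sub-)population and spot identifiers")
  n <- object@capacity
  if (!length(n) %in% c(1L, ncol(Y)))
    return("capacity must have length 1 or one entry per spot")
  if (any(n < 1)) return("capacity must be >= 1")
  if (ncol(Y) > 0L) {
    cs <- colSums(Y)
    tol <- 1e-8
    if (any(cs < 1 - tol) || any(cs > n + tol))
      return("column sums must lie within [1, capacity]")
  }
  if (!identical(names(object@parent), rownames(Y)))
    return("parent must be named by the rows of Y")
  TRUE
})

#' Construct a ReferenceData object
#'
#' @param expr numeric matrix of cells by genes (nonnegative), with row
#'   and column names.
#' @param labels character or factor of per-cell annotations, one per row
#'   of `expr`.
#' @return A validated [ReferenceData-class] object. Unused factor levels
#'   are dropped.
#' @examples
#' expr <- matrix(rpois(12, 4), 4, 3,
#'                dimnames = list(paste0("cell", 1:4), paste0("g", 1:3)))
#' ReferenceData(expr, c("A", "A", "B", "B"))
#' @export
ReferenceData <- function(expr, labels) {
  expr <- .asExprMatrix(expr)
  labels <- droplevels(as.factor(labels))
  new("ReferenceData", expr = expr, labels = labels)
}

#' Construct a SpatialData object
#'
#' @param expr numeric matrix of spots by genes (nonnegative), with row
#'   and column names.
#' @param coords numeric matrix (or data.frame) of spot coordinates, 2 or
#'   3 columns, in the same row order as `expr`.
#' @return A validated [SpatialData-class] object.
#' @examples
#' expr <- matrix(rpois(6, 4), 3, 2,
#'                dimnames = list(paste0("s", 1:3), c("g1", "g2")))
#' SpatialData(expr, cbind(x = 1:3, y = 0))
#' @export
SpatialData <- function(expr, coords) {
  expr <- .asExprMatrix(expr)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(rownames(coords)) && nrow(coords) == nrow(expr))
    rownames(coords) <- rownames(expr)
  new("SpatialData", expr = expr, coords = coords)
}

#' Construct a TransferMap object
#'
#' @param Y numeric nonnegative matrix, (sub-)populations by spots, with
#'   dimnames; column sums must lie in `[1, capacity]`.
#' @param capacity numeric per-spot capacity bound (length 1 or
#'   `ncol(Y)`).
#' @param parent optional named character vector mapping rows to parent
#'   populations; defaults to the identity map.
#' @return A validated [TransferMap-class] object.
#' @examples
#' Y <- matrix(c(0.2, 0.8), 2, 1, dimnames = list(c("A", "B"), "s1"))
#' TransferMap(Y, capacity = 1)
#' @export
TransferMap <- function(Y, capacity = 1, parent = NULL) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (is.null(parent)) parent <- setNames(rownames(Y), rownames(Y))
  new("TransferMap", Y = Y, capacity = as.numeric(capacity),
      parent = parent)
}

.asExprMatrix <- function(expr) {
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  if (!is.null(rownames(expr))) rownames(expr) <- trimws(rownames(expr))
  if (!is.null(colnames(expr))) colnames(expr) <- trimws(colnames(expr))
  expr
}
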