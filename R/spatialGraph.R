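#' Data-driven adjacency distance threshold
#'
#' Pools, for each spot, the Euclidean distances to its 8 nearest
#' neighbouring spots (mimicking the 8 adjacent tiles of a regular 2D
#' grid) and returns the 90th percentile of the pooled values
#' (`stats::quantile` type 7, i.e. linear interpolation between order
#' statistics). With fewer than 9 spots the maximum pairwise distance is
#' returned instead. Duplicated coordinates contribute their true zero
#' distances.
#'
#' @param coords numeric matrix of spot coordinates (or a
#'   [SpatialData-class]).
#' @param k number of nearest neighbours pooled per spot (default 8).
#' @param prob percentile of the pooled distances (default 0.9).
#' @return The distance threshold, a single number.
#' @export
adjacencyThreshold <- function(coords, k = 8L, prob = 0.9) {
  if (is(coords, "SpatialData")) coords <- spotCoords(coords)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n <= 1L) return(0)
  if (n < k + 1L) {
    return(max(dist(coords)))
  }
  pooled <- .knnDistances(coords, k)
  as.numeric(quantile(pooled, probs = prob, type = 7, names = FALSE))
}

# exact k-nearest-neighbour distances, chunked so memory stays O(chunk * n)
.knnDistances <- function(coords, k) {
  n <- nrow(coords)
  sq <- rowSums(coords^2)
  chunk <- max(1L, min(n, as.integer(2^22 / n)))
  out <- numeric(n * k)
  pos <- 0L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(coords[idx, , drop = FALSE], coords)
    d2[cbind(seq_along(idx), idx)] <- Inf   # exclude self
    d2[d2 < 0] <- 0
    for (r in seq_along(idx)) {
      kd <- sqrt(sort.int(d2[r, ], partial = k)[seq_len(k)])
      out[pos + seq_len(k)] <- kd
      pos <- pos + k
    }
  }
  out
}

# candidate pairs (i < j) within distance dBar, with their distances
.candidatePairs <- function(coords, dBar) {
  n <- nrow(coords)
  sq <- rowSums(coords^2)
  chunk <- max(1L, min(n, as.integer(2^22 / n)))
  ii <- list(); jj <- list()
  b <- 0L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(coords[idx, , drop = FALSE], coords)
    hit <- which(d2 <= dBar^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit)) {
      a <- idx[hit[, 1L]]; bcol <- hit[, 2L]
      keep <- a < bcol
      if (any(keep)) {
        b <- b + 1L
        ii[[b]] <- a[keep]; jj[[b]] <- bcol[keep]
      }
    }
  }
  cbind(i = as.integer(unlist(ii)), j = as.integer(unlist(jj)))
}

# cosine similarity of spot pairs over the full spatial gene set;
# all-zero spots get NA and are excluded by callers (with a warning)
.pairCosine <- function(expr, pairs) {
  nrm <- sqrt(rowSums(expr^2))
  w <- rowSums(expr[pairs[, 1L], , drop = FALSE] *
               expr[pairs[, 2L], , drop = FALSE]) /
       (nrm[pairs[, 1L]] * nrm[pairs[, 2L]])
  w[!is.finite(w)] <- NA_real_
  w
}

#' Data-driven similarity cutoff for spot pairs
#'
#' Among candidate pairs within the distance threshold, the cutoff is the
#' maximum of `floor` (default 0.6) and the largest similarity value that
#' keeps the number of retained pairs at or below the number of spots —
#' so the spatial penalty scales linearly in the number of spots. Ties at
#' the cutoff are kept (the cutoff is defined on the value, not the
#' count), so the pair set may slightly exceed the spot count.
#'
#' @param spatial a [SpatialData-class].
#' @param dBar distance threshold (see [adjacencyThreshold()]).
#' @param floor minimum cutoff, in `[-1, 1]`.
#' @return The similarity cutoff, a single number.
#' @export
similarityCutoff <- function(spatial, dBar, floor = 0.6) {
  stopifnot(floor >= -1, floor <= 1)
  coords <- spotCoords(spatial)
  pairs <- .candidatePairs(coords, dBar)
  if (!nrow(pairs)) return(floor)
  w <- .pairCosine(exprValues(spatial), pairs)
  w <- w[!is.na(w)]
  nSpots <- nrow(coords)
  if (sum(w >= floor) <= nSpots) return(floor)
  wSorted <- sort(w, decreasing = TRUE)
  max(floor, wSorted[nSpots])
}

#' Build the set of adjacent, expression-similar spot pairs
#'
#' Enumerates all pairs (i, j), i < j, whose spots lie within `dBar` of
#' each other and whose cosine similarity — computed on the full spatial
#' gene set, not just the genes shared with the reference — is at least
#' `wBar`. Spots with all-zero expression join no pair (cosine
#' undefined); a warning reports them.
#'
#' @param spatial a [SpatialData-class].
#' @param dBar distance threshold.
#' @param wBar similarity cutoff.
#' @return A [SpatialPairSet-class].
#' @seealso [buildSpatialGraph()] for the fully data-driven version.
#' @export
buildPairs <- function(spatial, dBar, wBar) {
  stopifnot(is.finite(dBar), is.finite(wBar))
  coords <- spotCoords(spatial)
  expr <- exprValues(spatial)
  zero <- rowSums(expr) == 0
  if (any(zero))
    warning(sum(zero), " spot(s) with all-zero expression join no pair")
  pairs <- .candidatePairs(coords, dBar)
  if (nrow(pairs)) {
    w <- .pairCosine(expr, pairs)
    keep <- !is.na(w) & w >= wBar
    pairs <- pairs[keep, , drop = FALSE]
    w <- w[keep]
  } else w <- numeric()
  new("SpatialPairSet", pairs = pairs, weights = as.numeric(w),
      dBar = as.numeric(dBar), wBar = as.numeric(wBar))
}

#' Construct the spatial pair set with data-driven thresholds
#'
#' Convenience wrapper: infers the distance threshold with
#' [adjacencyThreshold()] and the similarity cutoff with
#' [similarityCutoff()] unless explicit values are given, then calls
#' [buildPairs()].
#'
#' @param spatial a [SpatialData-class].
#' @param dBar,wBar optional explicit thresholds.
#' @param floor minimum similarity cutoff used during auto-selection.
#' @return A [SpatialPairSet-class].
#' @export
buildSpatialGraph <- function(spatial, dBar = NULL, wBar = NULL,
                              floor = 0.6) {
  if (is.null(dBar)) dBar <- adjacencyThreshold(spotCoords(spatial))
  if (is.null(wBar)) wBar <- similarityCutoff(spatial, dBar, floor)
  buildPairs(spatial, dBar, wBar)
}

#' Export a spot pair set as an edge list
#'
#' @param pairs a [SpatialPairSet-class].
#' @param path output path for a 3-column (i, j, w) delimited file.
#' @return `path`, invisibly.
#' @export
writePairSet <- function(pairs, path) {
  data.table::fwrite(data.table::data.table(
    i = pairMatrix(pairs)[, 1L], j = pairMatrix(pairs)[, 2L],
    w = pairWeights(pairs)), path)
  invisible(path)
}
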