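#' Per-population centroid profiles
#'
#' Computes, for every annotation category, the arithmetic mean
#' expression of its member cells. This is the kappa = 1 special case of
#' [subclusterReference()].
#'
#' @param ref a [ReferenceData-class].
#' @param genes optional character vector restricting the genes (kept in
#'   the given order); default all reference genes.
#' @return A [ReferenceProfiles-class] with one row per category and an
#'   identity parent map. An all-zero centroid triggers a warning, since
#'   it is degenerate for the cosine metric.
#' @examples
#' rd <- ReferenceData(matrix(c(1, 3, 3, 1), 2, 2,
#'   dimnames = list(c("c1", "c2"), c("g1", "g2"))), c("A", "A"))
#' profileMatrix(computeCentroids(rd))  # (2, 2)
#' @export
computeCentroids <- function(ref, genes = NULL) {
  expr <- exprValues(ref)
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(expr))
    if (length(missing))
      stop("genes not present in the reference: ",
           paste(head(missing, 5L), collapse = ", "))
    expr <- expr[, genes, drop = FALSE]
  }
  lab <- cellLabels(ref)
  counts <- as.numeric(table(lab))
  cent <- rowsum(expr, lab) / counts
  rownames(cent) <- levels(lab)
  if (any(rowSums(cent) == 0))
    warning("all-zero centroid for: ",
            paste(rownames(cent)[rowSums(cent) == 0], collapse = ", "),
            " (degenerate for the cosine metric)")
  new("ReferenceProfiles", profiles = cent,
      parent = setNames(levels(lab), levels(lab)),
      memberCounts = setNames(counts, levels(lab)), kappa = 1L)
}

#' Sub-cluster reference populations to capture heterogeneity
#'
#' A single centroid can misrepresent a heterogeneous population, so each
#' population is partitioned into up to `kappa` sub-clusters by k-means
#' (10 restarts, deterministic given `seed`) on all reference genes —
#' including genes the spatial data does not measure. Sub-clusters
#' holding fewer than `minFraction` of the population's cells are treated
#' as outliers and dropped. Sub-cluster centroids replace the population
#' centroids during fitting and are re-aggregated afterwards with
#' [collapseMap()].
#'
#' @param ref a [ReferenceData-class].
#' @param kappa maximum sub-clusters per population (default 10). A
#'   population with fewer cells than `kappa` yields at most one cluster
#'   per cell. `kappa = 1` reproduces [computeCentroids()].
#' @param minFraction drop sub-clusters with fewer than this fraction of
#'   the population's cells (default 0.01).
#' @param seed integer seed controlling the k-means restarts.
#' @param logTransform cluster on `log1p` expression instead of the raw
#'   values (centroids are always means of the raw values).
#' @return A [ReferenceProfiles-class] whose rows are named
#'   `<population>#<k>` (or the bare population name when kappa = 1).
#' @export
subclusterReference <- function(ref, kappa = 10, minFraction = 0.01,
                                seed = 0L, logTransform = FALSE) {
  stopifnot(kappa >= 1, minFraction >= 0, minFraction < 1)
  kappa <- as.integer(kappa)
  if (kappa == 1L) return(computeCentroids(ref))
  expr <- exprValues(ref)
  lab <- cellLabels(ref)
  rows <- list(); parents <- character(); counts <- numeric()
  for (pop in levels(lab)) {
    cells <- expr[lab == pop, , drop = FALSE]
    feat <- if (logTransform) log1p(cells) else cells
    k <- min(kappa, nrow(cells), nrow(unique(feat)))
    cl <- if (k == 1L) rep(1L, nrow(cells)) else
      withLocalSeed(seed + match(pop, levels(lab)),
                    kmeans(feat, centers = k, nstart = 10,
                           iter.max = 100)$cluster)
    tab <- table(cl)
    keep <- names(tab)[tab >= minFraction * nrow(cells)]
    j <- 0L
    for (g in keep) {
      j <- j + 1L
      nm <- paste0(pop, "#", j)
      rows[[nm]] <- colMeans(cells[cl == g, , drop = FALSE])
      parents[nm] <- pop
      counts[nm] <- sum(cl == g)
    }
  }
  cent <- do.call(rbind, rows)
  new("ReferenceProfiles", profiles = cent, parent = parents,
      memberCounts = counts, kappa = kappa)
}
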