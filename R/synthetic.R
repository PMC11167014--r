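#' Specification of a synthetic benchmark
#'
#' Describes a synthetic tissue emulating the structure of imaging-based
#' single-cell resolution SRT benchmarks: distinct per-population
#' expression programs with elevated marker genes, optional
#' within-population subtypes (to exercise sub-clustering), spatially
#' contiguous cell-type regions (to exercise the spatial penalty),
#' grid pooling into multicell tiles with known compositions,
#' multiplicative uniform expression noise, and shared-gene subsetting.
#'
#' @param numPopulations number of cell populations.
#' @param genesTotal total genes; the first
#'   `numPopulations * markersPerPopulation` are population markers.
#' @param markersPerPopulation marker genes per population.
#' @param markerFold fold elevation of a population's markers over the
#'   baseline (default 10).
#' @param cellsPerPopulation reference cells drawn per population.
#' @param withinPopSubtypes subtypes per population (1 = homogeneous);
#'   each subtype elevates its own small gene set by `subtypeFold`.
#' @param subtypeFold fold elevation of subtype-specific genes.
#' @param spatialLayout `"regions"` (labels form contiguous Voronoi
#'   regions, one seed per population) or `"random"` (labels uniform in
#'   space).
#' @param positionMode `"random"` (cells uniform in the square — cell
#'   densities then vary across tiles like real tissue) or `"grid"`
#'   (regular lattice).
#' @param gridSide side length of the square domain (and of the lattice
#'   for `positionMode = "grid"`).
#' @param numSpots cells placed for `positionMode = "random"` (default
#'   `gridSide^2`).
#' @param tileLength side of the square pooling tiles (default chosen so
#'   tiles hold roughly 10 cells, a Visium-like density).
#' @param noisePhi half-width of the multiplicative uniform noise
#'   (entries are scaled by `1 + beta`, `beta ~ U(-phi, phi)`); 0, 0.25
#'   and 0.5 are the conventional settings.
#' @param sharedGeneCount genes retained in the spatial panel (the first
#'   `sharedGeneCount` genes, in stored order).
#' @param baselineRange range of the per-gene baseline expression level
#'   (drawn once, shared across populations).
#' @param seed integer seed; every generator draw derives from it.
#' @return A validated `SimulationSpec` list.
#' @seealso [makeReference()], [makeHighresSpatial()], [poolToLowres()],
#'   [addNoise()], [subsetGenes()]
#' @export
simulationSpec <- function(numPopulations = 10, genesTotal = 100,
                           markersPerPopulation = 5, markerFold = 10,
                           cellsPerPopulation = 100,
                           withinPopSubtypes = 1, subtypeFold = 4,
                           spatialLayout = c("regions", "random"),
                           positionMode = c("random", "grid"),
                           gridSide = 45, numSpots = NULL,
                           tileLength = 3.2, noisePhi = 0,
                           sharedGeneCount = genesTotal,
                           baselineRange = c(0.5, 2), seed = 1L) {
  spatialLayout <- match.arg(spatialLayout)
  positionMode <- match.arg(positionMode)
  if (is.null(numSpots)) numSpots <- gridSide^2
  stopifnot(numPopulations >= 1, genesTotal >= 1,
            markersPerPopulation >= 1, cellsPerPopulation >= 1,
            withinPopSubtypes >= 1, gridSide >= 1, tileLength > 0,
            noisePhi >= 0, sharedGeneCount >= 1,
            sharedGeneCount <= genesTotal,
            numPopulations * markersPerPopulation <= genesTotal)
  structure(list(
    numPopulations = numPopulations, genesTotal = genesTotal,
    markersPerPopulation = markersPerPopulation, markerFold = markerFold,
    cellsPerPopulation = cellsPerPopulation,
    withinPopSubtypes = withinPopSubtypes, subtypeFold = subtypeFold,
    spatialLayout = spatialLayout, positionMode = positionMode,
    gridSide = gridSide, numSpots = numSpots, tileLength = tileLength,
    noisePhi = noisePhi, sharedGeneCount = sharedGeneCount,
    baselineRange = baselineRange, seed = as.integer(seed)),
    class = "SimulationSpec")
}

# per-(population, subtype) Poisson mean programs; deterministic given
# the spec seed so the reference and the spatial data share programs
.populationPrograms <- function(spec) {
  withLocalSeed(spec$seed, {
    G <- spec$genesTotal
    base <- runif(G, spec$baselineRange[1L], spec$baselineRange[2L])
    pops <- paste0("pop", seq_len(spec$numPopulations))
    nonMarkers <- setdiff(seq_len(G),
                          seq_len(spec$numPopulations * spec$markersPerPopulation))
    programs <- list()
    for (p in seq_len(spec$numPopulations)) {
      prog <- base
      mk <- (p - 1L) * spec$markersPerPopulation +
        seq_len(spec$markersPerPopulation)
      prog[mk] <- prog[mk] * spec$markerFold
      for (s in seq_len(spec$withinPopSubtypes)) {
        sProg <- prog
        if (spec$withinPopSubtypes > 1L && length(nonMarkers)) {
          su <- sample(nonMarkers,
                       min(spec$markersPerPopulation, length(nonMarkers)))
          sProg[su] <- sProg[su] * spec$subtypeFold
        }
        programs[[paste0(pops[p], ".s", s)]] <-
          list(pop = pops[p], subtype = s, mean = sProg)
      }
    }
    list(populations = pops, programs = programs,
         genes = paste0("g", seq_len(G)))
  })
}

#' Generate an annotated synthetic reference
#'
#' Draws `cellsPerPopulation` cells per population (split evenly over
#' subtypes) as independent Poisson counts around the population's
#' (subtype's) program vector. Deterministic given the spec seed.
#'
#' @param spec a [simulationSpec()].
#' @return A [ReferenceData-class] labelled at the population level.
#' @export
makeReference <- function(spec) {
  pg <- .populationPrograms(spec)
  withLocalSeed(spec$seed + 1L, {
    rows <- list(); labs <- character()
    for (nm in names(pg$programs)) {
      prg <- pg$programs[[nm]]
      nCells <- ceiling(spec$cellsPerPopulation / spec$withinPopSubtypes)
      m <- matrix(rpois(nCells * spec$genesTotal, rep(prg$mean, each = nCells)),
                  nCells, spec$genesTotal)
      rows[[nm]] <- m
      labs <- c(labs, rep(prg$pop, nCells))
    }
    expr <- do.call(rbind, rows)
    dimnames(expr) <- list(paste0("cell", seq_len(nrow(expr))), pg$genes)
    ReferenceData(expr, labs)
  })
}

#' Generate single-cell resolution spatial data with known labels
#'
#' Places cells in a square domain (uniformly at random or on a
#' lattice), assigns each cell a population either by contiguous Voronoi
#' regions (one seed point per population) or uniformly at random, draws
#' its expression from the population program restricted to the first
#' `sharedGeneCount` genes, and records the true label of every spot.
#'
#' @param spec a [simulationSpec()].
#' @return List with `spatial` (a [SpatialData-class]) and `truth` (a
#'   [SyntheticTruth-class] carrying the per-spot labels).
#' @export
makeHighresSpatial <- function(spec) {
  pg <- .populationPrograms(spec)
  withLocalSeed(spec$seed + 2L, {
    L <- spec$gridSide
    if (spec$positionMode == "grid") {
      side <- ceiling(sqrt(spec$numSpots))
      gx <- seq(0, L, length.out = side)
      coords <- as.matrix(expand.grid(x = gx, y = gx))[seq_len(spec$numSpots), ]
    } else {
      coords <- cbind(x = runif(spec$numSpots, 0, L),
                      y = runif(spec$numSpots, 0, L))
    }
    nPop <- spec$numPopulations
    if (spec$spatialLayout == "regions") {
      centers <- cbind(runif(nPop, 0, L), runif(nPop, 0, L))
      d2 <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
        2 * tcrossprod(coords, centers)
      popIdx <- max.col(-d2, ties.method = "first")
    } else {
      popIdx <- sample.int(nPop, spec$numSpots, replace = TRUE)
    }
    subIdx <- sample.int(spec$withinPopSubtypes, spec$numSpots,
                         replace = TRUE)
    panel <- seq_len(spec$sharedGeneCount)
    expr <- matrix(0, spec$numSpots, length(panel))
    for (nm in names(pg$programs)) {
      prg <- pg$programs[[nm]]
      sel <- which(popIdx == match(prg$pop, pg$populations) &
                     subIdx == prg$subtype)
      if (length(sel))
        expr[sel, ] <- matrix(
          rpois(length(sel) * length(panel),
                rep(prg$mean[panel], each = length(sel))),
          length(sel), length(panel))
    }
    dimnames(expr) <- list(paste0("spot", seq_len(spec$numSpots)),
                           pg$genes[panel])
    rownames(coords) <- rownames(expr)
    labels <- factor(pg$populations[popIdx], levels = pg$populations)
    spatial <- SpatialData(expr, coords)
    if (spec$noisePhi > 0)
      spatial <- addNoise(spatial, spec$noisePhi, seed = spec$seed + 3L)
    list(spatial = spatial,
         truth = new("SyntheticTruth", labels = labels,
                     composition = matrix(0, nPop, 0,
                       dimnames = list(pg$populations, NULL)),
                     cellCount = rep(1, spec$numSpots), members = list()))
  })
}

#' Pool single-cell spots into multicell grid tiles
#'
#' Splits the domain into square tiles of side `tileLength`, sums the
#' expression of the member cells of each nonempty tile (empty tiles are
#' dropped), places the pooled spot at the tile centre, and records the
#' true per-tile composition counts and cell counts.
#'
#' @param highres a [SpatialData-class] of single-cell spots.
#' @param truth the matching [SyntheticTruth-class] (per-spot labels).
#' @param tileLength tile side, in coordinate units.
#' @return List with `spatial` (pooled [SpatialData-class]) and `truth`
#'   (a [SyntheticTruth-class] with `composition`, `cellCount`,
#'   `members`).
#' @export
poolToLowres <- function(highres, truth, tileLength) {
  stopifnot(tileLength > 0)
  coords <- spotCoords(highres)
  expr <- exprValues(highres)
  tx <- floor(coords[, 1L] / tileLength)
  ty <- floor(coords[, 2L] / tileLength)
  tile <- factor(paste0(tx, "_", ty))
  pooled <- rowsum(expr, tile, reorder = FALSE)
  rownames(pooled) <- paste0("tile", seq_len(nrow(pooled)))
  # first-appearance order matches rowsum(reorder = FALSE)
  ord <- unique(as.character(tile))
  centers <- cbind(
    x = (as.numeric(sub("_.*", "", ord)) + 0.5) * tileLength,
    y = (as.numeric(sub(".*_", "", ord)) + 0.5) * tileLength)
  rownames(centers) <- rownames(pooled)
  members <- split(seq_along(tile), factor(as.character(tile), levels = ord))
  names(members) <- rownames(pooled)
  pops <- levels(truth@labels)
  comp <- vapply(members, function(ix)
    as.numeric(table(factor(truth@labels[ix], levels = pops))),
    numeric(length(pops)))
  comp <- matrix(comp, nrow = length(pops),
                 dimnames = list(pops, rownames(pooled)))
  list(spatial = SpatialData(pooled, centers),
       truth = new("SyntheticTruth",
                   labels = factor(character(), levels = pops),
                   composition = comp, cellCount = colSums(comp),
                   members = members))
}

#' Multiplicative uniform expression noise
#'
#' Multiplies every entry by an independent factor `1 + beta` with
#' `beta ~ U(-phi, phi)`, emulating platform measurement-sensitivity
#' fluctuations. `phi = 0` is the identity; `phi > 1` would create
#' negative values and is an error.
#'
#' @param spatial a [SpatialData-class].
#' @param phi noise half-width in `[0, 1]`.
#' @param seed integer seed.
#' @return A [SpatialData-class] with perturbed expression.
#' @export
addNoise <- function(spatial, phi, seed = 0L) {
  if (phi < 0 || phi > 1)
    stop("phi must lie in [0, 1]; larger values would create negative ",
         "expression")
  if (phi == 0) return(spatial)
  expr <- exprValues(spatial)
  noisy <- withLocalSeed(seed,
    expr * (1 + runif(length(expr), -phi, phi)))
  SpatialData(noisy, spotCoords(spatial))
}

#' Restrict the spatial panel to the first genes
#'
#' Emulates limited gene coverage by keeping the first `count` genes in
#' stored order (the conventional shared-gene subsetting of panel-based
#' benchmarks).
#'
#' @param spatial a [SpatialData-class].
#' @param count number of genes to keep, `1 <= count <= ncol`.
#' @return A [SpatialData-class] with the reduced panel.
#' @export
subsetGenes <- function(spatial, count) {
  expr <- exprValues(spatial)
  if (count < 1 || count > ncol(expr))
    stop("count must be between 1 and the number of genes")
  SpatialData(expr[, seq_len(count), drop = FALSE], spotCoords(spatial))
}
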