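#' Read an expression matrix from disk
#'
#' Reads either a dense delimited table (CSV/TSV; first column holds row
#' identifiers, header holds gene identifiers) or a MatrixMarket
#' coordinate file with sidecar row/column label files (one identifier
#' per line). The on-disk orientation is observations (cells or spots) in
#' rows and genes in columns. Negative entries are rejected with the
#' offending cell named.
#'
#' @param path path to the matrix file.
#' @param format `"auto"` (MatrixMarket for `.mtx` files, dense
#'   otherwise), `"dense"`, or `"matrixmarket"`.
#' @param rowFile,colFile label sidecar files for the MatrixMarket
#'   format; default `<path>.rows` and `<path>.cols`.
#' @return Numeric matrix with row and gene identifiers (whitespace
#'   stripped).
#' @seealso [writeExpression()], [readCoordinates()], [readAnnotations()]
#' @export
readExpression <- function(path, format = c("auto", "dense", "matrixmarket"),
                           rowFile = paste0(path, ".rows"),
                           colFile = paste0(path, ".cols")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE))
      "matrixmarket" else "dense"
  if (format == "matrixmarket") {
    if (!file.exists(rowFile))
      stop("missing row-label file: ", rowFile)
    if (!file.exists(colFile))
      stop("missing gene-label file: ", colFile)
    m <- as.matrix(Matrix::readMM(path))
    rows <- trimws(readLines(rowFile))
    cols <- trimws(readLines(colFile))
    if (length(rows) != nrow(m))
      stop(sprintf("row-label file has %d entries but the matrix has %d rows",
                   length(rows), nrow(m)))
    if (length(cols) != ncol(m))
      stop(sprintf("gene-label file has %d entries but the matrix has %d columns",
                   length(cols), ncol(m)))
    dimnames(m) <- list(rows, cols)
  } else {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    rows <- trimws(as.character(dt[[1L]]))
    m <- as.matrix(dt[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    dimnames(m) <- list(rows, trimws(colnames(dt)[-1L]))
  }
  msg <- .checkExprMatrix(m, sprintf("matrix read from '%s'", path))
  if (!isTRUE(msg)) stop(msg)
  m
}

#' Write an expression matrix to disk
#'
#' Inverse of [readExpression()]; round-trips are exact for integer
#' counts and accurate to at least 1e-12 (relative) for reals.
#'
#' @param mat numeric matrix with dimnames (or a [ReferenceData-class] /
#'   [SpatialData-class], whose expression matrix is written).
#' @param path output path.
#' @param format `"dense"` or `"matrixmarket"` (sidecar label files are
#'   written next to the matrix).
#' @return `path`, invisibly.
#' @export
writeExpression <- function(mat, path, format = c("dense", "matrixmarket")) {
  format <- match.arg(format)
  if (is(mat, "ReferenceData") || is(mat, "SpatialData")) mat <- exprValues(mat)
  if (format == "matrixmarket") {
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), path)
    writeLines(rownames(mat), paste0(path, ".rows"))
    writeLines(colnames(mat), paste0(path, ".cols"))
  } else {
    dt <- data.table::data.table(id = rownames(mat))
    dt <- cbind(dt, data.table::as.data.table(mat))
    data.table::fwrite(dt, path)
  }
  invisible(path)
}

#' Read a spot coordinate table
#'
#' Expects columns `spot_id, x, y` and optionally `z`. Units are taken
#' as-is; the pipeline only uses relative distances.
#'
#' @param path path to a delimited table with a header.
#' @return Numeric matrix of coordinates with spot identifiers as row
#'   names.
#' @export
readCoordinates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 3L)
    stop("coordinate table needs columns spot_id, x, y[, z]")
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- trimws(as.character(dt[[1L]]))
  if (!all(is.finite(m))) stop("coordinates must be finite")
  m
}

#' Read per-cell annotations
#'
#' Reads a delimited table whose first column holds cell identifiers and
#' second column the categorical annotation, or a headerless single
#' column of labels.
#'
#' @param path path to the table.
#' @return Named (when identifiers are present) character vector of
#'   labels.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(dt) >= 2L)
    setNames(trimws(as.character(dt[[2L]])), trimws(as.character(dt[[1L]])))
  else trimws(as.character(dt[[1L]]))
}

#' Write a transfer map to disk
#'
#' Writes a delimited table with one row per spot: spot identifier, one
#' column per (sub-)population, and a final `size` column holding the
#' column sums of `Y` (the estimated spot size).
#'
#' @param map a [TransferMap-class] (or plain populations-by-spots
#'   matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readTransferMap()]
#' @export
writeTransferMap <- function(map, path) {
  Y <- if (is(map, "TransferMap")) transferMatrix(map) else as.matrix(map)
  dt <- data.table::data.table(
    spot_id = if (is.null(colnames(Y))) character() else colnames(Y))
  dt <- cbind(dt, data.table::as.data.table(t(Y)))
  dt$size <- colSums(Y)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a transfer map written by [writeTransferMap()]
#'
#' @param path path to the table.
#' @param capacity per-spot capacity recorded with the map (defaults to
#'   the maximum observed size, so the object validates).
#' @return A [TransferMap-class].
#' @export
readTransferMap <- function(path, capacity = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  stopifnot(colnames(dt)[1L] == "spot_id",
            colnames(dt)[ncol(dt)] == "size")
  Y <- t(as.matrix(dt[, -c(1L, ncol(dt)), drop = FALSE]))
  colnames(Y) <- as.character(dt[[1L]])
  if (is.null(capacity)) capacity <- max(1, colSums(Y))
  TransferMap(Y, capacity = capacity)
}

#' Match gene identifiers between reference and spatial data
#'
#' Intersects gene identifiers by exact string match after whitespace
#' stripping (no case folding or alias resolution: silent mismatches are
#' worse than explicit errors). The shared set is returned in the spatial
#' data's gene order; the remaining spatial genes still inform the
#' spatial pair weights.
#'
#' @param ref a [ReferenceData-class], matrix, or character vector of
#'   reference gene identifiers.
#' @param spatial a [SpatialData-class], matrix, or character vector of
#'   spatial gene identifiers.
#' @return List with `shared` (genes present in both, spatial order) and
#'   `spatialOnly` (spatial genes absent from the reference).
#' @examples
#' alignGenes(c("a", "b", "c"), c("b", "c", "d"))
#' @export
alignGenes <- function(ref, spatial) {
  refGenes <- trimws(.geneIdsOf(ref))
  spatialGenes <- trimws(.geneIdsOf(spatial))
  if (!length(refGenes) || !length(spatialGenes))
    stop("both inputs must have at least one gene")
  shared <- spatialGenes[spatialGenes %in% refGenes]
  if (!length(shared))
    stop("no genes are shared between the reference and the spatial data; ",
         "harmonize the gene identifiers (same nomenclature and casing) ",
         "before fitting")
  list(shared = shared, spatialOnly = setdiff(spatialGenes, shared))
}

.geneIdsOf <- function(x) {
  if (is.character(x)) x
  else if (is(x, "ReferenceData") || is(x, "SpatialData"))
    colnames(exprValues(x))
  else colnames(x)
}
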