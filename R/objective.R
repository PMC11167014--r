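#' Scale-invariant cosine distance
#'
#' `sqrt(1 - cos(a, b))`. Unlike the plain cosine dissimilarity
#' `1 - cos`, this square-root form is a metric on rays of the positive
#' orthant (identity on positively collinear vectors, symmetry, triangle
#' inequality) and is quasi-convex for positive vectors. Scale invariance
#' makes it indifferent to the measurement sensitivity of the platform
#' and to spot/population sizes.
#'
#' Degenerate-input policy: an all-zero vector is at distance 1 from any
#' nonzero vector (with a warning) and at distance 0 from another
#' all-zero vector — bounded, continuous-in-limit behaviour instead of
#' NaN.
#'
#' @param a,b nonnegative numeric vectors of equal length.
#' @return A number in `[0, 1]`.
#' @examples
#' cosineDist(c(1, 2), c(3, 6))  # 0: collinear
#' cosineDist(c(1, 0), c(0, 1))  # 1: orthogonal
#' @export
cosineDist <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    if (na == 0 && nb == 0) return(0)
    warning("cosine distance of an all-zero vector; returning 1")
    return(1)
  }
  s <- sum(a * b) / (na * nb)
  sqrt(max(1 - s, 0))
}

#' Jensen-Shannon divergence (base 2)
#'
#' `0.5 * KL(p || m) + 0.5 * KL(q || m)` with `m = (p + q)/2`, base-2
#' logarithms and the convention `0 * log(0) = 0`. Applied directly to
#' the given nonnegative vectors: they are *not* normalised first (set
#' `normalize = TRUE` for the probability-vector behaviour). For
#' probability vectors the value lies in `[0, 1]`; for mass-`m` vectors
#' with disjoint support it equals `m` — the property behind the default
#' spatial penalty weight.
#'
#' @param p,q nonnegative numeric vectors of equal length, not both all
#'   zero.
#' @param normalize divide each vector by its sum first (default FALSE).
#' @return A nonnegative number.
#' @examples
#' jsDivergence(c(1, 0), c(0, 1))  # 1 bit
#' @export
jsDivergence <- function(p, q, normalize = FALSE) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0)) stop("negative entries are not allowed")
  if (sum(p) == 0 && sum(q) == 0) stop("both vectors are all-zero")
  if (normalize) { p <- p / sum(p); q <- q / sum(q) }
  0.5 * sum(.xlog2x(p) + .xlog2x(q) - .xlog2x(p + q)) + 0.5 * sum(p + q)
}

# x * log2(x) with 0 * log(0) = 0, branch-free (x == 0 shifts the log
# argument to 1, and the product with x = 0 is then exactly 0)
.xlog2x <- function(x) x * log2(x + (x == 0))

#' Objective weights container
#'
#' @param lambdaC,lambdaG,lambdaS,lambdaA nonnegative penalty weights of
#'   the population, gene, spatial, and abundance terms (the spot term
#'   carries unit weight).
#' @param theta sparsity parameter in `[0, 1]`: interpolates between the
#'   mixed-composition spot term (`theta = 0`) and a linear term whose
#'   corner solutions are pure, one-population spots (`theta = 1`).
#' @param nbar per-spot scaling of the linear sparsity term; fixed to the
#'   spot capacity by the pipeline.
#' @return Named list of validated weights.
#' @seealso [inferWeights()], [inferTheta()] for the data-driven values.
#' @export
objectiveWeights <- function(lambdaC = 0, lambdaG = 0, lambdaS = 0,
                             lambdaA = 0, theta = 0, nbar = 1) {
  stopifnot(lambdaC >= 0, lambdaG >= 0, lambdaS >= 0, lambdaA >= 0,
            theta >= 0, theta <= 1, all(nbar >= 1))
  list(lambdaC = lambdaC, lambdaG = lambdaG, lambdaS = lambdaS,
       lambdaA = lambdaA, theta = theta, nbar = nbar)
}

.profMat <- function(x) if (is(x, "ReferenceProfiles")) profileMatrix(x) else as.matrix(x)
.spatMat <- function(x) if (is(x, "SpatialData")) exprValues(x) else as.matrix(x)
.pairParts <- function(pairs, weights = NULL) {
  if (is.null(pairs)) return(list(i = integer(), j = integer(), w = numeric()))
  if (is(pairs, "SpatialPairSet"))
    return(list(i = pairMatrix(pairs)[, 1L], j = pairMatrix(pairs)[, 2L],
                w = pairWeights(pairs)))
  pairs <- as.matrix(pairs)
  if (is.null(weights)) weights <- rep(1, nrow(pairs))
  list(i = pairs[, 1L], j = pairs[, 2L], w = weights)
}

.colScale <- function(M, v) M * rep(v, each = nrow(M))

# distance matrix D[c, i] = cosineDist(XS[i, ], XR[c, ])
.pairwiseCosineDist <- function(XR, XS) {
  nr <- sqrt(rowSums(XR^2)); nx <- sqrt(rowSums(XS^2))
  S <- tcrossprod(XR, XS)                 # C x I inner products
  cosm <- S / outer(nr, nx)
  D <- sqrt(pmax(1 - cosm, 0))
  zr <- which(nr == 0); zx <- which(nx == 0)  # NA norms propagate as NaN
  if (length(zr) || length(zx)) {
    D[zr, ] <- 1
    D[, zx] <- 1
    D[zr, zx] <- 0
  }
  D
}

# cosine distances between the columns of A (targets) and B (models),
# with the degenerate policy; returns list(d, s, nA, nB) for reuse
.colCosine <- function(A, B) {
  nA <- sqrt(colSums(A^2)); nB <- sqrt(colSums(B^2))
  dots <- colSums(A * B)
  s <- dots / (nA * nB)
  d <- sqrt(pmax(1 - s, 0))
  degen <- (nA == 0 | nB == 0)
  degen[is.na(degen)] <- FALSE    # non-finite input propagates as NaN
  if (any(degen)) {
    d[degen] <- 1
    d[degen & nA == 0 & nB == 0] <- 0
    s[degen] <- NA_real_
  }
  list(d = d, s = s, nA = nA, nB = nB, degen = degen)
}

#' Spot expression matching term (with sparsity interpolation)
#'
#' Sum over spots of
#' `(1 - theta) * d_cos(x_i, sum_c Y[c,i] XR[c,]) +
#'  (theta / nbar_i) * sum_c Y[c,i] d_cos(x_i, XR[c,])`.
#' With `theta = 0` this is the pure mixed-composition spot term; the
#' linear `theta` branch promotes corner (one-population) solutions. For
#' binary columns (all mass on one population) the two branches coincide.
#'
#' @param Y (sub-)populations-by-spots matrix.
#' @param spatialExpr spots-by-genes matrix over the shared genes (or
#'   [SpatialData-class]).
#' @param profiles (sub-)populations-by-genes matrix over the shared
#'   genes (or [ReferenceProfiles-class]).
#' @param theta sparsity parameter in `[0, 1]`.
#' @param nbar per-spot scaling of the linear branch (scalar or one per
#'   spot).
#' @return The term value, a nonnegative number.
#' @export
termSpots <- function(Y, spatialExpr, profiles, theta = 0, nbar = 1) {
  XS <- .spatMat(spatialExpr); XR <- .profMat(profiles)
  M <- crossprod(XR, Y)                    # G x I transferred profiles
  cc <- .colCosine(t(XS), M)
  val <- (1 - theta) * sum(cc$d)
  if (theta > 0) {
    D <- .pairwiseCosineDist(XR, XS)
    val <- val + theta * sum(colSums(Y * D) / rep_len(nbar, ncol(Y)))
  }
  val
}

#' Population expression matching term
#'
#' Sum over (sub-)populations of the cosine distance between the
#' reference centroid and the expression the map assigns to that
#' population in space, `sum_i Y[c,i] XS[i,]`. Scale invariance absorbs
#' the population mass, so no normalisation is needed.
#'
#' @inheritParams termSpots
#' @return The term value.
#' @export
termPopulations <- function(Y, spatialExpr, profiles) {
  XS <- .spatMat(spatialExpr); XR <- .profMat(profiles)
  U <- Y %*% XS                            # C x G transferred centroids
  sum(.colCosine(t(XR), t(U))$d)
}

#' Gene expression map matching term
#'
#' Sum over shared genes of the cosine distance between the gene's
#' spatial expression map and the map transferred from the reference,
#' `sum_c Y[c,] XR[c,g]`.
#'
#' @inheritParams termSpots
#' @return The term value.
#' @export
termGenes <- function(Y, spatialExpr, profiles) {
  XS <- .spatMat(spatialExpr); XR <- .profMat(profiles)
  V <- crossprod(Y, XR)                    # I x G transferred maps
  sum(.colCosine(XS, V)$d)
}

#' Spatial smoothing term
#'
#' Weighted sum, over adjacent expression-similar spot pairs, of the
#' base-2 Jensen-Shannon divergence between the two spots' (raw,
#' unnormalised) composition columns. Convex in Y; bounded by
#' `n * |pairs|` when column sums are at most `n`.
#'
#' @param Y (sub-)populations-by-spots matrix.
#' @param pairs a [SpatialPairSet-class], or a 2-column index matrix.
#' @param weights pair weights when `pairs` is a plain matrix.
#' @return The term value.
#' @export
termSpatial <- function(Y, pairs, weights = NULL) {
  pp <- .pairParts(pairs, weights)
  if (!length(pp$i)) return(0)
  P <- Y[, pp$i, drop = FALSE]; Q <- Y[, pp$j, drop = FALSE]
  js <- 0.5 * colSums(.xlog2x(P) + .xlog2x(Q) - .xlog2x(P + Q)) +
        0.5 * colSums(P + Q)
  sum(pp$w * js)
}

#' Expected abundance matching term
#'
#' Aggregates the map to parent-population total masses
#' `rho_c = sum_i sum_{k in K_c} Y[k,i]` and returns the base-2
#' Jensen-Shannon divergence to the expected abundance vector `r`.
#' Defined at the population level because priors are typically known
#' for populations, not sub-clusters.
#'
#' @param Y (sub-)populations-by-spots matrix.
#' @param prior named nonnegative abundance vector over parent
#'   populations (scaled to the expected total cell count by the
#'   pipeline).
#' @param parent named character vector mapping rows of `Y` to parent
#'   populations (identity when omitted).
#' @return The term value.
#' @export
termAbundance <- function(Y, prior, parent = NULL) {
  if (all(prior == 0)) stop("the abundance prior is all-zero")
  if (is.null(parent)) parent <- setNames(rownames(Y), rownames(Y))
  rho <- .populationMass(Y, parent, names(prior))
  jsDivergence(rho, as.numeric(prior))
}

.populationMass <- function(Y, parent, popOrder) {
  mass <- rowSums(Y)
  grp <- parent[rownames(Y)]
  if (anyNA(grp)) stop("rows of Y without a parent population")
  rho <- rowsum(mass, grp)[, 1L]
  missing <- setdiff(popOrder, names(rho))
  if (length(missing)) rho[missing] <- 0
  rho[popOrder]
}

#' Combined transfer objective
#'
#' Evaluates the weighted multi-objective model: the spot term (unit
#' weight) plus `lambdaC`, `lambdaG`, `lambdaS`, `lambdaA` times the
#' population, gene, spatial, and abundance terms.
#'
#' @param Y (sub-)populations-by-spots matrix.
#' @param spatialExpr spots-by-genes matrix over the shared genes.
#' @param profiles (sub-)populations-by-genes matrix over the shared
#'   genes.
#' @param weights list from [objectiveWeights()].
#' @param pairs optional [SpatialPairSet-class].
#' @param prior optional named abundance vector (required when
#'   `lambdaA > 0`).
#' @param parent optional row-to-population map for sub-clustered fits.
#' @return Named list with the raw term values (`spots`, `populations`,
#'   `genes`, `spatial`, `abundance`) and the weighted `total`.
#' @export
transferObjective <- function(Y, spatialExpr, profiles, weights,
                              pairs = NULL, prior = NULL, parent = NULL) {
  br <- list(
    spots = termSpots(Y, spatialExpr, profiles, weights$theta, weights$nbar),
    populations = if (weights$lambdaC > 0)
      termPopulations(Y, spatialExpr, profiles) else 0,
    genes = if (weights$lambdaG > 0)
      termGenes(Y, spatialExpr, profiles) else 0,
    spatial = if (weights$lambdaS > 0) termSpatial(Y, pairs) else 0,
    abundance = if (weights$lambdaA > 0)
      termAbundance(Y, prior, parent) else 0)
  br$total <- br$spots + weights$lambdaC * br$populations +
    weights$lambdaG * br$genes + weights$lambdaS * br$spatial +
    weights$lambdaA * br$abundance
  br
}

#' Gradient of the combined transfer objective
#'
#' Analytic gradient with respect to `Y`, with two smoothing safeguards
#' that keep the Frank-Wolfe linearisation finite: the `1 - cos` factor
#' inside the derivative of the cosine metric is clamped at `epsCos`
#' (the metric's derivative is unbounded as cos approaches 1), and the
#' Jensen-Shannon log arguments are floored at `epsJs` (the log is
#' unbounded at zero coordinates). Both effects vanish as the epsilons
#' go to zero; the reported objective is never smoothed. At random
#' interior points the gradient matches central finite differences of
#' the exact objective to high relative accuracy.
#'
#' @inheritParams transferObjective
#' @param epsCos clamp for `1 - cos` inside the cosine derivative.
#' @param epsJs floor for Jensen-Shannon log arguments.
#' @return Matrix of the same shape as `Y`.
#' @export
transferGradient <- function(Y, spatialExpr, profiles, weights,
                             pairs = NULL, prior = NULL, parent = NULL,
                             epsCos = 1e-9, epsJs = 1e-12) {
  XS <- .spatMat(spatialExpr); XR <- .profMat(profiles)
  theta <- weights$theta
  nbar <- rep_len(weights$nbar, ncol(Y))
  G <- matrix(0, nrow(Y), ncol(Y), dimnames = dimnames(Y))

  # spot term: composite branch via the transferred profile M = XR' Y
  if (theta < 1) {
    M <- crossprod(XR, Y)
    cc <- .colCosine(t(XS), M)
    coef <- -0.5 / sqrt(pmax(1 - cc$s, epsCos))
    coef[cc$degen] <- 0
    a <- coef / (cc$nA * cc$nB); b <- coef * cc$s / cc$nB^2
    a[cc$degen] <- 0; b[cc$degen] <- 0
    Gm <- .colScale(t(XS), a) - .colScale(M, b)
    G <- G + (1 - theta) * (XR %*% Gm)
  }
  # spot term: linear sparsity branch (constant coefficients)
  if (theta > 0)
    G <- G + theta * .colScale(.pairwiseCosineDist(XR, XS), 1 / nbar)

  if (weights$lambdaC > 0) {
    U <- Y %*% XS
    cc <- .colCosine(t(XR), t(U))
    coef <- -0.5 / sqrt(pmax(1 - cc$s, epsCos))
    coef[cc$degen] <- 0
    a <- coef / (cc$nA * cc$nB); b <- coef * cc$s / cc$nB^2
    a[cc$degen] <- 0; b[cc$degen] <- 0
    Gu <- XR * a - U * b                   # row-scaled: a, b recycle by row
    G <- G + weights$lambdaC * (Gu %*% t(XS))
  }

  if (weights$lambdaG > 0) {
    V <- crossprod(Y, XR)
    cc <- .colCosine(XS, V)
    coef <- -0.5 / sqrt(pmax(1 - cc$s, epsCos))
    coef[cc$degen] <- 0
    a <- coef / (cc$nA * cc$nB); b <- coef * cc$s / cc$nB^2
    a[cc$degen] <- 0; b[cc$degen] <- 0
    Gv <- .colScale(XS, a) - .colScale(V, b)
    G <- G + weights$lambdaG * (XR %*% t(Gv))
  }

  if (weights$lambdaS > 0) {
    pp <- .pairParts(pairs)
    if (length(pp$i)) {
      P <- Y[, pp$i, drop = FALSE]; Q <- Y[, pp$j, drop = FALSE]
      S <- pmax(P + Q, epsJs)
      Gp <- .colScale(0.5 * log2(pmax(2 * P, epsJs) / S), pp$w)
      Gq <- .colScale(0.5 * log2(pmax(2 * Q, epsJs) / S), pp$w)
      G <- G + weights$lambdaS * (.accumulateColumns(Gp, pp$i, ncol(Y)) +
                                  .accumulateColumns(Gq, pp$j, ncol(Y)))
    }
  }

  if (weights$lambdaA > 0) {
    if (is.null(parent)) parent <- setNames(rownames(Y), rownames(Y))
    rho <- .populationMass(Y, parent, names(prior))
    g <- 0.5 * log2(pmax(2 * rho, epsJs) / pmax(rho + as.numeric(prior), epsJs))
    G <- G + weights$lambdaA * g[match(parent[rownames(Y)], names(prior))]
  }
  G
}

# add the columns of M (one per index) into an all-zero C x n matrix
.accumulateColumns <- function(M, idx, n) {
  acc <- matrix(0, nrow(M), n)
  tp <- rowsum(t(M), idx)
  acc[, as.integer(rownames(tp))] <- t(tp)
  acc
}
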