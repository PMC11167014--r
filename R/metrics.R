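#' Classification accuracy
#'
#' Proportion of spots whose predicted label equals the true label.
#'
#' @param pred,truth label vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
accuracyScore <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("prediction and truth have different lengths")
  mean(as.character(pred) == as.character(truth))
}

#' Brier score (mean squared error of membership probabilities)
#'
#' `|I|^-1 sum_i sum_c (Y[c,i] - P[c,i])^2`, a strictly proper scoring
#' rule: lower values mean better-calibrated probabilities.
#'
#' @param Yprob populations-by-spots matrix of predicted probabilities
#'   (columns sum to 1).
#' @param P populations-by-spots ground-truth matrix (one-hot columns
#'   for single-cell resolution, relative abundances for multicell).
#' @return A nonnegative number.
#' @export
brierScore <- function(Yprob, P) {
  if (!all(dim(Yprob) == dim(P))) stop("shape mismatch")
  sum((Yprob - P)^2) / ncol(P)
}

#' Gaussian-smoothed ground-truth compositions
#'
#' Replaces each spot's (one-hot) truth column with a kernel-weighted
#' average of its neighbourhood:
#' `Ptilde[c,i] = sum_j K[i,j] P[c,j] / sum_j K[i,j]` with
#' `K[i,j] = exp(-||x_i - x_j||^2 / (2 sigma^2))`. The self term
#' (`K[i,i] = 1`) is included, so columns remain probability vectors and
#' `Ptilde -> P` as `sigma -> 0`. The width defaults to half the
#' adjacency distance threshold in the calling code.
#'
#' @param P populations-by-spots truth matrix (columns sum to 1).
#' @param coords spot coordinate matrix.
#' @param sigma kernel width (> 0), same units as the coordinates.
#' @return Smoothed matrix of the same shape; columns sum to 1.
#' @export
smoothedTruth <- function(P, coords, sigma) {
  stopifnot(sigma > 0, ncol(P) == nrow(coords))
  K <- exp(-as.matrix(dist(coords))^2 / (2 * sigma^2))
  W <- K / rowSums(K)
  Pt <- P %*% t(W)
  dimnames(Pt) <- dimnames(P)
  Pt
}

#' Spatial Jensen-Shannon divergence
#'
#' Mean, over spots, of the base-2 Jensen-Shannon divergence between the
#' predicted membership probabilities and the Gaussian-smoothed truth.
#' In `[0, 1]` for probability columns; rewards predictions that respect
#' the local spatial composition even when the hard label is missed.
#'
#' @param Yprob populations-by-spots predicted probabilities.
#' @param Ptilde smoothed truth from [smoothedTruth()] (or any matrix of
#'   probability columns).
#' @return A number in `[0, 1]`.
#' @export
spatialJS <- function(Yprob, Ptilde) {
  mean(perSpotJS(Yprob, Ptilde))
}

#' Per-spot Jensen-Shannon divergence
#'
#' Base-2 Jensen-Shannon divergence between predicted and true
#' composition, one value per spot. Both inputs should be
#' column-normalised.
#'
#' @param Yrel populations-by-spots predicted relative abundances.
#' @param P populations-by-spots true relative abundances.
#' @return Numeric vector over spots, each in `[0, 1]`.
#' @export
perSpotJS <- function(Yrel, P) {
  if (!all(dim(Yrel) == dim(P))) stop("shape mismatch")
  0.5 * colSums(.xlog2x(Yrel) + .xlog2x(P) - .xlog2x(Yrel + P)) +
    0.5 * colSums(Yrel + P)
}
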