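#' Solver settings for the Frank-Wolfe loop
#'
#' @param maxIters maximum number of Frank-Wolfe iterations (default
#'   300; conditional-gradient convergence is sublinear, and spot-size
#'   estimates in particular keep improving well past the point where
#'   labels stabilise).
#' @param tol relative objective-change stopping tolerance (default
#'   1e-6; looser values stop before the column masses settle).
#' @param stepRule `"backtracking"` (Armijo line search on the step size,
#'   guaranteeing monotone descent) or `"diminishing"` (`2 / (t + 2)`).
#' @param armijo Armijo sufficient-decrease constant.
#' @param gapTol stop when the Frank-Wolfe duality gap falls below this.
#' @return Named list of validated settings.
#' @export
solverSettings <- function(maxIters = 300L, tol = 1e-6,
                           stepRule = c("backtracking", "diminishing"),
                           armijo = 1e-4, gapTol = 1e-8) {
  stopifnot(maxIters >= 1, tol >= 0)
  list(maxIters = as.integer(maxIters), tol = tol,
       stepRule = match.arg(stepRule), armijo = armijo, gapTol = gapTol)
}

#' Closed-form per-spot linear subproblem
#'
#' The Frank-Wolfe linearisation decomposes into one independent problem
#' per spot: minimise `<y, delta>` over `{y >= 0, 1 <= sum(y) <= n}`.
#' The solution is a one-hot column on the category with the smallest
#' coefficient (ties broken towards the smallest index), scaled to `n`
#' when that coefficient is negative and to 1 otherwise.
#'
#' @param delta gradient matrix ((sub-)populations by spots) or a single
#'   column vector.
#' @param capacity per-spot upper bound (scalar or one per spot).
#' @return Atom matrix of the same shape as `delta` (a matrix even for
#'   vector input).
#' @examples
#' solveSubproblem(c(-2, 1), 5)  # (5, 0)
#' solveSubproblem(c(3, 1), 5)   # (0, 1)
#' @export
solveSubproblem <- function(delta, capacity) {
  delta <- as.matrix(delta)
  stopifnot(all(is.finite(delta)), all(capacity >= 1))
  n <- rep_len(capacity, ncol(delta))
  chat <- max.col(-t(delta), ties.method = "first")
  best <- delta[cbind(chat, seq_len(ncol(delta)))]
  atom <- matrix(0, nrow(delta), ncol(delta), dimnames = dimnames(delta))
  atom[cbind(chat, seq_len(ncol(delta)))] <- ifelse(best < 0, n, 1)
  atom
}

#' One Frank-Wolfe step
#'
#' Convex combination `(1 - gamma) * Y + gamma * atom`. Feasibility
#' (nonnegativity, column sums within `[1, capacity]`) is preserved
#' because the feasible set is convex.
#'
#' @param Y current iterate.
#' @param atom atom matrix from [solveSubproblem()].
#' @param gamma step size in `[0, 1]`.
#' @return The next iterate.
#' @export
fwStep <- function(Y, atom, gamma) {
  stopifnot(gamma >= 0, gamma <= 1)
  (1 - gamma) * Y + gamma * atom
}

#' Fit the transfer model with Frank-Wolfe
#'
#' Iterates gradient evaluation, the closed-form per-spot subproblems,
#' and a line-searched convex-combination step, starting from uniform
#' columns (`Y[c,i] = 1/C`, column sum 1 — an unbiased interior point).
#' Stops when the relative objective change falls below `tol`, the
#' duality gap vanishes, or `maxIters` is reached. The gradient uses the
#' smoothed surrogates of [transferGradient()]; reported objective
#' values are unsmoothed. Deterministic given its inputs.
#'
#' @param spatialExpr spots-by-genes matrix over the shared genes (or
#'   [SpatialData-class], whose matrix must already be restricted).
#' @param profiles (sub-)populations-by-genes matrix over the shared
#'   genes (or [ReferenceProfiles-class]).
#' @param weights list from [objectiveWeights()] or [inferWeights()].
#' @param capacity per-spot capacity (scalar or one per spot).
#' @param pairs optional [SpatialPairSet-class] for the spatial term.
#' @param prior optional named abundance vector (with `lambdaA`).
#' @param parent optional row-to-population map.
#' @param settings list from [solverSettings()].
#' @return List with `map` (a [TransferMap-class] over the profile rows)
#'   and `trace` (data.frame: iteration, objective, gamma, gap).
#' @export
solveTransferModel <- function(spatialExpr, profiles, weights,
                               capacity = 1, pairs = NULL, prior = NULL,
                               parent = NULL,
                               settings = solverSettings()) {
  XS <- .spatMat(spatialExpr); XR <- .profMat(profiles)
  if (is(profiles, "ReferenceProfiles") && is.null(parent))
    parent <- parentMap(profiles)
  C <- nrow(XR); I <- nrow(XS)
  Y <- matrix(1 / C, C, I, dimnames = list(rownames(XR), rownames(XS)))
  br <- transferObjective(Y, XS, XR, weights, pairs, prior, parent)
  bad <- names(br)[!vapply(br, is.finite, logical(1L))]
  if (length(bad))
    stop("non-finite objective at the starting point in term(s): ",
         paste(setdiff(bad, "total"), collapse = ", "))
  env <- .makeObjectiveEnv(XS, XR, weights, pairs, prior, parent)
  fY <- br$total
  trace <- vector("list", settings$maxIters)
  t <- 0L
  while (t < settings$maxIters) {
    t <- t + 1L
    grad <- .coreGradient(Y, env)
    atom <- solveSubproblem(grad, capacity)
    dir <- atom - Y
    g0 <- sum(grad * dir)                  # <= 0; -g0 is the FW gap
    if (g0 >= -settings$gapTol) { t <- t - 1L; break }
    if (settings$stepRule == "diminishing") {
      gamma <- 2 / (t + 2)
      Ynew <- fwStep(Y, atom, gamma)
      fNew <- .coreObjective(Ynew, env)
    } else {
      # Armijo backtracking from gamma = 1. The smoothed gradient can
      # be much steeper than the objective near perfectly matched
      # profiles (the metric's derivative blows up as cos -> 1), which
      # inflates the Armijo bar; if no step clears it, fall back to the
      # largest step that still plainly decreases the objective,
      # keeping descent monotone.
      gamma <- 1
      gammaSd <- 0; fSd <- fY
      repeat {
        Ynew <- fwStep(Y, atom, gamma)
        fNew <- .coreObjective(Ynew, env)
        if (fNew <= fY + settings$armijo * gamma * g0) break
        if (gammaSd == 0 && fNew < fY) { gammaSd <- gamma; fSd <- fNew }
        gamma <- gamma / 2
        if (gamma < 1e-12) {
          gamma <- gammaSd
          Ynew <- if (gamma > 0) fwStep(Y, atom, gamma) else Y
          fNew <- fSd
          break
        }
      }
      if (gamma == 0) { t <- t - 1L; break }
    }
    trace[[t]] <- data.frame(iteration = t, objective = fNew,
                             gamma = gamma, gap = -g0)
    converged <- abs(fY - fNew) <= settings$tol * max(abs(fY), 1e-12)
    Y <- Ynew; fY <- fNew
    if (converged) break
  }
  trace <- if (t > 0L) do.call(rbind, trace[seq_len(t)]) else
    data.frame(iteration = integer(), objective = numeric(),
               gamma = numeric(), gap = numeric())
  list(map = TransferMap(Y, capacity = capacity, parent = parent),
       trace = trace)
}
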