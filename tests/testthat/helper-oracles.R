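# Independent oracle implementations: deliberately naive scalar loops,
# kept free of the package's vectorised code paths so they can serve as
# ground truth for equivalence tests.

oracleCos <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0) return(1)
  sqrt(max(0, 1 - sum(a * b) / (na * nb)))
}

oracleJS <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(x, y) {
    s <- 0
    for (k in seq_along(x)) if (x[k] > 0) s <- s + x[k] * log2(x[k] / y[k])
    s
  }
  as.numeric(0.5 * kl(p, m) + 0.5 * kl(q, m))
}

naiveTermSpots <- function(Y, XS, XR, theta, nbar) {
  nbar <- rep_len(nbar, ncol(Y))
  total <- 0
  for (i in seq_len(ncol(Y))) {
    mixed <- drop(Y[, i] %*% XR)
    lin <- 0
    for (cc in seq_len(nrow(Y)))
      lin <- lin + Y[cc, i] * oracleCos(XS[i, ], XR[cc, ])
    total <- total + (1 - theta) * oracleCos(XS[i, ], mixed) +
      theta * lin / nbar[i]
  }
  as.numeric(total)
}

naiveTermPopulations <- function(Y, XS, XR) {
  total <- 0
  for (cc in seq_len(nrow(Y)))
    total <- total + oracleCos(XR[cc, ], drop(Y[cc, ] %*% XS))
  total
}

naiveTermGenes <- function(Y, XS, XR) {
  total <- 0
  for (g in seq_len(ncol(XS)))
    total <- total + oracleCos(XS[, g], drop(t(Y) %*% XR[, g]))
  total
}

naiveTermSpatial <- function(Y, pairIdx, w) {
  total <- 0
  for (k in seq_len(nrow(pairIdx)))
    total <- total + w[k] * oracleJS(Y[, pairIdx[k, 1]], Y[, pairIdx[k, 2]])
  total
}

naiveTermAbundance <- function(Y, prior, parent) {
  rho <- setNames(numeric(length(prior)), names(prior))
  for (k in seq_len(nrow(Y)))
    rho[parent[rownames(Y)[k]]] <- rho[parent[rownames(Y)[k]]] + sum(Y[k, ])
  as.numeric(oracleJS(rho, prior))
}

# random feasible problem instance over the positive orthant
randomInstance <- function(C, I, G, seed, nmax = 4, numPairs = 0,
                           withPrior = FALSE) {
  set.seed(seed)
  XS <- matrix(runif(I * G, 0.1, 3), I, G,
               dimnames = list(paste0("s", seq_len(I)),
                               paste0("g", seq_len(G))))
  XR <- matrix(runif(C * G, 0.1, 3), C, G,
               dimnames = list(paste0("p", seq_len(C)),
                               paste0("g", seq_len(G))))
  Y <- matrix(runif(C * I, 0.05, 1), C, I,
              dimnames = list(rownames(XR), rownames(XS)))
  Y <- sweep(Y, 2, colSums(Y), "/") *
    runif(I, 1 + 0.1 * (nmax - 1), nmax - 0.1 * (nmax - 1))
  pairs <- NULL
  if (numPairs > 0) {
    idx <- t(replicate(numPairs, sort(sample.int(I, 2))))
    idx <- unique(idx)
    pairs <- new("SpatialPairSet", pairs = idx,
                 weights = runif(nrow(idx), 0.6, 1),
                 dBar = 1, wBar = 0.6)
  }
  prior <- if (withPrior)
    setNames(runif(C, 0.5, 2) * I * nmax / C, rownames(XR)) else NULL
  list(XS = XS, XR = XR, Y = Y, pairs = pairs, prior = prior, nmax = nmax)
}

# central finite differences of a scalar function of a matrix
fdGradient <- function(f, Y, h = 1e-6) {
  g <- Y * 0
  for (k in seq_along(Y)) {
    Yp <- Y; Ym <- Y
    Yp[k] <- Yp[k] + h; Ym[k] <- Ym[k] - h
    g[k] <- (f(Yp) - f(Ym)) / (2 * h)
  }
  g
}

# brute-force enumeration of adjacent, expression-similar pairs
bruteForcePairs <- function(coords, expr, dBar, wBar) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    ni <- sqrt(sum(expr[i, ]^2)); nj <- sqrt(sum(expr[j, ]^2))
    if (ni == 0 || nj == 0) next
    w <- sum(expr[i, ] * expr[j, ]) / (ni * nj)
    if (d <= dBar + 1e-12 && w >= wBar) out <- rbind(out, c(i, j, w))
  }
  out
}

# small labelled reference + matching spatial data where every spot's
# profile equals (a noisy draw around) its population's program
toySimSpec <- function(seed = 7, ...) {
  simulationSpec(numPopulations = 4, genesTotal = 40,
                 markersPerPopulation = 4, cellsPerPopulation = 40,
                 gridSide = 10, numSpots = 100, tileLength = 2.5,
                 seed = seed, ...)
}
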