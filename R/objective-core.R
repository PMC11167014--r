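# Internal fast path for the Frank-Wolfe loop: identical mathematics to
# the exported term functions (tests assert the equality), but with the
# quantities that do not change across iterations — transposes, row and
# column norms, the constant population-to-spot distance matrix, pair
# indices — computed once per solve.

.makeObjectiveEnv <- function(XS, XR, weights, pairs = NULL, prior = NULL,
                              parent = NULL, epsCos = 1e-9,
                              epsJs = 1e-12) {
  e <- new.env(parent = emptyenv())
  e$XS <- XS; e$XR <- XR; e$tXS <- t(XS)
  e$w <- weights
  e$nbar <- rep_len(weights$nbar, nrow(XS))
  e$nx <- sqrt(rowSums(XS^2))          # spot norms over shared genes
  e$nr <- sqrt(rowSums(XR^2))          # profile norms
  e$nsg <- sqrt(colSums(XS^2))         # gene-map norms
  if (weights$theta > 0) {
    e$D <- .pairwiseCosineDist(XR, XS)
    e$DoverN <- .colScale(e$D, 1 / e$nbar)
  }
  pp <- .pairParts(pairs)
  e$pi <- pp$i; e$pj <- pp$j; e$pw <- pp$w
  e$prior <- if (is.null(prior)) NULL else as.numeric(prior)
  if (!is.null(prior)) {
    if (is.null(parent)) parent <- setNames(rownames(XR), rownames(XR))
    e$parentIdx <- match(parent[rownames(XR)], names(prior))
    if (anyNA(e$parentIdx)) stop("rows of Y without a parent population")
  }
  e$epsCos <- epsCos; e$epsJs <- epsJs
  e
}

.coreCosine <- function(dots, nA, nB) {
  s <- dots / (nA * nB)
  d <- sqrt(pmax(1 - s, 0))
  degen <- (nA == 0 | nB == 0)
  degen[is.na(degen)] <- FALSE    # non-finite input propagates as NaN
  if (any(degen)) {
    d[degen] <- 1
    d[degen & nA == 0 & nB == 0] <- 0
  }
  list(d = d, s = s, degen = degen)
}

.coreObjective <- function(Y, e) {
  w <- e$w
  total <- 0
  if (w$theta < 1) {
    M <- crossprod(e$XR, Y)
    cc <- .coreCosine(colSums(e$tXS * M), e$nx, sqrt(colSums(M * M)))
    total <- total + (1 - w$theta) * sum(cc$d)
  }
  if (w$theta > 0) total <- total + w$theta * sum(Y * e$DoverN)
  if (w$lambdaC > 0) {
    U <- Y %*% e$XS
    cc <- .coreCosine(rowSums(U * e$XR), e$nr, sqrt(rowSums(U * U)))
    total <- total + w$lambdaC * sum(cc$d)
  }
  if (w$lambdaG > 0) {
    V <- crossprod(Y, e$XR)
    cc <- .coreCosine(colSums(e$XS * V), e$nsg, sqrt(colSums(V * V)))
    total <- total + w$lambdaG * sum(cc$d)
  }
  if (w$lambdaS > 0 && length(e$pi)) {
    P <- Y[, e$pi, drop = FALSE]; Q <- Y[, e$pj, drop = FALSE]
    js <- 0.5 * colSums(.xlog2x(P) + .xlog2x(Q) - .xlog2x(P + Q)) +
      0.5 * colSums(P + Q)
    total <- total + w$lambdaS * sum(e$pw * js)
  }
  if (w$lambdaA > 0) {
    rho <- .coreRho(Y, e)
    total <- total + w$lambdaA *
      (0.5 * sum(.xlog2x(rho) + .xlog2x(e$prior) - .xlog2x(rho + e$prior)) +
       0.5 * sum(rho + e$prior))
  }
  total
}

.coreGradient <- function(Y, e) {
  w <- e$w
  G <- matrix(0, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  if (w$theta < 1) {
    M <- crossprod(e$XR, Y)
    nm <- sqrt(colSums(M * M))
    cc <- .coreCosine(colSums(e$tXS * M), e$nx, nm)
    coef <- -0.5 / sqrt(pmax(1 - cc$s, e$epsCos))
    a <- coef / (e$nx * nm); b <- coef * cc$s / nm^2
    a[cc$degen] <- 0; b[cc$degen] <- 0
    a[!is.finite(a)] <- 0; b[!is.finite(b)] <- 0
    G <- G + (1 - w$theta) *
      (e$XR %*% (.colScale(e$tXS, a) - .colScale(M, b)))
  }
  if (w$theta > 0) G <- G + w$theta * e$DoverN
  if (w$lambdaC > 0) {
    U <- Y %*% e$XS
    nu <- sqrt(rowSums(U * U))
    cc <- .coreCosine(rowSums(U * e$XR), e$nr, nu)
    coef <- -0.5 / sqrt(pmax(1 - cc$s, e$epsCos))
    a <- coef / (e$nr * nu); b <- coef * cc$s / nu^2
    a[cc$degen] <- 0; b[cc$degen] <- 0
    a[!is.finite(a)] <- 0; b[!is.finite(b)] <- 0
    G <- G + w$lambdaC * ((e$XR * a - U * b) %*% e$tXS)
  }
  if (w$lambdaG > 0) {
    V <- crossprod(Y, e$XR)
    nv <- sqrt(colSums(V * V))
    cc <- .coreCosine(colSums(e$XS * V), e$nsg, nv)
    coef <- -0.5 / sqrt(pmax(1 - cc$s, e$epsCos))
    a <- coef / (e$nsg * nv); b <- coef * cc$s / nv^2
    a[cc$degen] <- 0; b[cc$degen] <- 0
    a[!is.finite(a)] <- 0; b[!is.finite(b)] <- 0
    G <- G + w$lambdaG *
      (e$XR %*% t(.colScale(e$XS, a) - .colScale(V, b)))
  }
  if (w$lambdaS > 0 && length(e$pi)) {
    P <- Y[, e$pi, drop = FALSE]; Q <- Y[, e$pj, drop = FALSE]
    S <- pmax(P + Q, e$epsJs)
    Gp <- .colScale(0.5 * log2(pmax(2 * P, e$epsJs) / S), e$pw)
    Gq <- .colScale(0.5 * log2(pmax(2 * Q, e$epsJs) / S), e$pw)
    G <- G + w$lambdaS * (.accumulateColumns(Gp, e$pi, ncol(Y)) +
                          .accumulateColumns(Gq, e$pj, ncol(Y)))
  }
  if (w$lambdaA > 0) {
    rho <- .coreRho(Y, e)
    g <- 0.5 * log2(pmax(2 * rho, e$epsJs) / pmax(rho + e$prior, e$epsJs))
    G <- G + w$lambdaA * g[e$parentIdx]
  }
  G
}

# population masses aligned to the prior's order (a population can have
# had all its sub-clusters filtered, hence the explicit zero fill)
.coreRho <- function(Y, e) {
  rho <- numeric(length(e$prior))
  tmp <- rowsum(rowSums(Y), e$parentIdx)
  rho[as.integer(rownames(tmp))] <- tmp[, 1L]
  rho
}
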