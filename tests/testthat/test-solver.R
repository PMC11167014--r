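test_that("per-spot subproblem follows the closed-form rule", {
  expect_equal(drop(solveSubproblem(c(-2, 1), 5)), c(5, 0))
  expect_equal(drop(solveSubproblem(c(3, 1), 5)), c(0, 1))
  # capacity 1: always a unit one-hot
  expect_equal(drop(solveSubproblem(c(-2, -5), 1)), c(0, 1))
  # ties break to the smallest index
  expect_equal(drop(solveSubproblem(c(0.5, 0.5), 3)), c(1, 0))
  expect_equal(drop(solveSubproblem(c(-1, -1), 3)), c(3, 0))
})

test_that("subproblem atoms beat every feasible-set vertex", {
  set.seed(50)
  for (k in 1:200) {
    C <- sample(2:12, 1)
    n <- runif(1, 1, 20)
    delta <- rnorm(C)
    atom <- drop(solveSubproblem(delta, n))
    got <- sum(atom * delta)
    # brute force over all 2C vertices {e_c, n e_c}
    best <- Inf
    for (cc in seq_len(C)) {
      best <- min(best, delta[cc], n * delta[cc])
    }
    expect_equal(got, best, tolerance = 1e-12)
    expect_true(sum(atom) %in% c(1, n))
  }
})

test_that("Frank-Wolfe steps preserve feasibility", {
  inst <- randomInstance(C = 5, I = 10, G = 6, seed = 51)
  atom <- solveSubproblem(matrix(rnorm(50), 5, 10,
                                 dimnames = dimnames(inst$Y)), inst$nmax)
  expect_equal(fwStep(inst$Y, atom, 0), inst$Y)
  expect_equal(fwStep(inst$Y, atom, 1), atom)
  for (gamma in c(0.25, 0.5, 0.9)) {
    Ynew <- fwStep(inst$Y, atom, gamma)
    cs <- colSums(Ynew)
    expect_true(all(Ynew >= 0))
    expect_true(all(cs >= 1 - 1e-12 & cs <= inst$nmax + 1e-12))
  }
})

test_that("pure linear case converges in one iteration to nearest centroid", {
  inst <- randomInstance(C = 6, I = 20, G = 10, seed = 52)
  w <- objectiveWeights(theta = 1, nbar = 1)
  sol <- solveTransferModel(inst$XS, inst$XR, w, capacity = 1)
  Y <- transferMatrix(sol$map)
  expect_equal(nrow(sol$trace), 1)
  expect_true(all(Y %in% c(0, 1)))
  expect_equal(unname(colSums(Y)), rep(1, 20))
  nearest <- apply(inst$XS, 1, function(x)
    which.min(apply(inst$XR, 1, function(r) oracleCos(x, r))))
  expect_identical(unname(hardLabels(sol$map)), rownames(inst$XR)[nearest])
})

test_that("iterates stay feasible and the objective descends", {
  for (seed in 1:8) {
    inst <- randomInstance(C = 5, I = 12, G = 8, seed = 60 + seed,
                           numPairs = 8, withPrior = (seed %% 2 == 0))
    w <- objectiveWeights(lambdaC = 0.5, lambdaG = 0.5, lambdaS = 0.5,
                          lambdaA = if (seed %% 2 == 0) 0.3 else 0,
                          theta = 0.4, nbar = inst$nmax)
    sol <- solveTransferModel(inst$XS, inst$XR, w, capacity = inst$nmax,
                              pairs = inst$pairs, prior = inst$prior,
                              settings = solverSettings(maxIters = 30))
    Y <- transferMatrix(sol$map)
    cs <- colSums(Y)
    expect_true(all(Y >= 0))
    expect_true(all(cs >= 1 - 1e-9 & cs <= inst$nmax + 1e-9))
    # backtracking guarantees a non-increasing trace
    expect_true(all(diff(sol$trace$objective) <= 1e-10))
    expect_true(all(sol$trace$gamma > 0 & sol$trace$gamma <= 1))
  }
})

test_that("a separable instance is recovered exactly", {
  # spots equal to distinct population centroids, single-cell resolution
  set.seed(70)
  C <- 8; G <- 20
  XR <- matrix(runif(C * G, 0.5, 2), C, G,
               dimnames = list(paste0("p", 1:C), paste0("g", 1:G)))
  XR[cbind(1:C, 1:C)] <- 30        # strong marker per population
  truth <- sample(1:C, 60, replace = TRUE)
  XS <- XR[truth, ] * runif(60, 0.5, 2)   # scaled copies of centroids
  rownames(XS) <- paste0("s", 1:60)
  w <- objectiveWeights(theta = 0.6, nbar = 1)
  sol <- solveTransferModel(XS, XR, w, capacity = 1)
  expect_identical(unname(hardLabels(sol$map)), rownames(XR)[truth])
})

test_that("determinism and error reporting", {
  inst <- randomInstance(C = 4, I = 8, G = 6, seed = 71, numPairs = 5)
  w <- objectiveWeights(lambdaC = 0.5, lambdaS = 0.5, theta = 0.4,
                        nbar = inst$nmax)
  s1 <- solveTransferModel(inst$XS, inst$XR, w, capacity = inst$nmax,
                           pairs = inst$pairs)
  s2 <- solveTransferModel(inst$XS, inst$XR, w, capacity = inst$nmax,
                           pairs = inst$pairs)
  expect_identical(transferMatrix(s1$map), transferMatrix(s2$map))
  # a non-finite starting objective names the offending term
  XSbad <- inst$XS; XSbad[1, 1] <- NaN
  expect_error(
    suppressWarnings(solveTransferModel(XSbad, inst$XR, w,
                                        capacity = inst$nmax)),
    "non-finite objective")
})
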