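test_that("cosine distance has the stated exact values and policies", {
  expect_equal(cosineDist(c(2, 1), c(2, 1)), 0, tolerance = 1e-7)
  expect_equal(cosineDist(c(1, 0), c(0, 1)), 1)
  expect_equal(cosineDist(c(1, 2), c(3, 6)), 0, tolerance = 1e-7)
  expect_warning(d <- cosineDist(c(0, 0), c(1, 1)), "all-zero")
  expect_equal(d, 1)
  expect_equal(cosineDist(c(0, 0), c(0, 0)), 0)
})

test_that("cosine distance is a metric on rays of the positive orthant", {
  set.seed(10)
  n <- 2000
  A <- matrix(runif(n * 6), n, 6)
  B <- matrix(runif(n * 6), n, 6)
  C <- matrix(runif(n * 6), n, 6)
  dAB <- dBC <- dAC <- numeric(n)
  for (k in seq_len(n)) {
    dAB[k] <- cosineDist(A[k, ], B[k, ])
    dBC[k] <- cosineDist(B[k, ], C[k, ])
    dAC[k] <- cosineDist(A[k, ], C[k, ])
    expect_equal(dAB[k], cosineDist(B[k, ], A[k, ]))     # symmetry
  }
  expect_true(all(dAC <= dAB + dBC + 1e-12))             # triangle
  expect_true(all(dAB >= 0 & dAB <= 1))
})

test_that("Jensen-Shannon divergence matches the direct-summation oracle", {
  expect_equal(jsDivergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsDivergence(c(1, 0), c(0, 1)), 1)        # 1 bit
  # mass-m disjoint supports give m
  expect_equal(jsDivergence(c(3, 0), c(0, 3)), 3)
  set.seed(11)
  for (k in 1:25) {
    p <- runif(8); q <- runif(8)
    expect_equal(jsDivergence(p, q), oracleJS(p, q), tolerance = 1e-12)
    expect_equal(jsDivergence(p, q), jsDivergence(q, p))
    # probability vectors stay within one bit
    expect_lte(jsDivergence(p / sum(p), q / sum(q)), 1)
  }
  expect_error(jsDivergence(c(-1, 1), c(1, 1)), "negative")
})

test_that("objective terms equal their naive-loop oracles", {
  for (seed in 1:5) {
    inst <- randomInstance(C = 6, I = 15, G = 10, seed = seed,
                           numPairs = 12, withPrior = TRUE)
    theta <- runif(1)
    expect_equal(termSpots(inst$Y, inst$XS, inst$XR, theta, inst$nmax),
                 naiveTermSpots(inst$Y, inst$XS, inst$XR, theta, inst$nmax),
                 tolerance = 1e-10)
    expect_equal(termPopulations(inst$Y, inst$XS, inst$XR),
                 naiveTermPopulations(inst$Y, inst$XS, inst$XR),
                 tolerance = 1e-10)
    expect_equal(termGenes(inst$Y, inst$XS, inst$XR),
                 naiveTermGenes(inst$Y, inst$XS, inst$XR),
                 tolerance = 1e-10)
    expect_equal(termSpatial(inst$Y, inst$pairs),
                 naiveTermSpatial(inst$Y, pairMatrix(inst$pairs),
                                  pairWeights(inst$pairs)),
                 tolerance = 1e-10)
    parent <- setNames(rownames(inst$Y), rownames(inst$Y))
    expect_equal(termAbundance(inst$Y, inst$prior, parent),
                 naiveTermAbundance(inst$Y, inst$prior, parent),
                 tolerance = 1e-10)
  }
})

test_that("term structure: reductions, invariances, bounds", {
  inst <- randomInstance(C = 5, I = 10, G = 8, seed = 42, numPairs = 8)
  # theta = 0 spot term is the pure composite form
  expect_equal(termSpots(inst$Y, inst$XS, inst$XR, theta = 0),
               naiveTermSpots(inst$Y, inst$XS, inst$XR, 0, 1))
  # binary columns: composite and linear branches coincide
  Yb <- matrix(0, 5, 10, dimnames = dimnames(inst$Y))
  Yb[cbind(sample(5, 10, TRUE), 1:10)] <- 3
  expect_equal(termSpots(Yb, inst$XS, inst$XR, theta = 0, nbar = 3),
               termSpots(Yb, inst$XS, inst$XR, theta = 1, nbar = 3),
               tolerance = 1e-10)
  # population term is invariant to rescaling a row of Y
  Y2 <- inst$Y; Y2[3, ] <- 7.3 * Y2[3, ]
  expect_equal(termPopulations(Y2, inst$XS, inst$XR),
               termPopulations(inst$Y, inst$XS, inst$XR), tolerance = 1e-12)
  # all terms invariant to joint positive rescaling of the expression
  w <- objectiveWeights(lambdaC = 1, lambdaG = 1, theta = 0.3, nbar = 4)
  o1 <- transferObjective(inst$Y, inst$XS, inst$XR, w)
  o2 <- transferObjective(inst$Y, 2.7 * inst$XS, 0.3 * inst$XR, w)
  expect_equal(o1$total, o2$total, tolerance = 1e-10)
  # spatial term: zero for identical columns, bounded by n |P|
  Yu <- matrix(1, 5, 10, dimnames = dimnames(inst$Y))
  expect_equal(termSpatial(Yu, inst$pairs), 0)
  n <- 4
  Yd <- matrix(0, 5, 10, dimnames = dimnames(inst$Y))
  Yd[1, seq(1, 10, 2)] <- n; Yd[2, seq(2, 10, 2)] <- n
  expect_lte(termSpatial(Yd, pairMatrix(inst$pairs),
                         rep(1, nrow(pairMatrix(inst$pairs)))),
             n * nrow(pairMatrix(inst$pairs)) + 1e-9)
  # single pair, disjoint unit columns, weight 1 -> exactly 1
  expect_equal(termSpatial(diag(2), matrix(c(1L, 2L), 1), 1), 1)
})

test_that("spatial term is midpoint-convex in Y", {
  inst <- randomInstance(C = 6, I = 12, G = 5, seed = 13, numPairs = 10)
  for (k in 1:10) {
    a <- randomInstance(6, 12, 5, seed = 100 + k)$Y
    b <- randomInstance(6, 12, 5, seed = 200 + k)$Y
    lhs <- termSpatial((a + b) / 2, inst$pairs)
    rhs <- (termSpatial(a, inst$pairs) + termSpatial(b, inst$pairs)) / 2
    expect_lte(lhs, rhs + 1e-10)
  }
})

test_that("abundance term aggregates sub-clusters before comparing", {
  inst <- randomInstance(C = 6, I = 8, G = 5, seed = 14)
  parent <- setNames(rep(c("A", "B", "C"), each = 2), rownames(inst$Y))
  prior <- c(A = 10, B = 20, C = 5)
  v1 <- termAbundance(inst$Y, prior, parent)
  # permute mass among sub-clusters of one population: value unchanged
  Y2 <- inst$Y
  Y2[1, ] <- inst$Y[2, ]; Y2[2, ] <- inst$Y[1, ]
  expect_equal(termAbundance(Y2, prior, parent), v1, tolerance = 1e-12)
  # exact prior match gives zero at the population level
  Yexact <- matrix(0, 3, 4, dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
  Yexact["A", ] <- c(4, 3, 2, 1); Yexact["B", ] <- 5; Yexact["C", ] <- 1.25
  expect_equal(termAbundance(Yexact, c(A = 10, B = 20, C = 5)), 0)
  expect_error(termAbundance(inst$Y, c(A = 0, B = 0, C = 0), parent),
               "all-zero")
})

test_that("the combined objective is linear in the penalty weights", {
  inst <- randomInstance(C = 5, I = 12, G = 9, seed = 15, numPairs = 9,
                         withPrior = TRUE)
  parent <- setNames(rownames(inst$Y), rownames(inst$Y))
  w <- objectiveWeights(lambdaC = 0.8, lambdaG = 0.5, lambdaS = 1.2,
                        lambdaA = 0.3, theta = 0.4, nbar = inst$nmax)
  half <- objectiveWeights(lambdaC = 0.4, lambdaG = 0.25, lambdaS = 0.6,
                           lambdaA = 0.15, theta = 0.4, nbar = inst$nmax)
  o <- transferObjective(inst$Y, inst$XS, inst$XR, w, inst$pairs,
                         inst$prior, parent)
  oh <- transferObjective(inst$Y, inst$XS, inst$XR, half, inst$pairs,
                          inst$prior, parent)
  expect_equal(o$total - o$spots, 2 * (oh$total - oh$spots),
               tolerance = 1e-12)
  # breakdown sums to the total
  expect_equal(o$total,
               o$spots + 0.8 * o$populations + 0.5 * o$genes +
                 1.2 * o$spatial + 0.3 * o$abundance)
  # all lambdas zero, theta 0: only the spot term remains
  w0 <- objectiveWeights(theta = 0)
  o0 <- transferObjective(inst$Y, inst$XS, inst$XR, w0)
  expect_equal(o0$total, o0$spots)
})

test_that("the solver's cached objective equals the exported objective", {
  inst <- randomInstance(C = 7, I = 14, G = 11, seed = 16, numPairs = 10,
                         withPrior = TRUE)
  parent <- setNames(rownames(inst$Y), rownames(inst$Y))
  w <- objectiveWeights(lambdaC = 0.7, lambdaG = 0.4, lambdaS = 0.9,
                        lambdaA = 0.2, theta = 0.35, nbar = inst$nmax)
  env <- SpotCast:::.makeObjectiveEnv(inst$XS, inst$XR, w, inst$pairs,
                                      inst$prior, parent)
  expect_equal(SpotCast:::.coreObjective(inst$Y, env),
               transferObjective(inst$Y, inst$XS, inst$XR, w, inst$pairs,
                                 inst$prior, parent)$total,
               tolerance = 1e-12)
  expect_equal(SpotCast:::.coreGradient(inst$Y, env),
               transferGradient(inst$Y, inst$XS, inst$XR, w, inst$pairs,
                                inst$prior, parent),
               tolerance = 1e-12)
})
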