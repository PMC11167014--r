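test_that("self-transfer recovers every label", {
  # spatial spots drawn as exact copies of distinct reference centroids
  spec <- toySimSpec(seed = 20)
  ref <- makeReference(spec)
  cent <- profileMatrix(computeCentroids(ref))
  truth <- rep(seq_len(nrow(cent)), length.out = 48)
  XS <- cent[truth, ]
  rownames(XS) <- paste0("s", seq_along(truth))
  spatial <- SpatialData(XS, cbind(seq_along(truth), 0))
  fit <- fitTransfer(ref, spatial, mode = "high", kappa = 1)
  expect_equal(accuracyScore(hardLabels(fit), rownames(cent)[truth]), 1)
})

test_that("fit output satisfies the transfer-map contract", {
  spec <- toySimSpec(seed = 21)
  ref <- makeReference(spec)
  hs <- makeHighresSpatial(spec)
  fit <- fitTransfer(ref, hs$spatial, mode = "high", kappa = 3)
  Y <- transferMatrix(populationMap(fit))
  expect_true(all(Y >= 0))
  expect_equal(unname(spotSizes(fit)), rep(1, ncol(Y)), tolerance = 1e-9)
  expect_true(validObject(populationMap(fit)))
  expect_true(validObject(subclusterMap(fit)))
  # collapsed rows are the populations; sub-cluster rows map onto them
  expect_setequal(rownames(Y), unique(parentMap(refProfiles(fit))))
  expect_equal(colSums(transferMatrix(subclusterMap(fit))),
               colSums(Y))
  cfg <- effectiveConfig(fit)
  expect_equal(cfg$capacity, 1)
  expect_equal(cfg$theta, 0.6)
  for (key in c("lambdaC", "lambdaG", "lambdaS", "dBar", "wBar",
                "numPairs", "seed"))
    expect_false(is.null(cfg[[key]]))
})

test_that("fits are reproducible and the empty prior equals lambdaA = 0", {
  spec <- toySimSpec(seed = 22)
  ref <- makeReference(spec)
  hs <- makeHighresSpatial(spec)
  f1 <- fitTransfer(ref, hs$spatial, mode = "high", kappa = 2, seed = 4)
  f2 <- fitTransfer(ref, hs$spatial, mode = "high", kappa = 2, seed = 4)
  expect_identical(transferMatrix(populationMap(f1)),
                   transferMatrix(populationMap(f2)))
  f3 <- fitTransfer(ref, hs$spatial, mode = "high", kappa = 2, seed = 4,
                    prior = NULL)
  expect_identical(transferMatrix(populationMap(f1)),
                   transferMatrix(populationMap(f3)))
  expect_equal(effectiveConfig(f3)$lambdaA, 0)
})

test_that("an abundance prior is scaled and steers the population masses", {
  spec <- toySimSpec(seed = 23)
  ref <- makeReference(spec)
  hs <- makeHighresSpatial(spec)
  prior <- setNames(rep(1, 4), paste0("pop", 1:4))
  fit <- fitTransfer(ref, hs$spatial, mode = "high", kappa = 1,
                     prior = prior)
  cfg <- effectiveConfig(fit)
  expect_equal(cfg$lambdaA, 1)        # 1/n with n = 1
  expect_equal(sum(cfg$prior), 1 * nrow(exprValues(hs$spatial)))
  expect_error(fitTransfer(ref, hs$spatial, mode = "high", kappa = 1,
                           prior = c(pop1 = 1)), "lacks populations")
})

test_that("relative abundances and hard labels behave as documented", {
  Y <- matrix(c(2, 2, 0.1, 0.9, 0.5, 0.5), 2, 3,
              dimnames = list(c("A", "B"), paste0("s", 1:3)))
  map <- TransferMap(Y, capacity = 4)
  rel <- relativeAbundance(map)
  expect_equal(rel[, "s1"], c(A = 0.5, B = 0.5))
  expect_equal(unname(colSums(rel)), rep(1, 3))
  expect_identical(rownames(rel), rownames(Y))
  lab <- hardLabels(map)
  expect_identical(unname(lab), c("A", "B", "A"))  # tie goes to row 1
  # one-hot columns are unchanged by normalisation
  oneHot <- TransferMap(matrix(c(1, 0, 0, 1), 2, 2,
    dimnames = list(c("A", "B"), c("s1", "s2"))), capacity = 1)
  expect_equal(relativeAbundance(oneHot), transferMatrix(oneHot))
})

test_that("feature transfer projects per-population values onto spots", {
  Y <- matrix(c(1, 0, 0, 1, 0.5, 0.5), 2, 3,
              dimnames = list(c("A", "B"), paste0("s", 1:3)))
  map <- TransferMap(Y, capacity = 1)
  feats <- matrix(c(10, 20, 3, 7), 2, 2,
                  dimnames = list(c("A", "B"), c("f1", "f2")))
  pred <- transferFeatures(map, feats)
  # one-hot columns copy the assigned population's value
  expect_equal(pred["s1", ], c(f1 = 10, f2 = 3))
  expect_equal(pred["s2", ], c(f1 = 20, f2 = 7))
  expect_equal(pred["s3", ], c(f1 = 15, f2 = 5))
  # a feature constant across populations gives a constant map
  const <- matrix(4, 2, 1, dimnames = list(c("A", "B"), "f"))
  expect_equal(unname(transferFeatures(map, const))[, 1], rep(4, 3))
  expect_error(transferFeatures(map, const[1, , drop = FALSE]),
               "must match")
  # raw (unnormalised) weighting scales with spot size
  mapBig <- TransferMap(Y * 3, capacity = 3)
  predRaw <- transferFeatures(mapBig, feats, normalize = FALSE)
  expect_equal(predRaw["s1", "f1"], 30)
})

test_that("low-resolution fits estimate sizes within the capacity bounds", {
  spec <- toySimSpec(seed = 24)
  ref <- makeReference(spec)
  hs <- makeHighresSpatial(spec)
  lr <- poolToLowres(hs$spatial, hs$truth, spec$tileLength)
  fit <- fitTransfer(ref, lr$spatial, mode = "low", capacity = 12,
                     kappa = 2)
  sz <- spotSizes(fit)
  expect_true(all(sz >= 1 - 1e-9 & sz <= 12 + 1e-9))
  expect_equal(effectiveConfig(fit)$theta, 0.4)
})
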