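test_that("generators are deterministic given the seed", {
  spec <- toySimSpec(seed = 5)
  expect_identical(exprValues(makeReference(spec)),
                   exprValues(makeReference(spec)))
  a <- makeHighresSpatial(spec); b <- makeHighresSpatial(spec)
  expect_identical(exprValues(a$spatial), exprValues(b$spatial))
  expect_identical(a$truth@labels, b$truth@labels)
  # a different seed changes the data
  expect_false(identical(exprValues(makeReference(toySimSpec(seed = 6))),
                         exprValues(makeReference(spec))))
})

test_that("reference populations are separable through their markers", {
  spec <- toySimSpec()
  ref <- makeReference(spec)
  cent <- profileMatrix(computeCentroids(ref))
  for (a in 1:(nrow(cent) - 1)) for (b in (a + 1):nrow(cent))
    expect_gt(oracleCos(cent[a, ], cent[b, ]), 0.3)
})

test_that("subtype structure is recovered by sub-clustering", {
  skip_if_not_installed("mclust")
  spec <- simulationSpec(numPopulations = 2, genesTotal = 60,
                         markersPerPopulation = 5, cellsPerPopulation = 120,
                         withinPopSubtypes = 2, subtypeFold = 12,
                         gridSide = 6, seed = 8)
  ref <- makeReference(spec)
  # regenerate the subtype assignment the generator used
  prog <- SpotCast:::.populationPrograms(spec)
  sub <- unlist(lapply(names(prog$programs), function(nm) {
    n <- ceiling(spec$cellsPerPopulation / 2)
    rep(prog$programs[[nm]]$subtype, n)
  }))
  prof <- subclusterReference(ref, kappa = 2, seed = 3)
  expect_equal(nrow(profileMatrix(prof)), 4)
  km <- kmeans(exprValues(ref)[cellLabels(ref) == "pop1", ], centers = 2,
               nstart = 10)
  ari <- mclust::adjustedRandIndex(km$cluster,
                                   sub[cellLabels(ref) == "pop1"])
  expect_gte(ari, 0.95)
})

test_that("region layout makes neighbouring labels agree more than chance", {
  spec <- toySimSpec(seed = 9)
  hs <- makeHighresSpatial(spec)
  coords <- spotCoords(hs$spatial)
  lab <- as.character(hs$truth@labels)
  dm <- as.matrix(dist(coords))
  diag(dm) <- Inf
  nn <- apply(dm, 1, which.min)
  nnAgree <- mean(lab == lab[nn])
  permAgree <- mean(replicate(20, mean(lab == sample(lab))))
  expect_gt(nnAgree, permAgree + 0.2)
})

test_that("pooling conserves expression and composition bookkeeping", {
  spec <- toySimSpec(seed = 10)
  hs <- makeHighresSpatial(spec)
  lr <- poolToLowres(hs$spatial, hs$truth, tileLength = 2.5)
  # total expression conserved per gene
  expect_equal(colSums(exprValues(lr$spatial)),
               colSums(exprValues(hs$spatial)))
  # composition counts sum to the member count per tile
  expect_equal(unname(colSums(lr$truth@composition)),
               unname(lengths(lr$truth@members)))
  expect_equal(lr$truth@cellCount, colSums(lr$truth@composition))
  # compositions are recoverable from the member lists and labels
  for (t in seq_along(lr$truth@members)) {
    ix <- lr$truth@members[[t]]
    expect_equal(unname(lr$truth@composition[, t]),
                 as.numeric(table(factor(hs$truth@labels[ix],
                                         levels = levels(hs$truth@labels)))))
  }
  # expression of each tile is the sum over its member cells
  t1 <- lr$truth@members[[1]]
  expect_equal(unname(exprValues(lr$spatial)[1, ]),
               unname(colSums(exprValues(hs$spatial)[t1, , drop = FALSE])))
  # tiny tiles reproduce the original rows
  tiny <- poolToLowres(hs$spatial, hs$truth, tileLength = 1e-6)
  expect_equal(nrow(exprValues(tiny$spatial)), nrow(exprValues(hs$spatial)))
  expect_equal(unname(exprValues(tiny$spatial)),
               unname(exprValues(hs$spatial)))
})

test_that("multiplicative noise respects its bounds and mean", {
  spec <- toySimSpec(seed = 11)
  hs <- makeHighresSpatial(spec)
  expect_identical(exprValues(addNoise(hs$spatial, 0)),
                   exprValues(hs$spatial))
  noisy <- addNoise(hs$spatial, 0.5, seed = 1)
  ratio <- exprValues(noisy) / exprValues(hs$spatial)
  ratio <- ratio[is.finite(ratio)]
  expect_true(all(ratio >= 0.5 - 1e-12 & ratio <= 1.5 + 1e-12))
  expect_equal(mean(ratio), 1, tolerance = 0.01)
  expect_error(addNoise(hs$spatial, 1.5), "negative")
})

test_that("gene subsetting keeps the first genes in order", {
  spec <- toySimSpec(seed = 12)
  hs <- makeHighresSpatial(spec)
  all <- subsetGenes(hs$spatial, ncol(exprValues(hs$spatial)))
  expect_identical(exprValues(all), exprValues(hs$spatial))
  one <- subsetGenes(hs$spatial, 1)
  expect_identical(colnames(exprValues(one)), "g1")
  ten <- subsetGenes(hs$spatial, 10)
  expect_identical(colnames(exprValues(ten)), paste0("g", 1:10))
  expect_error(subsetGenes(hs$spatial, 0), "between 1")
  expect_error(subsetGenes(hs$spatial, 10000), "between 1")
})
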