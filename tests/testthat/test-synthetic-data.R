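test_that("descriptor generation is a pure function of its spec", {
  spec <- linearPlantSpec(34, 50, c("A", "B"), c(A = 1, B = 2, "(Intercept)" = 0),
                          collinearityBlocks = list(list(size = 5, r = 0.9)),
                          seed = 7)
  t1 <- generateDescriptorMatrix(spec)
  t2 <- generateDescriptorMatrix(spec)
  expect_identical(descriptorMatrix(t1), descriptorMatrix(t2))
  expect_equal(dim(t1), c(34L, 50L))
  expect_true(all(c("A", "B") %in% descriptorNames(t1)))
})

test_that("collinearity blocks hit their target correlation", {
  spec <- linearPlantSpec(1000, 12, "A", c(A = 1, "(Intercept)" = 0),
                          collinearityBlocks = list(list(size = 5, r = 0.9)),
                          seed = 3)
  m <- descriptorMatrix(generateDescriptorMatrix(spec))
  block <- m[, 2:6]
  r <- cor(block)[upper.tri(diag(5))]
  expect_true(mean(r) > 0.8 && mean(r) < 1.0)
  # null correlation stays null
  spec0 <- linearPlantSpec(1000, 30, "A", c(A = 1, "(Intercept)" = 0), seed = 5)
  m0 <- descriptorMatrix(generateDescriptorMatrix(spec0))
  r0 <- cor(m0)
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.15)
  # infeasible equicorrelation is rejected
  bad <- linearPlantSpec(50, 10, "A", c(A = 1, "(Intercept)" = 0),
                         collinearityBlocks = list(list(size = 5, r = -0.5)),
                         seed = 1)
  expect_error(generateDescriptorMatrix(bad), "positive semi-definite")
})

test_that("noiseless plants are exactly recoverable downstream", {
  spec <- linearPlantSpec(60, 8, c("A", "B"), c(A = 2, B = -1, "(Intercept)" = 3),
                          noiseSd = 0, seed = 11)
  tb <- generateDescriptorMatrix(spec)
  act <- generateActivity(tb, spec)
  fit <- fitMlr(descriptorMatrix(tb)[, c("A", "B")], act$activity)
  expect_equal(fit@stats$r2, 1, tolerance = 1e-9)
  expect_equal(unname(fit@coefficients), c(2, -1), tolerance = 1e-9)
  # nonlinear plant: evaluator reproduces y exactly
  nl <- nonlinearPlantSpec(parseExpression("A + sin(B)"), noiseSd = 0, seed = 11)
  actNl <- generateActivity(tb, nl)
  m <- descriptorMatrix(tb)
  expect_equal(actNl$activity, m[, "A"] + sin(m[, "B"]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("noise calibrated to signal/noise variance 4 yields r2 near 4/5", {
  sd0 <- sqrt((2^2 + 1^2) / 4)  # signal variance over unit-variance columns
  spec <- linearPlantSpec(200, 6, c("A", "B"), c(A = 2, B = 1, "(Intercept)" = 0),
                          noiseSd = sd0, seed = 13)
  tb <- generateDescriptorMatrix(spec)
  act <- generateActivity(tb, spec)
  r2 <- summary(lm(act$activity ~ descriptorMatrix(tb)[, c("A", "B")]))$r.squared
  expect_gt(r2, 0.7)
  expect_lt(r2, 0.9)
})

test_that("undefined planted expressions flag the offending rows", {
  spec <- linearPlantSpec(10, 3, "A", c(A = 1, "(Intercept)" = 0), seed = 2)
  tb <- generateDescriptorMatrix(spec)
  nl <- nonlinearPlantSpec(parseExpression("inv(A - A)"), seed = 2)
  expect_warning(out <- generateActivity(tb, nl), "undefined")
  expect_length(out$flagged, 10)
})

test_that("the study-emulation preset reproduces the assay activity span", {
  p <- paperPresetLinear(seed = 4)
  expect_equal(range(p$noiseless), c(8.97, 9.74), tolerance = 1e-9)
  expect_identical(p$trueSubset, descriptorRegistry()$name)
  expect_equal(dim(p$table), c(34L, 500L))
  # noise sized for a true-model r2 near 0.67
  snr <- var(p$noiseless) / (var(p$noiseless) + p$spec@noiseSd^2)
  expect_equal(snr, 0.67, tolerance = 0.02)
})

test_that("molecule generation is deterministic and field-faithful", {
  spec <- fieldPlantSpec(nMolecules = 8, noiseSd = 0, seed = 21)
  g1 <- generateAlignedMolecules(spec)
  g2 <- generateAlignedMolecules(spec)
  expect_identical(g1$molecules[[3]]@atoms, g2$molecules[[3]]@atoms)
  expect_identical(g1$activity, g2$activity)
  # scaffold is shared and pre-aligned
  s1 <- as.matrix(g1$molecules[[1]]@atoms[1:3, c("x", "y", "z")])
  s2 <- as.matrix(g1$molecules[[5]]@atoms[1:3, c("x", "y", "z")])
  expect_identical(s1, s2)
  # identical molecules produce identical field rows
  mol <- g1$molecules[[1]]
  grid <- buildGrid(list(mol))
  expect_identical(computeField(mol, grid, "H"), computeField(mol, grid, "H"))
})

test_that("a noiseless field plant is exactly recovered by PLS", {
  g <- generateAlignedMolecules(fieldPlantSpec(nMolecules = 20, noiseSd = 0,
                                               seed = 31))
  fit <- fitPls(g$truth$fieldMatrix, g$activity, ncomp = 15)
  expect_gte(fit@r2, 0.999)
  expect_gt(cor(fit@coefficients, g$truth$weights), 0.99)
})
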