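test_that("fitMlr agrees with the normal-equations oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(10:30, 1); k <- sample(2:4, 1)
    X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", 1:k)))
    y <- rnorm(n)
    fit <- fitMlr(X, y)
    oracle <- olsOracle(X, y)
    expect_equal(unname(c(fit@intercept, fit@coefficients)), unname(oracle),
                 tolerance = 1e-8)
    expect_equal(fit@stats$r2_cv, looOracle(X, y), tolerance = 1e-8)
  }
})

test_that("fitMlr handles exact and degenerate responses", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- 1 + 2 * X[, 1] - X[, 2]
  fit <- fitMlr(X, y)
  expect_equal(fit@stats$r2, 1, tolerance = 1e-9)
  expect_lt(fit@stats$s2, 1e-9)
  fit0 <- fitMlr(X, rep(3, 20))
  expect_equal(fit0@stats$r2, 0)
  # a 4-point bivariate toy fit against hand normal equations
  X4 <- cbind(u = c(0, 1, 2, 3), v = c(1, 0, 1, 0))
  y4 <- c(0.5, 1.2, 2.1, 2.8)
  expect_equal(unname(coef(fitMlr(X4, y4))), unname(olsOracle(X4, y4)),
               tolerance = 1e-10)
  # rank deficiency is named
  Xr <- cbind(p = X[, 1], q = X[, 1])
  expect_error(fitMlr(Xr, y), "q")
})

test_that("the prefilter drops constants, duplicates and capped pairs", {
  set.seed(5)
  n <- 40
  base <- rnorm(n)
  y <- base + rnorm(n, 0, 0.3)
  twin <- 0.97 * base + sqrt(1 - 0.97^2) * rnorm(n)  # |r| ~ 0.95 with base
  m <- cbind(strong = base, weakTwin = twin, flat = rep(1, n),
             other = rnorm(n))
  tb <- descriptorTable(m, ids = paste0("c", 1:n))
  expect_message(out <- prefilterDescriptors(tb, y, collinearityCap = 0.8),
                 "dropped")
  expect_false("flat" %in% descriptorNames(out))
  # of the collinear pair, the one more correlated with y survives
  expect_true("strong" %in% descriptorNames(out))
  expect_false("weakTwin" %in% descriptorNames(out))
  expect_true("other" %in% descriptorNames(out))
  dropped <- attr(out, "dropped")
  expect_setequal(dropped$name, c("flat", "weakTwin"))
  # exact duplicate: exactly one survives
  m2 <- cbind(a = base, b = base, y0 = rnorm(n))
  out2 <- suppressMessages(
    prefilterDescriptors(descriptorTable(m2, ids = paste0("c", 1:n)), y))
  expect_equal(sum(c("a", "b") %in% descriptorNames(out2)), 1L)
  expect_error(prefilterDescriptors(
    descriptorTable(cbind(k = rep(2, n)), ids = paste0("c", 1:n)), y),
    "dropped")
})

test_that("forward selection recovers a planted pair and behaves greedily", {
  set.seed(42)
  spec <- linearPlantSpec(120, 10, c("A", "B"),
                          c(A = 3, B = 2, "(Intercept)" = 0),
                          noiseSd = 0.4, seed = 17)
  tb <- generateDescriptorMatrix(spec)
  y <- generateActivity(tb, spec)$activity
  tr <- heuristicSelect(tb, y, kMax = 5)
  expect_setequal(tr@subsets[[2]], c("A", "B"))
  # exhaustive pair search agrees
  m <- descriptorMatrix(tb)
  pairs <- combn(colnames(m), 2)
  r2s <- apply(pairs, 2, function(p) fitMlr(m[, p], y)@stats$r2)
  expect_setequal(pairs[, which.max(r2s)], tr@subsets[[2]])
  # r2 non-decreasing, subsets nested
  expect_true(all(diff(tr@steps$r2) >= -1e-12))
  for (k in 2:length(tr@subsets))
    expect_true(all(tr@subsets[[k - 1]] %in% tr@subsets[[k]]))
})

test_that("selection agrees with exhaustive best subsets at small p", {
  hits <- 0L
  for (s in 1:6) {
    spec <- linearPlantSpec(80, 8, c("A", "B"),
                            c(A = 2.5, B = 2, "(Intercept)" = 1),
                            noiseSd = 0.3, seed = 100 + s)
    tb <- generateDescriptorMatrix(spec)
    y <- generateActivity(tb, spec)$activity
    tr <- heuristicSelect(tb, y, kMax = 4)
    k <- tr@recommended
    m <- descriptorMatrix(tb)
    subsets <- combn(colnames(m), k, simplify = FALSE)
    r2s <- vapply(subsets, function(p) fitMlr(m[, p, drop = FALSE], y)@stats$r2, 0)
    if (setequal(subsets[[which.max(r2s)]], tr@subsets[[k]])) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("selected subsets respect the pairwise collinearity cap", {
  spec <- linearPlantSpec(60, 20, c("A", "B"),
                          c(A = 2, B = 1, "(Intercept)" = 0), noiseSd = 0.5,
                          collinearityBlocks = list(list(size = 6, r = 0.92)),
                          seed = 23)
  tb <- generateDescriptorMatrix(spec)
  y <- generateActivity(tb, spec)$activity
  tr <- heuristicSelect(tb, y, kMax = 6, collinearityCap = 0.8)
  sel <- tr@subsets[[length(tr@subsets)]]
  r <- cor(descriptorMatrix(tb)[, sel])
  expect_lt(max(abs(r[upper.tri(r)])), 0.8)
})

test_that("the published six-descriptor model is carried verbatim", {
  m <- referenceHmModel()
  expect_length(m@coefficients, 6)
  zero <- setNames(rep(0, 6), names(m@coefficients))
  expect_equal(evaluateLinear(m, zero), -24.280)
  expect_equal(m@coefficients[["MECN"]], 5.6298)
  ord <- names(sort(abs(m@coefficients), decreasing = TRUE))
  expect_identical(ord, c("MECN", "MCIHN", "ZXS", "TEIZP", "MRCH", "NFA"))
  ones <- setNames(rep(1, 6), names(m@coefficients))
  expect_equal(evaluateLinear(m, ones), -24.280 + sum(m@coefficients))
  # published diagnostics are metadata, not recomputed
  expect_false(m@stats$recomputed)
  expect_equal(m@stats$r2, 0.6682)
  expect_equal(m@stats$r2_cv, 0.5669)
  expect_equal(m@stats$s2, 0.0199)
})

test_that("linear evaluation is name-keyed", {
  m <- referenceHmModel()
  x <- setNames(c(1, 0.5, 0.2, -1, 2, 0.3), names(m@coefficients))
  v1 <- evaluateLinear(m, x)
  v2 <- evaluateLinear(m, x[sample(names(x))])
  expect_identical(v1, v2)
  expect_error(evaluateLinear(m, x[-2]), names(x)[2])
  expect_warning(evaluateLinear(m, c(x, extra = 1)), "extra")
  single <- new("LinearQsarModel", intercept = 1, coefficients = c(q = 3),
                stats = list(), provenance = "toy")
  expect_equal(evaluateLinear(single, c(q = 2)), 7)
})

test_that("model serialization round-trips exactly", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- fitMlr(X, rnorm(20))
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLinearModel(fit, tmp)
  back <- readLinearModel(tmp)
  expect_identical(back@intercept, fit@intercept)
  expect_identical(back@coefficients, fit@coefficients)
  expect_identical(back@stats$r2, fit@stats$r2)
  expect_identical(back@stats$t_values, fit@stats$t_values)
})
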