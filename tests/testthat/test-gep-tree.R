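test_that("tail length and chromosome validity follow the Karva rules", {
  fs <- defaultFunctionSet()
  expect_identical(tailLength(3, fs), 4L)
  ch <- chromosome(c("+", "*", "a", "a", "b", "a", "b"), 3, c("a", "b"), fs)
  expect_length(ch@genes[[1]], 7)
  # function symbol in the tail violates the invariant at construction
  expect_error(chromosome(c("+", "*", "a", "a", "+", "a", "b"), 3,
                          c("a", "b"), fs), "tail")
  expect_error(chromosome(c("+", "*", "a", "a", "b", "a"), 3, c("a", "b"), fs),
               "length")
})

test_that("breadth-first decoding fills tree levels left to right", {
  fs <- defaultFunctionSet()
  ch <- chromosome(c("+", "*", "a", "a", "b", "a", "b"), 3, c("a", "b"), fs)
  tree <- decodeChromosome(ch)
  expect_identical(deparseTree(tree), "((a * b) + a)")
  # the worked decoding example: gene +*aab -> (a*b)+a, value 8 at a=2,b=3
  ch2 <- chromosome(c("+", "*", "a", "a", "b", "b", "a"), 3, c("a", "b"), fs)
  expect_equal(evaluateTree(decodeChromosome(ch2), list(a = 2, b = 3)), 8)
  # root terminal: identity in a, unused tail ignored
  ch3 <- chromosome(c("a", "b", "b", "a", "b", "a", "a"), 3, c("a", "b"), fs)
  expect_identical(deparseTree(decodeChromosome(ch3)), "a")
  expect_equal(evaluateTree(decodeChromosome(ch3), list(a = 5, b = 0)), 5)
  # multigene chromosomes join through the linker
  ch4 <- chromosome(list(c("a", "a", "a", "a", "a", "a", "a"),
                         c("sin", "b", "b", "a", "b", "a", "a")),
                    3, c("a", "b"), fs)
  expect_identical(deparseTree(decodeChromosome(ch4)), "(a + sin(b))")
})

test_that("tree evaluation implements the UNDEFINED contract", {
  t1 <- parseExpression("a / b")
  expect_equal(evaluateTree(t1, list(a = 1, b = 4)), 0.25)
  expect_true(is.na(evaluateTree(t1, list(a = 1, b = 0))))
  expect_true(is.na(evaluateTree(parseExpression("1 + inv(x - x)"),
                                 list(x = 2))))
  expect_error(evaluateTree(t1, list(a = 1)), "unbound")
  # vectorized evaluation with row-wise NA propagation
  v <- evaluateTree(t1, data.frame(a = c(1, 2), b = c(2, 0)))
  expect_equal(v[1], 0.5)
  expect_true(is.na(v[2]))
})

test_that("the published nonlinear equation matches its independent oracle", {
  tree <- publishedGepModel()
  expect_setequal(treeTerminals(tree),
                  c("TEIZP", "NFA", "MECN", "MRCH", "MCIHN", "ZXS"))
  b0 <- list(TEIZP = 2, NFA = 1, MECN = 5, MRCH = 1, MCIHN = 0.5, ZXS = 1)
  expect_equal(evaluateTree(tree, b0), 2.9111314678025506, tolerance = 1e-9)
  # TEIZP == NFA divides by zero in the leading term
  expect_true(is.na(evaluateTree(tree, modifyList(b0, list(TEIZP = 1)))))
  # the printed (MECN - MECN) self-cancellation contributes exactly 0
  expect_identical(evaluateTree(tree, b0),
                   evaluateTree(tree, modifyList(b0, list(MECN = -123.5))))
  # dual-implementation cross-check on 100 random bindings
  text <- paste(readLines(system.file("extdata", "gep_published_equation.txt",
                                      package = "gbmQSAR")), collapse = " ")
  set.seed(7)
  for (i in 1:100) {
    b <- safeBindings()
    expect_equal(evaluateTree(tree, b), evalOracle(text, b),
                 tolerance = 1e-10)
  }
})

test_that("print and parse are mutually inverse on trees", {
  exprs <- c("a + sin(b)*c", "inv(x) - 2.5/(y + z)",
             "sin(sin(a)) * (b - -3)",
             "ZXS*1/(MRCH*sin(ZXS)/ZXS + ZXS/TEIZP)")
  for (e in exprs) {
    tr <- parseExpression(e)
    expect_identical(parseExpression(deparseTree(tr))@root, tr@root)
  }
  tr <- publishedGepModel()
  expect_identical(parseExpression(deparseTree(tr))@root, tr@root)
  expect_error(parseExpression("a + * b"), "parse error")
  expect_error(parseExpression("sin(a"), "expected")
  expect_error(parseExpression("a + b)"), "trailing")
})

test_that("fitness rewards exact recovery and punishes degeneracy", {
  set.seed(12)
  X <- data.frame(a = rnorm(50), b = rnorm(50))
  y <- X$a + sin(X$b)
  expect_equal(gepFitness(parseExpression("a + sin(b)"), X, y), 1)
  expect_equal(gepFitness(parseExpression("a / (a - a)"), X, y), 0)
  expect_equal(gepFitness(parseExpression("b - b"), X, y), 0)  # constant tree
  wrongSign <- gepFitness(parseExpression("a - sin(b)"), X, y)
  expect_lt(wrongSign, 1)
})
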