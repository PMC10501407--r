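test_that("evolution is deterministic per seed and elitist", {
  set.seed(1)
  X <- data.frame(a = rnorm(60), b = rnorm(60))
  y <- X$a * X$b
  cfg <- gepConfig(populationSize = 30, generations = 15, seed = 9,
                   fitnessTarget = 2)  # unreachable: run all generations
  r1 <- evolveGep(X, y, cfg)
  r2 <- evolveGep(X, y, cfg)
  expect_identical(r1@bestChromosome@genes, r2@bestChromosome@genes)
  expect_identical(r1@history, r2@history)
  expect_true(all(diff(r1@history) >= 0))  # best-so-far never degrades
})

test_that("a seeded exact solution terminates evolution at generation 0", {
  set.seed(2)
  X <- data.frame(a = rnorm(40), b = rnorm(40))
  y <- X$a + sin(X$b)
  fs <- defaultFunctionSet()
  h <- 8L; t <- tailLength(h, fs)
  sol <- chromosome(list(c("+", "a", "sin", "b", rep("a", h + t - 4L)),
                         c("-", "b", "b", rep("a", h + t - 3L)),
                         c("-", "a", "a", rep("b", h + t - 3L))),
                    h, c("a", "b"), fs)
  cfg <- gepConfig(populationSize = 20, generations = 50, seed = 3)
  res <- evolveGep(X, y, cfg, initial = list(sol))
  expect_length(res@history, 1)
  expect_equal(res@trainR2, 1)
})

test_that("genetic operators preserve chromosome validity", {
  fs <- defaultFunctionSet()
  terminals <- c("a", "b", "c")
  h <- 6L; t <- tailLength(h, fs)
  set.seed(31)
  for (rep in 1:40) {
    ch <- randomChromosome(h, nGenes = 3, terminals, fs)
    genes <- ch@genes
    genes <- gbmQSAR:::.mutateGenes(genes, h, t, fs, terminals, 0.3)
    genes <- gbmQSAR:::.isTranspose(genes, h)
    genes <- gbmQSAR:::.risTranspose(genes, h, fs)
    genes <- gbmQSAR:::.geneTranspose(genes)
    other <- randomChromosome(h, nGenes = 3, terminals, fs)@genes
    out <- gbmQSAR:::.onePoint(genes, other)
    genes <- lapply(out[[1]], unname)
    out <- gbmQSAR:::.twoPoint(genes, other)
    genes <- lapply(out[[1]], unname)
    out <- gbmQSAR:::.geneRecombine(genes, other)
    genes <- out[[1]]
    # reconstructing through the validity-checked constructor must succeed
    expect_s4_class(chromosome(genes, h, terminals, fs), "Chromosome")
  }
})

test_that("terminal-only populations degenerate to the best single terminal", {
  set.seed(8)
  X <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  y <- X$b + rnorm(50, 0, 0.05)
  fs <- defaultFunctionSet()
  h <- 2L; t <- tailLength(h, fs)
  mono <- lapply(c("a", "b", "c"), function(s)
    chromosome(list(rep(s, h + t)), h, c("a", "b", "c"), fs))
  cfg <- gepConfig(populationSize = 3, generations = 1, elitism = 1,
                   rates = c(mutation = 0, is_transposition = 0,
                             ris_transposition = 0, gene_transposition = 0,
                             one_point = 0, two_point = 0,
                             gene_recombination = 0),
                   nGenes = 1, headLength = h, seed = 4)
  res <- evolveGep(X, y, cfg, initial = mono)
  expect_identical(deparseTree(res@bestTree), "b")
  best <- max(sapply(c("a", "b", "c"), function(s)
    gepFitness(parseExpression(s), X, y)))
  expect_equal(res@trainR2, best)
})

test_that("held-out data is scored with the final tree", {
  set.seed(10)
  X <- data.frame(a = rnorm(80), b = rnorm(80))
  y <- X$a + sin(X$b)
  res <- evolveGep(X[1:60, ], y[1:60],
                   gepConfig(populationSize = 300, generations = 40, seed = 6,
                             fitnessTarget = 0.999),
                   Xtest = X[61:80, ], ytest = y[61:80])
  expect_gte(res@trainR2, 0.99)
  expect_gte(res@heldOutR2, 0.9)
})
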