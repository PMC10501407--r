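# Gene expression programming over fixed-length Karva strings.
#
# Internally a population is a plain list of chromosomes, each a list of
# character vectors (genes); the S4 Chromosome wrapper is used at the API
# boundary. All evolution randomness is drawn inside withSeed(config@seed),
# so a run is a pure function of (X, y, config).

#' Construct a Karva chromosome
#'
#' The tail length is fixed by the head length and the maximum operator
#' arity: t = h*(amax - 1) + 1, which guarantees every decoding terminates
#' inside the gene.
#'
#' @param genes list of character vectors (one per gene) of symbols, each of
#'   length h + t with terminals only in the tail.
#' @param headLength head length h.
#' @param terminals terminal (descriptor) names.
#' @param functionSet a \linkS4class{FunctionSet}.
#' @param linker linking operator for multigenic chromosomes, default "+".
#' @return a \linkS4class{Chromosome}.
#' @export
chromosome <- function(genes, headLength, terminals,
                       functionSet = defaultFunctionSet(), linker = "+") {
  h <- as.integer(headLength)
  t <- h * (max(functionSet@arity) - 1L) + 1L
  if (is.character(genes)) genes <- list(genes)
  new("Chromosome", genes = genes, headLength = h, tailLength = t,
      terminals = as.character(terminals), functionSet = functionSet,
      linker = linker)
}

#' @rdname chromosome
#' @param headLength head length h.
#' @param functionSet a FunctionSet.
#' @return \code{tailLength}: the tail length t = h*(amax - 1) + 1.
#' @export
tailLength <- function(headLength, functionSet = defaultFunctionSet())
  as.integer(headLength) * (max(functionSet@arity) - 1L) + 1L

# random gene as character vector; head from functions+terminals, tail terminal
.randomGene <- function(h, t, fs, terminals) {
  headPool <- c(fs@symbols, terminals)
  headW <- c(fs@weight, rep(1, length(terminals)))
  head <- sample(headPool, h, replace = TRUE, prob = headW)
  tail <- sample(terminals, t, replace = TRUE)
  c(head, tail)
}

#' Random chromosome
#' @param headLength,nGenes,terminals,functionSet,linker chromosome shape.
#' @return a \linkS4class{Chromosome} (uses the current RNG stream).
#' @export
randomChromosome <- function(headLength, nGenes = 1L, terminals,
                             functionSet = defaultFunctionSet(), linker = "+") {
  h <- as.integer(headLength)
  t <- tailLength(h, functionSet)
  genes <- replicate(nGenes, .randomGene(h, t, functionSet, terminals),
                     simplify = FALSE)
  chromosome(genes, h, terminals, functionSet, linker)
}

# ---- Karva (breadth-first) decoding -----------------------------------------

# Child indices for one gene: returns list(children = list per position,
# used = number of positions consumed).
.karvaChildren <- function(gene, fs) {
  arities <- fs@arity[match(gene, fs@symbols)]
  arities[is.na(arities)] <- 0L
  children <- vector("list", length(gene))
  queue <- 1L; nxt <- 2L; used <- 1L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    a <- arities[i]
    if (a > 0L) {
      kids <- nxt:(nxt + a - 1L)
      children[[i]] <- kids
      queue <- c(queue, kids)
      nxt <- nxt + a
      used <- max(used, max(kids))
    }
  }
  list(children = children, used = used)
}

.geneToNode <- function(gene, fs) {
  kc <- .karvaChildren(gene, fs)
  build <- function(i) {
    s <- gene[i]
    if (s %in% fs@symbols)
      do.call(opNode, c(list(s), lapply(kc$children[[i]], build)))
    else terminalNode(s)
  }
  build(1L)
}

#' Decode a chromosome into its expression tree
#'
#' Breadth-first (Karva) decoding: symbols fill tree levels left to right,
#' each function symbol consuming as many following positions as its arity;
#' unused tail symbols are ignored. Multigene chromosomes are joined by the
#' linking operator (left fold).
#'
#' @param c a \linkS4class{Chromosome}.
#' @return an \linkS4class{ExpressionTree}.
#' @examples
#' fs <- defaultFunctionSet()
#' ch <- chromosome(c("+", "*", "a", "a", "b", "a", "b"), 3, c("a", "b"), fs)
#' deparseTree(decodeChromosome(ch))  # (a * a) + b  pattern depends on gene
#' @export
decodeChromosome <- function(c) {
  stopifnot(is(c, "Chromosome"))
  validObject(c)
  nodes <- lapply(c@genes, .geneToNode, fs = c@functionSet)
  root <- Reduce(function(a, b) opNode(c@linker, a, b), nodes)
  new("ExpressionTree", root = root)
}

# fast path used inside evolve: evaluate a raw gene list directly on the
# column bindings without building nested node lists
.evalGenes <- function(genes, fs, linker, cols, n) {
  total <- NULL
  for (gene in genes) {
    kc <- .karvaChildren(gene, fs)
    used <- kc$used
    vals <- vector("list", used)
    for (i in used:1) {
      s <- gene[i]
      if (s %in% fs@symbols)
        vals[[i]] <- .applyOp(s, vals[kc$children[[i]]])
      else vals[[i]] <- cols[[s]]
    }
    total <- if (is.null(total)) vals[[1L]]
             else .applyOp(linker, list(total, vals[[1L]]))
  }
  total
}

#' GEP fitness: coefficient of determination of tree predictions
#'
#' Fitness is 1 - RSS/TSS of the tree's predictions against the observed
#' activities, clamped below at 0; any UNDEFINED prediction (division
#' blow-up) or a degenerate constant prediction scores 0, the worst value.
#'
#' @param tree ExpressionTree (or raw node list).
#' @param X matrix/data.frame whose columns are the terminals.
#' @param y observed activities.
#' @return fitness in [0, 1].
#' @export
gepFitness <- function(tree, X, y) {
  preds <- evaluateTree(tree, X)
  .fitnessFromPreds(preds, y)
}

.fitnessFromPreds <- function(preds, y) {
  if (length(preds) == 1L) preds <- rep(preds, length(y))
  if (anyNA(preds) || any(!is.finite(preds))) return(0)
  if (stats::sd(preds) == 0) return(0)
  max(0, rSquared(y, preds))
}

# ---- genetic operators (plain gene lists) -----------------------------------

.mutateGenes <- function(genes, h, t, fs, terminals, rate) {
  headPool <- c(fs@symbols, terminals)
  lapply(genes, function(g) {
    hit <- which(runif(h + t) < rate)
    for (i in hit)
      g[i] <- if (i <= h) sample(headPool, 1L) else sample(terminals, 1L)
    g
  })
}

# insertion-sequence transposition: copy a short fragment to a non-root head
# position, shifting the head right (tail untouched)
.isTranspose <- function(genes, h) {
  if (h < 2L) return(genes)
  gi <- sample.int(length(genes), 1L)
  g <- genes[[gi]]
  len <- sample.int(min(3L, h), 1L)
  start <- sample.int(length(g) - len + 1L, 1L)
  frag <- g[start:(start + len - 1L)]
  target <- sample(2:h, 1L)
  keep <- min(len, h - target + 1L)
  newHead <- append(g[seq_len(h)], frag, after = target - 1L)[seq_len(h)]
  genes[[gi]] <- c(newHead, g[(h + 1L):length(g)])
  genes
}

# root-insertion transposition: fragment starting at a function symbol in the
# head is copied to the gene root
.risTranspose <- function(genes, h, fs) {
  gi <- sample.int(length(genes), 1L)
  g <- genes[[gi]]
  funPos <- which(g[seq_len(h)] %in% fs@symbols)
  if (!length(funPos)) return(genes)
  start <- if (length(funPos) == 1L) funPos else sample(funPos, 1L)
  len <- sample.int(min(3L, h - start + 1L), 1L)
  frag <- g[start:(start + len - 1L)]
  newHead <- c(frag, g[seq_len(h)])[seq_len(h)]
  genes[[gi]] <- c(newHead, g[(h + 1L):length(g)])
  genes
}

.geneTranspose <- function(genes) {
  if (length(genes) < 2L) return(genes)
  gi <- sample(2:length(genes), 1L)
  c(genes[gi], genes[-gi])
}

.onePoint <- function(a, b) {
  fa <- unlist(a); fb <- unlist(b)
  pt <- sample.int(length(fa) - 1L, 1L)
  ga <- c(fa[1:pt], fb[(pt + 1L):length(fb)])
  gb <- c(fb[1:pt], fa[(pt + 1L):length(fa)])
  glen <- length(a[[1L]])
  list(split(ga, ceiling(seq_along(ga) / glen)),
       split(gb, ceiling(seq_along(gb) / glen)))
}

.twoPoint <- function(a, b) {
  fa <- unlist(a); fb <- unlist(b)
  pts <- sort(sample.int(length(fa) - 1L, 2L))
  mid <- (pts[1L] + 1L):pts[2L]
  ga <- fa; ga[mid] <- fb[mid]
  gb <- fb; gb[mid] <- fa[mid]
  glen <- length(a[[1L]])
  list(split(ga, ceiling(seq_along(ga) / glen)),
       split(gb, ceiling(seq_along(gb) / glen)))
}

.geneRecombine <- function(a, b) {
  gi <- sample.int(length(a), 1L)
  tmp <- a[[gi]]; a[[gi]] <- b[[gi]]; b[[gi]] <- tmp
  list(a, b)
}

# strip split() names so genes stay plain character vectors
.unsplit <- function(genes) lapply(genes, unname)

#' Default GEP configuration
#'
#' Standard GEP practice where the study is silent: mutation 0.044,
#' IS/RIS/gene transposition 0.1 each, one-/two-point recombination 0.3
#' each, gene recombination 0.1; population 50, head length 8, 3 genes
#' linked by "+"; fitness target 1 and a 100-generation cap.
#'
#' @param populationSize,generations,fitnessTarget,elitism,headLength,nGenes,linker,seed scalars.
#' @param rates named numeric overriding any of the default operator rates.
#' @param functionSet a FunctionSet.
#' @return a \linkS4class{GepConfig}.
#' @export
gepConfig <- function(populationSize = 50L, generations = 100L,
                      fitnessTarget = 1, elitism = 1L, rates = numeric(),
                      headLength = 8L, nGenes = 3L, linker = "+",
                      functionSet = defaultFunctionSet(), seed = 1L) {
  r <- c(mutation = 0.044, is_transposition = 0.1, ris_transposition = 0.1,
         gene_transposition = 0.1, one_point = 0.3, two_point = 0.3,
         gene_recombination = 0.1)
  r[names(rates)] <- rates
  new("GepConfig", populationSize = as.integer(populationSize),
      generations = as.integer(generations), fitnessTarget = fitnessTarget,
      elitism = as.integer(elitism), rates = r,
      headLength = as.integer(headLength), nGenes = as.integer(nGenes),
      linker = linker, functionSet = functionSet, seed = as.integer(seed))
}

#' Evolve a GEP population against activity data
#'
#' Runs the standard GEP loop: evaluate fitness, stop on the fitness target
#' or the generation cap, select by elite roulette (fitness-proportional
#' selection with the elite individuals copied unconditionally), then apply
#' mutation, IS/RIS/gene transposition and one-point/two-point/gene
#' recombination at the configured rates. Deterministic per
#' \code{config@seed}.
#'
#' @param X matrix/data.frame of descriptor columns (the terminal set).
#' @param y activity vector.
#' @param config a \linkS4class{GepConfig}.
#' @param Xtest,ytest optional held-out data scored once at the end.
#' @param initial optional list of \linkS4class{Chromosome} objects seeded
#'   into the initial population.
#' @return a \linkS4class{GepResult}.
#' @export
evolveGep <- function(X, y, config = gepConfig(), Xtest = NULL, ytest = NULL,
                      initial = NULL) {
  X <- as.data.frame(X)
  terminals <- colnames(X)
  fs <- config@functionSet
  h <- config@headLength
  t <- tailLength(h, fs)
  cols <- as.list(X)
  n <- length(y)
  withSeed(config@seed, {
    pop <- replicate(config@populationSize,
                     replicate(config@nGenes, .randomGene(h, t, fs, terminals),
                               simplify = FALSE),
                     simplify = FALSE)
    if (!is.null(initial))
      for (i in seq_along(initial)) pop[[i]] <- initial[[i]]@genes
    history <- numeric()
    bestGenes <- NULL; bestFit <- -Inf
    for (gen in seq_len(config@generations)) {
      fit <- vapply(pop, function(genes)
        .fitnessFromPreds(.evalGenes(genes, fs, config@linker, cols, n), y), 0)
      genBest <- which.max(fit)
      if (fit[genBest] > bestFit) { bestFit <- fit[genBest]
                                    bestGenes <- pop[[genBest]] }
      history <- c(history, bestFit)
      if (bestFit >= config@fitnessTarget) break
      # elite roulette selection
      ord <- order(fit, decreasing = TRUE)
      elite <- pop[ord[seq_len(config@elitism)]]
      prob <- if (sum(fit) > 0) fit / sum(fit)
              else rep(1 / length(fit), length(fit))
      picked <- sample.int(length(pop), length(pop) - config@elitism,
                           replace = TRUE, prob = prob)
      nextPop <- pop[picked]
      # operators
      nextPop <- lapply(nextPop, .mutateGenes, h = h, t = t, fs = fs,
                        terminals = terminals, rate = config@rates[["mutation"]])
      nextPop <- lapply(nextPop, function(g)
        if (runif(1) < config@rates[["is_transposition"]]) .isTranspose(g, h) else g)
      nextPop <- lapply(nextPop, function(g)
        if (runif(1) < config@rates[["ris_transposition"]]) .risTranspose(g, h, fs) else g)
      nextPop <- lapply(nextPop, function(g)
        if (runif(1) < config@rates[["gene_transposition"]]) .geneTranspose(g) else g)
      # pairwise recombination
      if (length(nextPop) >= 2L) {
        nPair <- floor(length(nextPop) / 2)
        pairIdx <- matrix(sample.int(length(nextPop), 2L * nPair),
                          ncol = 2L, nrow = nPair)
        for (rowi in seq_len(nrow(pairIdx))) {
          i1 <- pairIdx[rowi, 1L]; i2 <- pairIdx[rowi, 2L]
          if (runif(1) < config@rates[["one_point"]]) {
            out <- .onePoint(nextPop[[i1]], nextPop[[i2]])
            nextPop[[i1]] <- .unsplit(out[[1L]]); nextPop[[i2]] <- .unsplit(out[[2L]])
          }
          if (runif(1) < config@rates[["two_point"]]) {
            out <- .twoPoint(nextPop[[i1]], nextPop[[i2]])
            nextPop[[i1]] <- .unsplit(out[[1L]]); nextPop[[i2]] <- .unsplit(out[[2L]])
          }
          if (length(nextPop[[i1]]) > 1L &&
              runif(1) < config@rates[["gene_recombination"]]) {
            out <- .geneRecombine(nextPop[[i1]], nextPop[[i2]])
            nextPop[[i1]] <- out[[1L]]; nextPop[[i2]] <- out[[2L]]
          }
        }
      }
      pop <- c(elite, nextPop)
    }
    bestChrom <- chromosome(bestGenes, h, terminals, fs, config@linker)
    bestTree <- decodeChromosome(bestChrom)
    heldOut <- if (!is.null(Xtest))
      .fitnessFromPreds(evaluateTree(bestTree, as.data.frame(Xtest)), ytest)
      else NA_real_
    new("GepResult", bestTree = bestTree, bestChromosome = bestChrom,
        history = history, trainR2 = bestFit, heldOutR2 = heldOut)
  })
}
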