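# Synthetic-data generators: planted linear, nonlinear and 3D-field
# structure-activity relationships with known ground truth. Every generator
# is a pure function of its spec (seed included).

#' Construct a LinearPlantSpec
#'
#' @param nCompounds,nDescriptors dimensions of the descriptor table.
#' @param trueSubset names of the causal descriptors; they occupy the first
#'   columns of the generated table.
#' @param trueCoefficients named numeric over \code{trueSubset} plus
#'   \code{"(Intercept)"}.
#' @param noiseSd Gaussian noise standard deviation on the activity.
#' @param collinearityBlocks list of \code{list(size =, r =)} equicorrelated
#'   blocks, placed on the columns immediately after the true subset.
#' @param seed integer seed.
#' @return a \linkS4class{LinearPlantSpec}.
#' @export
linearPlantSpec <- function(nCompounds, nDescriptors, trueSubset,
                            trueCoefficients, noiseSd = 0,
                            collinearityBlocks = list(), seed = 1L) {
  new("LinearPlantSpec", nCompounds = as.integer(nCompounds),
      nDescriptors = as.integer(nDescriptors),
      trueSubset = as.character(trueSubset),
      trueCoefficients = trueCoefficients, noiseSd = noiseSd,
      collinearityBlocks = collinearityBlocks, seed = as.integer(seed))
}

#' @rdname linearPlantSpec
#' @param expression an \linkS4class{ExpressionTree} over descriptor names.
#' @export
nonlinearPlantSpec <- function(expression, noiseSd = 0, seed = 1L) {
  new("NonlinearPlantSpec", expression = expression, noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' @rdname linearPlantSpec
#' @param nMolecules number of molecules.
#' @param atomsPerMolecule integer range c(min, max) of decoration atoms.
#' @param propertyRanges list with numeric(2) entries \code{charge} and
#'   \code{hydrophobicity}.
#' @param nPlantedWeights sparse support size of the planted coefficient
#'   vector.
#' @export
fieldPlantSpec <- function(nMolecules, atomsPerMolecule = c(4L, 10L),
                           propertyRanges = list(charge = c(-0.5, 0.5),
                                                 hydrophobicity = c(-0.6, 0.6)),
                           nPlantedWeights = 12L, noiseSd = 0, seed = 1L) {
  new("FieldPlantSpec", nMolecules = as.integer(nMolecules),
      atomsPerMolecule = as.integer(atomsPerMolecule),
      propertyRanges = propertyRanges,
      nPlantedWeights = as.integer(nPlantedWeights), noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' Generate a descriptor matrix with block collinearity
#'
#' Descriptor marginals are standard normal; collinearity is induced per
#' equicorrelated block through the Cholesky factor of the block correlation
#' matrix. The causal descriptors named in \code{trueSubset} occupy the
#' first columns and are mutually independent; collinearity blocks follow;
#' remaining columns are independent fill named \code{D<k>}.
#'
#' @param spec a \linkS4class{LinearPlantSpec}.
#' @return a \linkS4class{DescriptorTable} (rows \code{c1..cn}).
#' @export
generateDescriptorMatrix <- function(spec) {
  n <- spec@nCompounds; p <- spec@nDescriptors
  s <- length(spec@trueSubset)
  if (n < 4L) stopf("need at least 4 compounds")
  if (p < s) stopf("nDescriptors must be >= |trueSubset|")
  blockSizes <- vapply(spec@collinearityBlocks, function(b) as.integer(b$size), 0L)
  if (s + sum(blockSizes) > p)
    stopf("true subset plus collinearity blocks exceed nDescriptors")
  for (b in spec@collinearityBlocks) {
    if (b$size > 1L && (b$r > 1 || b$r < -1 / (b$size - 1)))
      stopf("block correlation r = %g with size %d is not positive semi-definite",
            b$r, b$size)
  }
  withSeed(spec@seed, {
    Z <- matrix(rnorm(n * p), n, p)
    pos <- s
    for (b in spec@collinearityBlocks) {
      sz <- as.integer(b$size)
      Sigma <- matrix(b$r, sz, sz); diag(Sigma) <- 1
      U <- chol(Sigma)
      idx <- (pos + 1L):(pos + sz)
      Z[, idx] <- Z[, idx, drop = FALSE] %*% U
      pos <- pos + sz
    }
    nm <- character(p)
    if (s) nm[seq_len(s)] <- spec@trueSubset
    if (p > s) nm[(s + 1L):p] <- paste0("D", (s + 1L):p)
    colnames(Z) <- nm
    rownames(Z) <- paste0("c", seq_len(n))
    new("DescriptorTable", values = Z)
  })
}

#' Generate activities from a planted relationship
#'
#' Evaluates the planted linear combination or expression tree on the
#' descriptor table and adds Gaussian noise (drawn from a seed offset so the
#' noise stream is independent of the matrix stream). Rows where a planted
#' expression is undefined (division blow-up) are flagged, reported with a
#' warning and receive \code{NA}.
#'
#' @param table a \linkS4class{DescriptorTable}.
#' @param plant a \linkS4class{LinearPlantSpec} or
#'   \linkS4class{NonlinearPlantSpec}.
#' @return list with elements \code{activity}, \code{noiseless} and
#'   \code{flagged} (row indices).
#' @export
generateActivity <- function(table, plant) {
  m <- descriptorMatrix(table)
  if (is(plant, "LinearPlantSpec")) {
    miss <- setdiff(plant@trueSubset, colnames(m))
    if (length(miss)) stopf("plant references missing descriptor(s): %s",
                            paste(miss, collapse = ", "))
    beta <- plant@trueCoefficients[plant@trueSubset]
    y0 <- drop(m[, plant@trueSubset, drop = FALSE] %*% beta) +
      plant@trueCoefficients[["(Intercept)"]]
  } else if (is(plant, "NonlinearPlantSpec")) {
    miss <- setdiff(treeTerminals(plant@expression), colnames(m))
    if (length(miss)) stopf("plant references missing descriptor(s): %s",
                            paste(miss, collapse = ", "))
    y0 <- evaluateTree(plant@expression, as.data.frame(m))
    if (length(y0) == 1L) y0 <- rep(y0, nrow(m))
  } else stopf("unsupported plant spec of class %s", class(plant))
  flagged <- which(!is.finite(y0))
  if (length(flagged))
    warnf("planted relationship undefined at row(s): %s",
          paste(flagged, collapse = ", "))
  noise <- withSeed(plant@seed + 1000003L,
                    rnorm(nrow(m), 0, plant@noiseSd))
  list(activity = y0 + noise, noiseless = y0, flagged = flagged)
}

#' Generate pseudo-aligned molecules with a planted field-activity model
#'
#' All molecules share a fixed three-atom scaffold (already in a common
#' frame) plus decoration atoms drawn at a set of substitution sites common
#' to the whole series (each molecule occupies a random subset of sites with
#' small positional jitter and randomized field properties), emulating a
#' congeneric series stacked on a template.
#' The five CoMSIA fields are assembled on the default grid; a planted
#' coefficient vector is built from a sparse draw over active columns,
#' projected onto the row space of the centered field matrix (the component
#' a field/PLS model can identify), and the noiseless activity
#' field-matrix %*% weights is rescaled to span the assay activity range
#' 8.97-9.74 before Gaussian noise is added.
#'
#' @param spec a \linkS4class{FieldPlantSpec}.
#' @param spacing,margin,alpha,minSigma field settings, defaults as in
#'   \code{\link{assembleFieldMatrix}}.
#' @return list with elements \code{molecules}, \code{activity} and
#'   \code{truth} (grid, fieldMatrix, weights over active columns,
#'   noiseless activity).
#' @export
generateAlignedMolecules <- function(spec, spacing = 2, margin = 4,
                                     alpha = 0.3, minSigma = 0.05) {
  lo <- spec@atomsPerMolecule[1L]; hi <- spec@atomsPerMolecule[2L]
  if (lo < 1L) stopf("atomsPerMolecule must be >= 1")
  scaffold <- list(element = c("N", "C", "C"),
                   xyz = rbind(c(0, 0, 0), c(1.4, 0, 0), c(0.7, 1.2, 0)))
  withSeed(spec@seed, {
    # fixed substitution sites shared by the whole series (congeneric
    # analogs vary at common positions around the stacked scaffold)
    sites <- matrix(runif(3L * hi, -3, 3), hi, 3L)
    sites <- sweep(sites, 2L, c(-0.7, -0.4, 0), FUN = "+")
    mols <- lapply(seq_len(spec@nMolecules), function(i) {
      k <- if (hi > lo) sample(lo:hi, 1L) else lo
      occ <- sort(sample.int(hi, k))
      el <- sample(c("C", "N", "O", "F"), k, replace = TRUE,
                   prob = c(0.55, 0.2, 0.15, 0.1))
      xyz <- sites[occ, , drop = FALSE] + matrix(rnorm(3L * k, 0, 0.35), k, 3L)
      chg <- runif(k, spec@propertyRanges$charge[1L],
                   spec@propertyRanges$charge[2L])
      hyd <- runif(k, spec@propertyRanges$hydrophobicity[1L],
                   spec@propertyRanges$hydrophobicity[2L])
      don <- runif(k) < 0.2
      acc <- runif(k) < 0.3
      alignedMolecule(
        id = sprintf("syn%03d", i),
        element = c(scaffold$element, el),
        xyz = rbind(scaffold$xyz, xyz),
        charge = c(0.1, 0, 0, chg),
        hydrophobicity = c(-0.5, 0.5, 0.5, hyd),
        donor = c(TRUE, FALSE, FALSE, don),
        acceptor = c(TRUE, FALSE, FALSE, acc),
        scaffoldMap = 1:3)
    })
    grid <- buildGrid(mols, spacing = spacing, margin = margin)
    fm <- assembleFieldMatrix(mols, grid, alpha = alpha, minSigma = minSigma)
    Fa <- fm@values[, fm@active, drop = FALSE]
    Fc <- sweep(Fa, 2L, colMeans(Fa))
    # planted PLS-style coefficient vector: a random combination of the top
    # singular directions of the centered field matrix (the coefficient
    # space a low-component PLS model spans), weighted by singular value so
    # high-variance field structure dominates
    sv <- svd(Fc)
    k <- min(spec@nPlantedWeights, sum(sv$d > sv$d[1L] * 1e-8))
    cw <- rnorm(k) * (sv$d[seq_len(k)] / sv$d[1L])
    w <- drop(sv$v[, seq_len(k), drop = FALSE] %*% cw)
    signal <- drop(Fc %*% w)
    span <- diff(range(signal))
    if (span < 1e-12) stopf("planted signal is degenerate; enlarge the spec")
    b <- (9.74 - 8.97) / span
    y0 <- 8.97 + (signal - min(signal)) * b
    w <- w * b
    noise <- rnorm(spec@nMolecules, 0, spec@noiseSd)
    list(molecules = mols, activity = y0 + noise,
         truth = list(grid = grid, fieldMatrix = fm, weights = w,
                      noiseless = y0))
  })
}

#' Study-condition emulation preset for the 2D branch
#'
#' Mirrors the published study's regime: 34 compounds, 500 candidate
#' descriptors, a six-descriptor causal subset named after the published
#' descriptors with coefficient magnitudes proportional to the published
#' ones, block collinearity among 100 of the nuisance descriptors (ten
#' equicorrelated blocks of ten at r = 0.9), noiseless activities rescaled
#' to the assay activity span 8.97-9.74 and Gaussian noise sized so the
#' true-model r2 is about 0.67.
#'
#' @param seed integer seed.
#' @return list with \code{table} (DescriptorTable), \code{spec} (the
#'   concrete LinearPlantSpec, scaled coefficients and noise included),
#'   \code{activity}, \code{noiseless} and \code{trueSubset}.
#' @export
paperPresetLinear <- function(seed = 1L) {
  reg <- descriptorRegistry()
  beta0 <- stats::setNames(reg$coefficient, reg$name)
  blocks <- rep(list(list(size = 10L, r = 0.9)), 10L)
  draft <- linearPlantSpec(
    nCompounds = 34L, nDescriptors = 500L, trueSubset = reg$name,
    trueCoefficients = c(beta0, "(Intercept)" = 0), noiseSd = 0,
    collinearityBlocks = blocks, seed = seed)
  table <- generateDescriptorMatrix(draft)
  y0 <- generateActivity(table, draft)$noiseless
  b <- (9.74 - 8.97) / diff(range(y0))
  a <- 8.97 - b * min(y0)
  beta <- b * beta0
  sdSig <- stats::sd(y0 * b)
  noiseSd <- sdSig * sqrt((1 - 0.67) / 0.67)
  spec <- linearPlantSpec(
    nCompounds = 34L, nDescriptors = 500L, trueSubset = reg$name,
    trueCoefficients = c(beta, "(Intercept)" = a), noiseSd = noiseSd,
    collinearityBlocks = blocks, seed = seed)
  act <- generateActivity(table, spec)
  list(table = table, spec = spec, activity = act$activity,
       noiseless = act$noiseless, trueSubset = reg$name)
}
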