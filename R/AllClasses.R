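#' @import methods
#' @importFrom stats coef cor lm.fit pf predict pt quantile rnorm runif sd var
#' @importFrom jsonlite write_json
#' @importFrom tools md5sum
NULL

.COMPOUND_ROLES <- c("train", "test", "validation", "unassigned")
.FIELD_LABELS <- c("S", "E", "H", "D", "A")

#' Compound activity set
#'
#' An ordered collection of assayed compounds. Each record carries a short
#' id (e.g. \code{"21E"}), an optional SMILES string, the measured IC50 in
#' micromolar, the transformed activity pAct = 9 - log10(IC50/uM) and a split
#' role (\code{train}, \code{test}, \code{validation} or \code{unassigned}).
#'
#' @slot data data.frame with columns \code{id}, \code{smiles}, \code{ic50},
#'   \code{activity}, \code{role}.
#' @slot provenance free-text source tag.
#' @slot transform activity transform in force: "pAct" (9 - log10 IC50,
#'   default) or "literal" (log10 IC50 + 9, audit mode).
#' @exportClass CompoundSet
setClass("CompoundSet",
  representation(data = "data.frame", provenance = "character",
                 transform = "character"),
  prototype(transform = "pAct"))

setValidity("CompoundSet", function(object) {
  d <- object@data
  if (length(object@transform) != 1L ||
      !object@transform %in% c("pAct", "literal"))
    return("transform must be 'pAct' or 'literal'")
  need <- c("id", "smiles", "ic50", "activity", "role")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$id)) return("compound ids must be unique")
  if (any(!nzchar(d$id))) return("compound ids must be non-empty")
  if (any(!is.na(d$ic50) & d$ic50 <= 0))
    return(paste("non-positive IC50 for compound(s):",
                 paste(d$id[!is.na(d$ic50) & d$ic50 <= 0], collapse = ", ")))
  if (!all(d$role %in% .COMPOUND_ROLES))
    return("role must be one of train/test/validation/unassigned")
  both <- !is.na(d$ic50) & !is.na(d$activity)
  expected <- if (object@transform == "pAct") function(x) 9 - log10(x)
              else function(x) log10(x) + 9
  if (any(both) && max(abs(d$activity[both] - expected(d$ic50[both]))) > 1e-9)
    return("activity inconsistent with the declared transform of ic50")
  TRUE
})

#' Named numeric descriptor matrix over a compound set
#'
#' @slot values numeric matrix, rows = compounds (rownames are compound ids),
#'   columns = named descriptors.
#' @exportClass DescriptorTable
setClass("DescriptorTable", representation(values = "matrix"))

setValidity("DescriptorTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("descriptor values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("descriptor matrix needs compound-id rownames and descriptor colnames")
  if (anyDuplicated(rownames(v))) return("duplicate compound ids")
  if (anyDuplicated(colnames(v))) return("duplicate descriptor names")
  TRUE
})

#' Multilinear QSAR model
#'
#' Intercept plus named descriptor coefficients, with fit diagnostics:
#' r-squared, leave-one-out cross-validated r-squared, residual variance
#' s2 = RSS/(n - k - 1), raw RSS, overall F and per-coefficient t values.
#'
#' @slot intercept numeric(1).
#' @slot coefficients named numeric vector of descriptor coefficients.
#' @slot stats list with elements r2, r2_cv, s2, rss, f_value, t_values, n.
#' @slot provenance character tag.
#' @exportClass LinearQsarModel
setClass("LinearQsarModel",
  representation(intercept = "numeric", coefficients = "numeric",
                 stats = "list", provenance = "character"))

setValidity("LinearQsarModel", function(object) {
  if (length(object@intercept) != 1L) return("intercept must be scalar")
  if (is.null(names(object@coefficients)) || anyDuplicated(names(object@coefficients)))
    return("coefficients must have unique names")
  s <- object@stats
  if (!is.null(s$r2) && is.finite(s$r2) && (s$r2 < -1e-9 || s$r2 > 1 + 1e-9))
    return("r2 outside [0, 1]")
  TRUE
})

#' Forward-selection trace
#'
#' One row per subset size k of the greedy heuristic search: the descriptor
#' chosen at that step, cumulative r2, LOO r2_cv and residual variance s2.
#'
#' @slot steps data.frame with columns k, added, r2, r2_cv, s2.
#' @slot subsets list of character vectors (nested subsets, one per k).
#' @slot recommended integer(1), last k whose r2 gain met the stop threshold.
#' @exportClass SelectionTrace
setClass("SelectionTrace",
  representation(steps = "data.frame", subsets = "list", recommended = "integer"))

#' GEP function set
#'
#' Operator symbols with arities and selection weights; default is the
#' six-operator set (+, -, *, /, inv, sin), all weight 1.
#' @slot symbols character vector.
#' @slot arity integer vector.
#' @slot weight numeric vector.
#' @exportClass FunctionSet
setClass("FunctionSet",
  representation(symbols = "character", arity = "integer", weight = "numeric"))

setValidity("FunctionSet", function(object) {
  if (length(object@symbols) != length(object@arity) ||
      length(object@symbols) != length(object@weight))
    return("symbols, arity, weight must have equal length")
  if (anyDuplicated(object@symbols)) return("duplicate operator symbols")
  if (any(object@arity < 1L)) return("arities must be >= 1")
  if (any(object@weight <= 0)) return("weights must be > 0")
  TRUE
})

#' Karva-encoded linear GEP genotype
#'
#' Each gene is a fixed-length symbol string with a function-bearing head of
#' length h and a terminal-only tail of length t = h*(amax - 1) + 1. Multi-gene
#' chromosomes are joined by the linking operator.
#'
#' @slot genes list of character vectors (symbols).
#' @slot headLength integer(1).
#' @slot tailLength integer(1).
#' @slot terminals character vector of terminal (descriptor) names.
#' @slot functionSet FunctionSet.
#' @slot linker linking operator symbol.
#' @exportClass Chromosome
setClass("Chromosome",
  representation(genes = "list", headLength = "integer", tailLength = "integer",
                 terminals = "character", functionSet = "FunctionSet",
                 linker = "character"))

setValidity("Chromosome", function(object) {
  h <- object@headLength; t <- object@tailLength
  fs <- object@functionSet
  amax <- max(fs@arity)
  if (t != h * (amax - 1L) + 1L) return("tail length must equal h*(amax-1)+1")
  for (g in object@genes) {
    if (length(g) != h + t) return("gene length must equal head + tail")
    if (any(g[(h + 1L):(h + t)] %in% fs@symbols))
      return("tail positions must contain terminals only")
    if (!all(g %in% c(fs@symbols, object@terminals)))
      return("unknown symbol in gene")
  }
  if (length(object@genes) > 1L && !(object@linker %in% fs@symbols))
    return("linker must be a function symbol")
  TRUE
})

#' Expression tree (decoded GEP phenotype)
#'
#' A recursive operator/terminal tree. Nodes are plain lists with fields
#' \code{type} ("op", "terminal" or "const"), \code{symbol}/\code{value} and
#' \code{children}.
#' @slot root list, the root node.
#' @exportClass ExpressionTree
setClass("ExpressionTree", representation(root = "list"))

#' GEP run configuration
#' @slot populationSize integer(1).
#' @slot generations integer(1), generation cap.
#' @slot fitnessTarget numeric(1), early-stop fitness.
#' @slot elitism integer(1), elite copies per generation.
#' @slot rates named numeric: mutation, is_transposition, ris_transposition,
#'   gene_transposition, one_point, two_point, gene_recombination.
#' @slot headLength integer(1).
#' @slot nGenes integer(1).
#' @slot linker character(1).
#' @slot functionSet FunctionSet.
#' @slot seed integer(1).
#' @exportClass GepConfig
setClass("GepConfig",
  representation(populationSize = "integer", generations = "integer",
                 fitnessTarget = "numeric", elitism = "integer",
                 rates = "numeric", headLength = "integer", nGenes = "integer",
                 linker = "character", functionSet = "FunctionSet",
                 seed = "integer"))

setValidity("GepConfig", function(object) {
  if (object@populationSize < 2L) return("population must be >= 2")
  if (object@elitism >= object@populationSize) return("elitism < population required")
  if (any(object@rates < 0 | object@rates > 1)) return("rates must lie in [0, 1]")
  need <- c("mutation", "is_transposition", "ris_transposition",
            "gene_transposition", "one_point", "two_point", "gene_recombination")
  if (!all(need %in% names(object@rates)))
    return(paste("missing rates:", paste(setdiff(need, names(object@rates)), collapse = ", ")))
  TRUE
})

#' GEP run result
#' @slot bestTree ExpressionTree.
#' @slot bestChromosome Chromosome.
#' @slot history numeric vector, best-so-far fitness per generation.
#' @slot trainR2 numeric(1).
#' @slot heldOutR2 numeric(1) or NA.
#' @exportClass GepResult
setClass("GepResult",
  representation(bestTree = "ExpressionTree", bestChromosome = "Chromosome",
                 history = "numeric", trainR2 = "numeric", heldOutR2 = "numeric"))

#' Aligned 3D molecule with per-atom field properties
#'
#' @slot id character(1).
#' @slot atoms data.frame with columns element, x, y, z (Angstrom), charge (e),
#'   radius (vdW, Angstrom), hydrophobicity, donor, acceptor.
#' @slot scaffoldMap integer indices of atoms matched to the template scaffold.
#' @exportClass AlignedMolecule
setClass("AlignedMolecule",
  representation(id = "character", atoms = "data.frame", scaffoldMap = "integer"))

setValidity("AlignedMolecule", function(object) {
  a <- object@atoms
  need <- c("element", "x", "y", "z", "charge", "radius", "hydrophobicity",
            "donor", "acceptor")
  if (!all(need %in% names(a)))
    return(paste("atoms missing columns:", paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) && !all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("non-finite coordinates")
  if (nrow(a) && any(a$radius <= 0)) return("vdW radii must be > 0")
  if (nrow(a) && (!is.logical(a$donor) || !is.logical(a$acceptor)))
    return("donor/acceptor flags must be logical")
  TRUE
})

#' Regular cubic field grid
#' @slot origin numeric(3), coordinates of the first grid point (Angstrom).
#' @slot spacing numeric(1), grid pitch (Angstrom), default 2.
#' @slot counts integer(3), points per axis.
#' @slot margin numeric(1), box extension beyond the molecules (Angstrom).
#' @exportClass FieldGrid
setClass("FieldGrid",
  representation(origin = "numeric", spacing = "numeric", counts = "integer",
                 margin = "numeric"))

setValidity("FieldGrid", function(object) {
  if (length(object@origin) != 3L || length(object@counts) != 3L)
    return("origin and counts must have length 3")
  if (object@spacing <= 0) return("spacing must be > 0")
  if (any(object@counts < 1L)) return("counts must be >= 1")
  TRUE
})

#' CoMSIA similarity-field matrix
#'
#' Rows are compounds; columns are (grid point, field label) pairs for the
#' five fields S, E, H, D, A. Low-variance columns are masked out rather than
#' removed so column indices remain grid-addressable.
#'
#' @slot values numeric matrix (rownames = compound ids).
#' @slot field character, field label per column.
#' @slot pointIndex integer, grid point index per column.
#' @slot active logical mask after variance filtering.
#' @slot grid FieldGrid.
#' @exportClass FieldMatrix
setClass("FieldMatrix",
  representation(values = "matrix", field = "character", pointIndex = "integer",
                 active = "logical", grid = "FieldGrid"))

setValidity("FieldMatrix", function(object) {
  p <- ncol(object@values)
  if (length(object@field) != p || length(object@pointIndex) != p ||
      length(object@active) != p)
    return("field/pointIndex/active must match column count")
  if (!all(object@field %in% .FIELD_LABELS)) return("unknown field label")
  if (any(!is.finite(object@values))) return("non-finite field values")
  TRUE
})

#' PLS model over a CoMSIA field matrix
#'
#' @slot ncomp integer(1), optimal number of components (ONC).
#' @slot coefficients numeric over active columns (named by column id).
#' @slot intercept numeric(1).
#' @slot q2 numeric(1), LOO cross-validated r-squared at ONC.
#' @slot q2History numeric, q2 per candidate component count.
#' @slot r2 numeric(1), non-CV r-squared at ONC.
#' @slot see numeric(1), standard error of estimate.
#' @slot fValue numeric(1).
#' @slot fractions named numeric, per-field contribution fractions (sum 1).
#' @slot columnField character, field label per active column.
#' @slot columnIndex integer, field-matrix column index per active column.
#' @slot xMeans,yMean centering used at fit time.
#' @slot meta list (published reference values, settings).
#' @exportClass PlsQsarModel
setClass("PlsQsarModel",
  representation(ncomp = "integer", coefficients = "numeric",
                 intercept = "numeric", q2 = "numeric", q2History = "numeric",
                 r2 = "numeric", see = "numeric", fValue = "numeric",
                 fractions = "numeric", columnField = "character",
                 columnIndex = "integer", xMeans = "numeric", yMean = "numeric",
                 meta = "list"))

setValidity("PlsQsarModel", function(object) {
  if (object@ncomp < 1L) return("ncomp must be >= 1")
  if (length(object@fractions) &&
      abs(sum(object@fractions) - 1) > 1e-9) return("fractions must sum to 1")
  if (is.finite(object@q2) && object@q2 > 1) return("q2 cannot exceed 1")
  TRUE
})

#' Contour point sets per field
#' @slot contours named list (per field label) of lists with elements
#'   favored, disfavored (grid point indices) and thresholds.
#' @slot grid FieldGrid.
#' @exportClass ContourSet
setClass("ContourSet", representation(contours = "list", grid = "FieldGrid"))

setValidity("ContourSet", function(object) {
  for (f in names(object@contours)) {
    ct <- object@contours[[f]]
    if (length(intersect(ct$favored, ct$disfavored)))
      return(paste("favored and disfavored overlap for field", f))
  }
  TRUE
})

#' External/internal validation report
#' @slot r2Ext numeric(1).
#' @slot r2 numeric(1), squared Pearson correlation of predictions vs observed.
#' @slot r02 named numeric: direct (predictions on observations, through
#'   origin) and reversed.
#' @slot rm2 named numeric: direct, reversed, overall.
#' @slot r2p numeric(1), Y-randomization statistic (NA until computed).
#' @slot r2rList numeric, per-iteration scrambled r2 values.
#' @slot meta list.
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(r2Ext = "numeric", r2 = "numeric", r02 = "numeric",
                 rm2 = "numeric", r2p = "numeric", r2rList = "numeric",
                 meta = "list"))

#' A candidate-design run
#' @slot template character(1), template compound id.
#' @slot table data.frame: rank, id, provenance and one prediction column per
#'   model, ordered by the primary model's prediction (descending, ties by id).
#' @slot primaryModel character(1).
#' @slot models character, names of all models applied.
#' @slot seed integer(1).
#' @exportClass DesignRun
setClass("DesignRun",
  representation(template = "character", table = "data.frame",
                 primaryModel = "character", models = "character",
                 seed = "integer"))

# ---- synthetic-data plant specifications ------------------------------------

#' Planted linear structure-activity specification
#' @slot nCompounds,nDescriptors integer(1).
#' @slot trueSubset character, names of the causal descriptors.
#' @slot trueCoefficients named numeric over trueSubset plus "(Intercept)".
#' @slot noiseSd numeric(1) >= 0.
#' @slot collinearityBlocks list of list(size=, r=).
#' @slot seed integer(1).
#' @exportClass LinearPlantSpec
setClass("LinearPlantSpec",
  representation(nCompounds = "integer", nDescriptors = "integer",
                 trueSubset = "character", trueCoefficients = "numeric",
                 noiseSd = "numeric", collinearityBlocks = "list",
                 seed = "integer"))

setValidity("LinearPlantSpec", function(object) {
  if (length(object@trueCoefficients) != length(object@trueSubset) + 1L)
    return("need one coefficient per true descriptor plus an intercept")
  if (!"(Intercept)" %in% names(object@trueCoefficients))
    return("trueCoefficients must include \"(Intercept)\"")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Planted nonlinear structure-activity specification
#' @slot expression ExpressionTree over descriptor names.
#' @slot noiseSd numeric(1) >= 0.
#' @slot seed integer(1).
#' @exportClass NonlinearPlantSpec
setClass("NonlinearPlantSpec",
  representation(expression = "ExpressionTree", noiseSd = "numeric",
                 seed = "integer"))

#' Planted 3D field-activity specification
#' @slot nMolecules integer(1).
#' @slot atomsPerMolecule integer(2), min/max decoration atoms.
#' @slot propertyRanges named list of numeric(2) ranges for charge and
#'   hydrophobicity.
#' @slot nPlantedWeights integer(1), size of the sparse support used to build
#'   the planted coefficient vector (drawn in the field-matrix row space).
#' @slot noiseSd numeric(1).
#' @slot seed integer(1).
#' @exportClass FieldPlantSpec
setClass("FieldPlantSpec",
  representation(nMolecules = "integer", atomsPerMolecule = "integer",
                 propertyRanges = "list", nPlantedWeights = "integer",
                 noiseSd = "numeric", seed = "integer"))
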