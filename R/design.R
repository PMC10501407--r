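# Candidate-analog enumeration and ranking. The study's own 200 analogs of
# the 21E template were drawn by hand from contour-map and descriptor
# guidance and cannot be regenerated; this module exposes the mechanism (an
# explicit modification library applied to a template) rather than the
# study's specific substituent choices.

#' Enumerate candidate analogs of a template
#'
#' Applies modifications from a user-supplied library to a template
#' compound. A template is a list with an \code{id}, an optional named
#' \code{descriptors} vector (2D branch) and an optional \code{molecule}
#' (\linkS4class{AlignedMolecule}, 3D branch). A modification is a list
#' with a \code{label}, an optional named \code{descriptorDelta} vector and
#' an optional \code{atomEdit} function(molecule) -> molecule. Candidate ids
#' are \code{<template id>.<k>} for k = 1..n.
#'
#' @param template template list as above.
#' @param modificationLibrary non-empty list of modifications.
#' @param n number of candidates.
#' @param seed integer seed for the modification draw.
#' @param replace draw modifications with replacement; without replacement
#'   (default) the library must hold at least \code{n} entries.
#' @return list of candidates (lists with id, provenance, descriptors,
#'   molecule).
#' @export
enumerateCandidates <- function(template, modificationLibrary, n, seed = 1L,
                                replace = FALSE) {
  if (!length(modificationLibrary)) stopf("modification library is empty")
  if (n < 1L) stopf("n must be >= 1")
  if (!replace && n > length(modificationLibrary))
    stopf(paste("library holds %d modifications but %d candidates requested;",
                "use replace = TRUE to sample with replacement"),
          length(modificationLibrary), n)
  picks <- withSeed(seed,
    sample.int(length(modificationLibrary), n, replace = replace))
  lapply(seq_len(n), function(k) {
    mod <- modificationLibrary[[picks[k]]]
    desc <- template$descriptors
    if (!is.null(mod$descriptorDelta) && !is.null(desc)) {
      delta <- mod$descriptorDelta
      miss <- setdiff(names(delta), names(desc))
      if (length(miss))
        stopf("modification '%s' perturbs unknown descriptor(s): %s",
              mod$label, paste(miss, collapse = ", "))
      desc[names(delta)] <- desc[names(delta)] + delta
    }
    mol <- template$molecule
    if (!is.null(mod$atomEdit) && !is.null(mol)) mol <- mod$atomEdit(mol)
    list(id = paste0(template$id, ".", k),
         provenance = paste0(template$id, " + ", mod$label),
         descriptors = desc, molecule = mol)
  })
}

# score one candidate with one model; NA (with a note) when inputs are absent
.scoreCandidate <- function(model, candidate, alpha = 0.3, minSigma = 0.05) {
  if (is(model, "LinearQsarModel")) {
    if (is.null(candidate$descriptors)) return(NA_real_)
    evaluateLinear(model, candidate$descriptors[names(model@coefficients)])
  } else if (is(model, "ExpressionTree")) {
    if (is.null(candidate$descriptors)) return(NA_real_)
    v <- evaluateTree(model, as.list(candidate$descriptors))
    if (is.na(v)) NA_real_ else v
  } else if (is(model, "PlsQsarModel")) {
    if (is.null(candidate$molecule)) return(NA_real_)
    grid <- model@meta$grid
    row <- unlist(lapply(.FIELD_LABELS, function(f)
      computeField(candidate$molecule, grid, f, alpha)))
    predict(model, matrix(row[model@columnIndex], nrow = 1L))
  } else stopf("unsupported model class: %s", class(model))
}

#' Score candidates with every model and rank by the primary one
#'
#' Every candidate is scored by every supplied model (prediction is
#' read-only; models are never modified). Candidates missing the inputs a
#' model needs get \code{NA} for that model with a warning, and the run
#' continues. The ranking orders by the primary model's prediction,
#' descending, with ties broken by id; candidates without a primary
#' prediction sort last.
#'
#' @param candidates list from \code{\link{enumerateCandidates}}.
#' @param models named list of models (LinearQsarModel, ExpressionTree
#'   and/or PlsQsarModel).
#' @param primaryModel name of the ranking model; defaults to the first
#'   PlsQsarModel present, else the first ExpressionTree, else the first
#'   model (the study ranks by the 3D model's prediction).
#' @param template template id recorded on the run.
#' @param seed seed recorded on the run (provenance only).
#' @return a \linkS4class{DesignRun}.
#' @export
predictAndRank <- function(candidates, models, primaryModel = NULL,
                           template = NA_character_, seed = NA_integer_) {
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stopf("models must be a named list")
  if (is.null(primaryModel)) {
    cls <- vapply(models, function(m)
      if (is(m, "PlsQsarModel")) 1L else if (is(m, "ExpressionTree")) 2L else 3L,
      0L)
    primaryModel <- names(models)[order(cls)][1L]
  }
  if (!primaryModel %in% names(models))
    stopf("primaryModel '%s' not among the supplied models", primaryModel)
  scores <- vapply(names(models), function(nm)
    vapply(candidates, function(cd)
      tryCatch(.scoreCandidate(models[[nm]], cd),
               error = function(e) NA_real_), 0),
    numeric(length(candidates)))
  if (length(candidates) == 1L) scores <- matrix(scores, nrow = 1L,
                                                 dimnames = list(NULL, names(models)))
  nMissing <- sum(is.na(scores))
  if (nMissing)
    warnf("%d candidate/model prediction(s) unavailable (missing inputs)",
          nMissing)
  ids <- vapply(candidates, `[[`, "", "id")
  prov <- vapply(candidates, `[[`, "", "provenance")
  d <- data.frame(id = ids, provenance = prov, scores, check.names = FALSE,
                  stringsAsFactors = FALSE)
  pri <- d[[primaryModel]]
  ord <- order(-pri, d$id, na.last = TRUE)
  d <- d[ord, , drop = FALSE]
  d <- cbind(rank = seq_len(nrow(d)), d)
  rownames(d) <- NULL
  new("DesignRun", template = as.character(template), table = d,
      primaryModel = primaryModel, models = names(models),
      seed = as.integer(seed))
}

#' Top of a design-run ranking
#' @param run a \linkS4class{DesignRun}.
#' @param n rows to return, default 8.
#' @return data.frame of the top-ranked candidates.
#' @export
topCandidates <- function(run, n = 8L) utils::head(run@table, n)
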