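#' @rdname CompoundSet-class
#' @param object,x an object.
#' @export
setGeneric("compoundIds", function(object) standardGeneric("compoundIds"))

#' @rdname CompoundSet-class
#' @export
setGeneric("activities", function(object) standardGeneric("activities"))

#' @rdname CompoundSet-class
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))

#' @rdname CompoundSet-class
#' @export
setGeneric("roles", function(object) standardGeneric("roles"))

#' @rdname DescriptorTable-class
#' @export
setGeneric("descriptorMatrix", function(object) standardGeneric("descriptorMatrix"))

#' @rdname DescriptorTable-class
#' @export
setGeneric("descriptorNames", function(object) standardGeneric("descriptorNames"))

# ---- CompoundSet methods ----------------------------------------------------

#' @rdname CompoundSet-class
#' @export
setMethod("compoundIds", "CompoundSet", function(object) object@data$id)

#' @rdname CompoundSet-class
#' @export
setMethod("activities", "CompoundSet", function(object)
  stats::setNames(object@data$activity, object@data$id))

#' @rdname CompoundSet-class
#' @export
setMethod("ic50", "CompoundSet", function(object)
  stats::setNames(object@data$ic50, object@data$id))

#' @rdname CompoundSet-class
#' @export
setMethod("roles", "CompoundSet", function(object)
  stats::setNames(object@data$role, object@data$id))

#' @rdname CompoundSet-class
#' @export
setMethod("length", "CompoundSet", function(x) nrow(x@data))

#' @rdname CompoundSet-class
#' @param i index (integer, logical or compound id).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@data$id)
  if (anyNA(i)) stop("unknown compound id")
  d <- x@data[i, , drop = FALSE]
  rownames(d) <- NULL
  new("CompoundSet", data = d, provenance = x@provenance,
      transform = x@transform)
})

setMethod("show", "CompoundSet", function(object) {
  d <- object@data
  cat("CompoundSet with", nrow(d), "compounds (", object@provenance, ")\n")
  cat("  activity (pAct) range:",
      if (nrow(d)) paste(round(range(d$activity), 4), collapse = " - ") else "-",
      "\n")
  tab <- table(d$role)
  cat("  roles:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
})

#' Convert a CompoundSet to a data.frame
#' @param x a CompoundSet.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "CompoundSet", function(x, ...) x@data)

# ---- DescriptorTable methods ------------------------------------------------

#' @rdname DescriptorTable-class
#' @export
setMethod("descriptorMatrix", "DescriptorTable", function(object) object@values)

#' @rdname DescriptorTable-class
#' @export
setMethod("descriptorNames", "DescriptorTable", function(object) colnames(object@values))

#' @rdname DescriptorTable-class
#' @export
setMethod("compoundIds", "DescriptorTable", function(object) rownames(object@values))

#' @rdname DescriptorTable-class
#' @export
setMethod("dim", "DescriptorTable", function(x) dim(x@values))

#' @rdname DescriptorTable-class
#' @param i row index; @param j column index.
#' @export
setMethod("[", "DescriptorTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values[i, j, drop = FALSE]
  new("DescriptorTable", values = v)
})

setMethod("show", "DescriptorTable", function(object) {
  cat("DescriptorTable:", nrow(object@values), "compounds x",
      ncol(object@values), "descriptors\n")
  if (anyNA(object@values)) cat("  (contains missing values)\n")
})

# ---- model shows ------------------------------------------------------------

setMethod("show", "LinearQsarModel", function(object) {
  cat("LinearQsarModel (", object@provenance, ")\n", sep = "")
  cat("  intercept:", format(object@intercept), "\n")
  for (nm in names(object@coefficients))
    cat(sprintf("  %-8s %12.6g\n", nm, object@coefficients[[nm]]))
  s <- object@stats
  if (!is.null(s$r2))
    cat(sprintf("  r2 = %.4f  r2_cv = %.4f  s2 = %.4g\n",
                s$r2, if (is.null(s$r2_cv)) NA else s$r2_cv,
                if (is.null(s$s2)) NA else s$s2))
})

setMethod("show", "SelectionTrace", function(object) {
  cat("SelectionTrace: forward search to k =", max(object@steps$k),
      "; recommended size", object@recommended, "\n")
  print(object@steps, row.names = FALSE)
})

#' @rdname LinearQsarModel-class
#' @param object a LinearQsarModel.
#' @export
setMethod("coef", "LinearQsarModel", function(object)
  c("(Intercept)" = object@intercept, object@coefficients))

setMethod("show", "Chromosome", function(object) {
  cat("Chromosome:", length(object@genes), "gene(s), h =", object@headLength,
      ", t =", object@tailLength, ", linker", object@linker, "\n")
  for (g in object@genes) cat(" ", paste(g, collapse = " "), "\n")
})

setMethod("show", "ExpressionTree", function(object)
  cat("ExpressionTree:", deparseTree(object), "\n"))

setMethod("show", "GepResult", function(object) {
  cat("GepResult: best fitness", format(max(object@history)), "after",
      length(object@history), "generation(s)\n")
  cat("  best:", deparseTree(object@bestTree), "\n")
  cat(sprintf("  train r2 = %.4f", object@trainR2))
  if (is.finite(object@heldOutR2))
    cat(sprintf("  held-out r2 = %.4f", object@heldOutR2))
  cat("\n")
})

setMethod("show", "AlignedMolecule", function(object)
  cat("AlignedMolecule", object@id, "with", nrow(object@atoms), "atoms\n"))

setMethod("show", "FieldGrid", function(object) {
  cat("FieldGrid:", paste(object@counts, collapse = " x "), "points, spacing",
      object@spacing, "A, margin", object@margin, "A\n")
  cat("  origin:", paste(round(object@origin, 3), collapse = ", "), "\n")
})

setMethod("show", "FieldMatrix", function(object)
  cat("FieldMatrix:", nrow(object@values), "compounds x", ncol(object@values),
      "columns (", sum(object@active), "active after variance filter )\n"))

setMethod("show", "PlsQsarModel", function(object) {
  cat("PlsQsarModel: ONC =", object@ncomp, "\n")
  cat(sprintf("  q2 = %.4f  r2 = %.4f  SEE = %.4f  F = %.4f\n",
              object@q2, object@r2, object@see, object@fValue))
  cat("  field fractions:",
      paste(names(object@fractions), round(object@fractions, 3),
            sep = ":", collapse = " "), "\n")
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport\n")
  cat(sprintf("  r2_ext = %.4f  r2 = %.4f\n", object@r2Ext, object@r2))
  cat(sprintf("  rm2 = %.4f (reversed %.4f, overall %.4f)\n",
              object@rm2[["direct"]], object@rm2[["reversed"]],
              object@rm2[["overall"]]))
  if (is.finite(object@r2p))
    cat(sprintf("  Y-randomization r2_p = %.4f over %d iterations\n",
                object@r2p, length(object@r2rList)))
})

setMethod("show", "DesignRun", function(object) {
  cat("DesignRun on template", object@template, ":", nrow(object@table),
      "candidates ranked by", object@primaryModel, "\n")
  print(utils::head(object@table, 8), row.names = FALSE)
})
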