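# CoMSIA similarity fields: Gaussian distance attenuation, no cutoff.

.fieldWeights <- function(mol, fieldLabel) {
  a <- mol@atoms
  w <- switch(fieldLabel,
    S = a$radius^3,
    E = a$charge,
    H = a$hydrophobicity,
    D = as.numeric(a$donor),
    A = as.numeric(a$acceptor),
    stopf("unknown field label: %s (use S, E, H, D or A)", fieldLabel))
  if (anyNA(w))
    stopf("missing %s-field property for atom(s) %s of molecule %s",
          fieldLabel, paste(which(is.na(w)), collapse = ", "), mol@id)
  w
}

#' Compute one CoMSIA similarity field for one molecule
#'
#' Value at grid point q is the negated Gaussian-attenuated sum
#' -sum_atoms w_probe * w_atom * exp(-alpha * r(atom, q)^2) (the CoMSIA
#' similarity-index sign convention), with no distance cutoff. Atom weights
#' per field: steric = vdW radius cubed, electrostatic = partial charge,
#' hydrophobic = atom hydrophobicity parameter, donor/acceptor = 0/1 flags.
#' The probe carries unit weight in every field (radius 1 Angstrom, charge
#' +1, hydrophobicity +1, donor/acceptor +1).
#'
#' @param mol an \linkS4class{AlignedMolecule}.
#' @param grid a \linkS4class{FieldGrid}.
#' @param fieldLabel one of "S", "E", "H", "D", "A".
#' @param alpha Gaussian attenuation factor in 1/Angstrom^2, default 0.3.
#' @return numeric vector over grid points.
#' @export
computeField <- function(mol, grid, fieldLabel, alpha = 0.3) {
  w <- .fieldWeights(mol, fieldLabel)
  pts <- gridPoints(grid)
  xyz <- as.matrix(mol@atoms[, c("x", "y", "z")])
  # squared distances grid-points x atoms
  d2 <- outer(rowSums(pts^2), rep(1, nrow(xyz))) +
        outer(rep(1, nrow(pts)), rowSums(xyz^2)) - 2 * pts %*% t(xyz)
  d2[d2 < 0] <- 0
  -drop(exp(-alpha * d2) %*% w)
}

#' Assemble the multi-molecule field matrix
#'
#' Stacks the five similarity fields of every molecule into a compounds x
#' (grid points x fields) matrix, field-major column order (all S columns,
#' then E, H, D, A). Columns whose standard deviation across compounds is
#' below \code{minSigma} are masked inactive rather than removed, so column
#' indices stay addressable on the grid. Masking is idempotent.
#'
#' @param molecules list of \linkS4class{AlignedMolecule}, all in the same
#'   reference frame.
#' @param grid a \linkS4class{FieldGrid}; defaults to
#'   \code{buildGrid(molecules)}.
#' @param alpha Gaussian attenuation, default 0.3.
#' @param minSigma column standard-deviation floor (similarity units),
#'   default 0.05.
#' @return a \linkS4class{FieldMatrix}.
#' @export
assembleFieldMatrix <- function(molecules, grid = buildGrid(molecules),
                                alpha = 0.3, minSigma = 0.05) {
  if (is(molecules, "AlignedMolecule")) molecules <- list(molecules)
  nPts <- prod(grid@counts)
  ids <- vapply(molecules, function(m) m@id, "")
  rows <- lapply(molecules, function(m)
    unlist(lapply(.FIELD_LABELS, function(f) computeField(m, grid, f, alpha))))
  vals <- do.call(rbind, rows)
  rownames(vals) <- ids
  field <- rep(.FIELD_LABELS, each = nPts)
  pointIndex <- rep(seq_len(nPts), times = length(.FIELD_LABELS))
  colnames(vals) <- paste0(field, ".", pointIndex)
  sds <- apply(vals, 2L, stats::sd)
  active <- sds >= minSigma
  if (!any(active))
    stopf("no field column passes the variance filter (minSigma = %g)", minSigma)
  new("FieldMatrix", values = vals, field = field,
      pointIndex = as.integer(pointIndex), active = unname(active),
      grid = grid)
}

#' Write a scalar grid in OpenDX format
#'
#' @param values numeric vector over grid points, in the package's grid-point
#'   order (x fastest); reordered internally to the OpenDX z-fastest
#'   convention.
#' @param grid a \linkS4class{FieldGrid}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeOpenDx <- function(values, grid, path) {
  ct <- grid@counts
  if (length(values) != prod(ct)) stopf("values length != grid size")
  # package order: x fastest; DX order: z fastest
  arr <- array(values, dim = ct)
  dxOrder <- as.vector(aperm(arr, c(3, 2, 1)))  # now x slowest
  sp <- grid@spacing
  lines <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", ct[1], ct[2], ct[3]),
    sprintf("origin %g %g %g", grid@origin[1], grid@origin[2], grid@origin[3]),
    sprintf("delta %g 0 0", sp), sprintf("delta 0 %g 0", sp),
    sprintf("delta 0 0 %g", sp),
    sprintf("object 2 class gridconnections counts %d %d %d", ct[1], ct[2], ct[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(ct)))
  nChunk <- ceiling(length(dxOrder) / 3L)
  dat <- vapply(seq_len(nChunk), function(i) {
    v <- dxOrder[(3L * i - 2L):min(3L * i, length(dxOrder))]
    paste(formatC(v, format = "g", digits = 8), collapse = " ")
  }, "")
  lines <- c(lines, dat,
             "attribute \"dep\" string \"positions\"",
             "object \"field\" class field",
             "component \"positions\" value 1",
             "component \"connections\" value 2",
             "component \"data\" value 3")
  writeLines(lines, path)
  invisible(path)
}
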