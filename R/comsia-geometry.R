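#' Rigid-body superposition onto a template (Kabsch)
#'
#' Least-squares superposition of a molecule onto a template over a set of
#' mapped scaffold atoms: the optimal rotation is obtained from the SVD of
#' the mapped-coordinate covariance (reflections excluded), translation from
#' the centroids. The whole molecule is moved by the resulting transform and
#' the scaffold RMSD after superposition is attached as
#' \code{attr(, "rmsd")}.
#'
#' @param mol an \linkS4class{AlignedMolecule} to move.
#' @param template an \linkS4class{AlignedMolecule} in the reference frame.
#' @param atomMap two-column integer matrix: column 1 = atom indices in
#'   \code{mol}, column 2 = matching atom indices in \code{template}. Needs
#'   at least 3 non-collinear pairs.
#' @return the transformed \linkS4class{AlignedMolecule} with
#'   \code{scaffoldMap} set and the scaffold RMSD as an attribute.
#' @export
alignToTemplate <- function(mol, template, atomMap) {
  atomMap <- as.matrix(atomMap)
  if (ncol(atomMap) != 2L || nrow(atomMap) < 3L)
    stopf("atomMap must have two columns and at least 3 rows")
  P <- as.matrix(mol@atoms[atomMap[, 1L], c("x", "y", "z")])
  Q <- as.matrix(template@atoms[atomMap[, 2L], c("x", "y", "z")])
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2L, cP); Qc <- sweep(Q, 2L, cQ)
  sv <- svd(crossprod(Pc, Qc))            # 3x3
  if (sv$d[2L] < 1e-8)
    stopf("mapped atoms are collinear or degenerate; cannot determine rotation")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  allXyz <- as.matrix(mol@atoms[, c("x", "y", "z")])
  moved <- sweep(allXyz, 2L, cP) %*% t(R)
  moved <- sweep(moved, 2L, cQ, FUN = "+")
  out <- mol
  out@atoms$x <- moved[, 1L]; out@atoms$y <- moved[, 2L]; out@atoms$z <- moved[, 3L]
  out@scaffoldMap <- as.integer(atomMap[, 1L])
  mappedMoved <- moved[atomMap[, 1L], , drop = FALSE]
  attr(out, "rmsd") <- sqrt(mean(rowSums((mappedMoved - Q)^2)))
  out
}

#' Build the cubic field grid around a molecule set
#'
#' Axis-aligned box covering the union of the molecules' bounding boxes,
#' extended by \code{margin} in all directions, sampled at \code{spacing}
#' pitch: per-axis point count is floor(extent/spacing) + 1. The defaults
#' (2 Angstrom pitch, 4 Angstrom extension) give a 5 x 5 x 5 grid for a
#' single atom at the origin.
#'
#' @param molecules list of \linkS4class{AlignedMolecule} (or a single one).
#' @param spacing grid pitch in Angstrom, default 2.
#' @param margin box extension in Angstrom, default 4.
#' @return a \linkS4class{FieldGrid}.
#' @export
buildGrid <- function(molecules, spacing = 2, margin = 4) {
  if (is(molecules, "AlignedMolecule")) molecules <- list(molecules)
  if (!length(molecules)) stopf("need at least one molecule")
  xyz <- do.call(rbind, lapply(molecules, function(m)
    as.matrix(m@atoms[, c("x", "y", "z")])))
  lo <- apply(xyz, 2L, min) - margin
  hi <- apply(xyz, 2L, max) + margin
  counts <- as.integer(floor((hi - lo) / spacing) + 1L)
  new("FieldGrid", origin = unname(lo), spacing = spacing, counts = counts,
      margin = margin)
}

#' Grid point coordinates
#'
#' Returns the coordinates of all grid points as an n x 3 matrix, x index
#' varying fastest, then y, then z.
#'
#' @param grid a \linkS4class{FieldGrid}.
#' @return numeric matrix (prod(counts) x 3).
#' @export
gridPoints <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid@origin[k] + grid@spacing * (seq_len(grid@counts[k]) - 1L))
  as.matrix(expand.grid(x = ax[[1L]], y = ax[[2L]], z = ax[[3L]]))
}
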