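# Aligned-molecule construction and SDF interchange (via ChemmineR).

.BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

.hydrophobicityTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "atom_hydrophobicity.csv",
                          package = "gbmQSAR", mustWork = TRUE)
      tb <- utils::read.csv(path, stringsAsFactors = FALSE)
      cache <<- stats::setNames(tb$hydrophobicity, tb$element)
    }
    cache
  }
})

#' Element-based default atom properties
#'
#' vdW radii follow the Bondi compilation; hydrophobicity comes from the
#' packaged atom-typed lookup table; acceptors are N and O atoms. Donor
#' flags need connectivity (an H on N or O) and default to FALSE here.
#'
#' @param element character vector of element symbols.
#' @return data.frame with columns radius, hydrophobicity, acceptor, donor.
#' @export
elementProperties <- function(element) {
  rad <- .BONDI_RADII[element]
  if (anyNA(rad))
    stopf("no vdW radius for element(s): %s",
          paste(unique(element[is.na(rad)]), collapse = ", "))
  hyd <- .hydrophobicityTable()[element]
  data.frame(radius = unname(rad), hydrophobicity = unname(hyd),
             acceptor = element %in% c("N", "O"),
             donor = FALSE)
}

#' Construct an AlignedMolecule
#'
#' @param id molecule id.
#' @param element element symbols.
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param charge partial charges (e); default 0.
#' @param radius,hydrophobicity,donor,acceptor per-atom properties;
#'   element-based defaults are filled in where omitted.
#' @param scaffoldMap optional integer atom indices matched to the template.
#' @return an \linkS4class{AlignedMolecule}.
#' @export
alignedMolecule <- function(id, element, xyz, charge = 0, radius = NULL,
                            hydrophobicity = NULL, donor = NULL,
                            acceptor = NULL, scaffoldMap = integer()) {
  xyz <- as.matrix(xyz)
  defs <- elementProperties(element)
  n <- length(element)
  atoms <- data.frame(
    element = element,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    charge = rep_len(charge, n),
    radius = if (is.null(radius)) defs$radius else rep_len(radius, n),
    hydrophobicity = if (is.null(hydrophobicity)) defs$hydrophobicity
                     else rep_len(hydrophobicity, n),
    donor = if (is.null(donor)) defs$donor else rep_len(as.logical(donor), n),
    acceptor = if (is.null(acceptor)) defs$acceptor
               else rep_len(as.logical(acceptor), n),
    stringsAsFactors = FALSE)
  new("AlignedMolecule", id = as.character(id), atoms = atoms,
      scaffoldMap = as.integer(scaffoldMap))
}

#' Read aligned molecules from a multi-record SDF (V2000)
#'
#' Coordinates and elements come from the atom blocks; donor flags are set
#' on N/O atoms bonded to a hydrogen (from the bond block); acceptors are N
#' and O; charges default to 0 unless overridden. An optional per-atom
#' property table (delimited text with columns \code{molecule},
#' \code{atom}, and any of \code{charge}, \code{hydrophobicity},
#' \code{donor}, \code{acceptor}) overrides the computed properties.
#'
#' @param path SDF file path.
#' @param propertyTable optional path to the per-atom property table.
#' @return list of \linkS4class{AlignedMolecule}.
#' @export
readAlignedMolecules <- function(path, propertyTable = NULL) {
  sdfs <- ChemmineR::read.SDFset(path)
  ChemmineR::cid(sdfs) <- ChemmineR::sdfid(sdfs)
  props <- if (!is.null(propertyTable)) {
    first <- readLines(propertyTable, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", first)) "\t" else ","
    utils::read.table(propertyTable, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
  } else NULL
  out <- vector("list", length(sdfs))
  for (i in seq_along(sdfs)) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    element <- gsub("_[0-9]+$", "", rownames(ab))
    xyz <- ab[, 1:3, drop = FALSE]
    mol <- alignedMolecule(ChemmineR::sdfid(sdfs)[i], element, xyz)
    # donor flags from connectivity: N/O bonded to H
    bb <- ChemmineR::bondblock(sdf)
    if (is.matrix(bb) && nrow(bb)) {
      isH <- element == "H"
      for (b in seq_len(nrow(bb))) {
        a1 <- bb[b, 1L]; a2 <- bb[b, 2L]
        if (is.na(a1) || is.na(a2) || a1 > length(element) ||
            a2 > length(element)) next
        if (isH[a1] && element[a2] %in% c("N", "O")) mol@atoms$donor[a2] <- TRUE
        if (isH[a2] && element[a1] %in% c("N", "O")) mol@atoms$donor[a1] <- TRUE
      }
    }
    if (!is.null(props)) {
      sub <- props[props$molecule == mol@id, , drop = FALSE]
      for (col in intersect(c("charge", "hydrophobicity", "donor", "acceptor"),
                            names(sub)))
        mol@atoms[[col]][sub$atom] <- if (col %in% c("donor", "acceptor"))
          as.logical(sub[[col]]) else sub[[col]]
    }
    validObject(mol)
    out[[i]] <- mol
  }
  out
}

#' Write aligned molecules as a multi-record SDF (V2000)
#'
#' Elements and coordinates are preserved; computed per-atom properties are
#' not representable in plain V2000 and can be exported separately with
#' \code{\link{writeAtomProperties}}.
#'
#' @param molecules list of \linkS4class{AlignedMolecule}.
#' @param path output SDF path.
#' @return invisibly, \code{path}.
#' @export
writeAlignedMolecules <- function(molecules, path) {
  if (is(molecules, "AlignedMolecule")) molecules <- list(molecules)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in molecules) {
    n <- nrow(m@atoms)
    # minimal chain connectivity: enough for a valid V2000 record (our
    # synthetic molecules carry no chemically meaningful bond graph)
    nb <- max(n - 1L, 0L)
    bonds <- if (nb) sprintf("%3d%3d  1  0  0  0  0", seq_len(nb), seq_len(nb) + 1L)
             else character()
    lines <- c(m@id, "  gbmQSAR", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       m@atoms$x, m@atoms$y, m@atoms$z, m@atoms$element),
               bonds, "M  END", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Export per-atom field properties as delimited text
#' @param molecules list of AlignedMolecule.
#' @param path output path (comma-delimited, columns molecule, atom,
#'   element, charge, hydrophobicity, donor, acceptor).
#' @return invisibly, \code{path}.
#' @export
writeAtomProperties <- function(molecules, path) {
  if (is(molecules, "AlignedMolecule")) molecules <- list(molecules)
  rows <- do.call(rbind, lapply(molecules, function(m)
    data.frame(molecule = m@id, atom = seq_len(nrow(m@atoms)),
               element = m@atoms$element, charge = m@atoms$charge,
               hydrophobicity = m@atoms$hydrophobicity,
               donor = m@atoms$donor, acceptor = m@atoms$acceptor)))
  utils::write.table(rows, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
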