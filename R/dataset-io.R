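#' Transform IC50 to the modelling activity scale
#'
#' Converts a micromolar IC50 to the dimensionless activity used throughout
#' the package, pAct = 9 - log10(IC50/uM), so that more potent compounds
#' (smaller IC50) get larger activities. The Table-1-range IC50s of the
#' dihydropteridone series (0.18-1.07 uM) map to roughly 8.97-9.74.
#' \code{formula = "literal"} applies log10(IC50) + 9 instead (an audit mode;
#' it is increasing in IC50).
#'
#' @param ic50 numeric vector of IC50 values in micromolar, strictly positive.
#' @param formula "pAct" (default) or "literal".
#' @param id optional compound ids used in error messages.
#' @return numeric vector of activities (log units).
#' @examples
#' transformActivity(1)    # 9
#' transformActivity(0.18) # 9.7447
#' @export
transformActivity <- function(ic50, formula = c("pAct", "literal"), id = NULL) {
  formula <- match.arg(formula)
  bad <- !is.finite(ic50) | ic50 <= 0
  if (any(bad)) {
    lab <- if (!is.null(id)) paste(id[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stopf("IC50 must be finite and > 0; offending compound(s): %s", lab)
  }
  if (formula == "pAct") 9 - log10(ic50) else log10(ic50) + 9
}

#' Invert the activity transform
#' @param activity numeric activity (pAct scale).
#' @param formula as in \code{\link{transformActivity}}.
#' @return IC50 in micromolar.
#' @export
inverseTransformActivity <- function(activity, formula = c("pAct", "literal")) {
  formula <- match.arg(formula)
  if (formula == "pAct") 10^(9 - activity) else 10^(activity - 9)
}

#' Construct a CompoundSet
#'
#' @param id character vector of unique, non-empty compound labels.
#' @param ic50 IC50 values in micromolar.
#' @param smiles optional SMILES strings.
#' @param role split role, recycled; default "unassigned".
#' @param provenance free-text source tag.
#' @param formula activity transform variant.
#' @return a \linkS4class{CompoundSet}; activities are computed from IC50.
#' @export
compoundSet <- function(id, ic50, smiles = NA_character_,
                        role = "unassigned", provenance = "in-memory",
                        formula = c("pAct", "literal")) {
  formula <- match.arg(formula)
  id <- as.character(id)
  if (anyDuplicated(id))
    stopf("duplicate compound id(s): %s",
          paste(unique(id[duplicated(id)]), collapse = ", "))
  act <- transformActivity(ic50, formula = formula, id = id)
  d <- data.frame(id = id, smiles = as.character(smiles), ic50 = as.numeric(ic50),
                  activity = act, role = rep_len(role, length(id)),
                  stringsAsFactors = FALSE)
  new("CompoundSet", data = d, provenance = provenance, transform = formula)
}

#' Read a compound activity table
#'
#' Reads a delimited text file (comma or tab, auto-detected from the header
#' line) with columns \code{id}, optional \code{smiles} and \code{ic50_uM}
#' (or \code{ic50}), and returns a validated \linkS4class{CompoundSet} with
#' activities computed.
#'
#' @param path file path.
#' @param formula activity transform variant.
#' @return a \linkS4class{CompoundSet}.
#' @seealso \code{\link{table1CompoundSet}} for the packaged assay fixture.
#' @export
readCompoundTable <- function(path, formula = c("pAct", "literal")) {
  formula <- match.arg(formula)
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(first)) stopf("empty compound table: %s", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                         stringsAsFactors = FALSE, comment.char = "",
                         colClasses = "character")
  names(d) <- tolower(names(d))
  if ("ic50_um" %in% names(d)) names(d)[names(d) == "ic50_um"] <- "ic50"
  if (!all(c("id", "ic50") %in% names(d)))
    stopf("compound table must have columns 'id' and 'ic50_uM' (or 'ic50'); found: %s",
          paste(names(d), collapse = ", "))
  if (!nrow(d)) stopf("compound table has no rows: %s", path)
  ic <- suppressWarnings(as.numeric(d$ic50))
  if (anyNA(ic))
    stopf("unparseable IC50 value(s) for compound(s): %s",
          paste(d$id[is.na(ic)], collapse = ", "))
  compoundSet(id = d$id, ic50 = ic,
              smiles = if ("smiles" %in% names(d)) d$smiles else NA_character_,
              provenance = path, formula = formula)
}

#' Write a compound table
#' @param set a CompoundSet.
#' @param path output path; comma-delimited with header id, smiles, ic50_uM.
#' @return invisibly, \code{path}.
#' @export
writeCompoundTable <- function(set, path) {
  d <- set@data
  out <- data.frame(id = d$id, smiles = d$smiles, ic50_uM = d$ic50)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' The packaged dihydropteridone assay fixture
#'
#' Loads the packaged table of 34 dihydropteridone derivatives with their
#' glioblastoma IC50 values in micromolar (series 13a-13v and 21A-21L;
#' the most potent compound is 21E at 0.18 uM, the least potent 13m at
#' 1.07 uM). Substituent structures are not machine-readable and are not
#' included.
#'
#' @param formula activity transform variant.
#' @return a \linkS4class{CompoundSet} of 34 records.
#' @export
table1CompoundSet <- function(formula = c("pAct", "literal")) {
  path <- system.file("extdata", "dihydropteridone_ic50.csv",
                      package = "gbmQSAR", mustWork = TRUE)
  readCompoundTable(path, formula = match.arg(formula))
}

#' Registry of the six published 2D descriptors
#'
#' The six CODESSA-type descriptors of the published six-parameter linear
#' model, with their physico-chemical meaning and published coefficient and
#' t statistics.
#'
#' @return data.frame with columns name, description, coefficient, t_value.
#' @export
descriptorRegistry <- function() {
  data.frame(
    name = c("NFA", "MRCH", "MECN", "TEIZP", "ZXS", "MCIHN"),
    description = c(
      "Number of F atoms",
      "Max e-e repulsion for a C-H bond",
      "Min exchange energy for a C-N bond",
      "Topographic electronic index (all bonds) [Zefirov's PC]",
      "ZX Shadow / ZX Rectangle",
      "Min coulombic interaction for a H-N bond"),
    coefficient = c(2.9798e-01, 4.4403e-01, 5.6298e+00, -5.7965e-01,
                    3.6953e+00, -3.8370e+00),
    t_value = c(4.0171, 2.5384, 3.3342, -3.1843, 2.7395, -1.5254),
    stringsAsFactors = FALSE)
}

#' Construct a DescriptorTable
#' @param values numeric matrix; rownames = compound ids, colnames =
#'   descriptor names (or supply via \code{ids}/\code{names}).
#' @param ids,names optional dimnames.
#' @return a \linkS4class{DescriptorTable}.
#' @export
descriptorTable <- function(values, ids = rownames(values),
                            names = colnames(values)) {
  values <- as.matrix(values)
  rownames(values) <- as.character(ids)
  colnames(values) <- as.character(names)
  new("DescriptorTable", values = values)
}

#' Read a descriptor matrix from delimited text
#'
#' First column is the compound id; remaining columns are named numeric
#' descriptors. Separator (comma/tab) is auto-detected.
#'
#' @param path file path.
#' @param na_action what to do with missing values: "error" (default),
#'   "drop_columns" or "drop_rows" (dropped names are reported in a message).
#' @return a \linkS4class{DescriptorTable} with no missing values.
#' @export
readDescriptorTable <- function(path,
                                na_action = c("error", "drop_columns", "drop_rows")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, comment.char = "",
                         check.names = FALSE)
  if (ncol(d) < 2L) stopf("descriptor table needs an id column plus descriptors")
  ids <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m)) {
    if (na_action == "error") {
      stopf("missing descriptor values (columns: %s); use na_action to drop",
            paste(colnames(m)[colSums(is.na(m)) > 0], collapse = ", "))
    } else if (na_action == "drop_columns") {
      drop <- colSums(is.na(m)) > 0
      message("dropping ", sum(drop), " descriptor column(s) with missing values: ",
              paste(colnames(m)[drop], collapse = ", "))
      m <- m[, !drop, drop = FALSE]
    } else {
      drop <- rowSums(is.na(m)) > 0
      message("dropping ", sum(drop), " compound row(s) with missing values: ",
              paste(rownames(m)[drop], collapse = ", "))
      m <- m[!drop, , drop = FALSE]
    }
  }
  new("DescriptorTable", values = m)
}

#' Write a descriptor matrix as delimited text
#' @param table a DescriptorTable.
#' @param path output path (comma-delimited; first column \code{id}).
#' @return invisibly, \code{path}.
#' @export
writeDescriptorTable <- function(table, path) {
  m <- descriptorMatrix(table)
  d <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(d, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Seeded train/held-out partition
#'
#' Randomly partitions a CompoundSet into a training set and a held-out set
#' at a given held-out:train ratio (the study design uses 1:3 test:train for
#' the 2D branch and 1:4 validation:train for the 3D branch). The held-out
#' size is \code{round(n * a/(a+b))} for a ratio a:b, so 34 compounds at 1:3
#' give 8 held out and 26 training. Same seed, same membership.
#'
#' @param set a CompoundSet.
#' @param ratio length-2 numeric c(a, b) meaning a:b held-out:train, or a
#'   single fraction in (0, 1).
#' @param seed integer RNG seed.
#' @param heldOutRole role stamped on held-out records ("test" or
#'   "validation").
#' @return list with elements \code{train} and \code{heldOut}
#'   (CompoundSets with roles stamped).
#' @export
splitDataset <- function(set, ratio = c(1, 3), seed = 1L,
                         heldOutRole = c("test", "validation")) {
  heldOutRole <- match.arg(heldOutRole)
  n <- length(set)
  if (n < 2L) stopf("need at least 2 compounds to split, got %d", n)
  frac <- if (length(ratio) == 2L) ratio[1] / sum(ratio) else ratio[1]
  if (!is.finite(frac) || frac <= 0 || frac >= 1)
    stopf("held-out fraction must lie in (0, 1), got %s", format(frac))
  nHeld <- round(n * frac)
  if (nHeld < 1L || nHeld >= n)
    stopf("ratio yields an empty partition (n = %d, held-out = %d)", n, nHeld)
  idx <- withSeed(seed, sample.int(n, nHeld))
  d <- set@data
  d$role <- "train"
  d$role[idx] <- heldOutRole
  held <- d[sort(idx), , drop = FALSE]
  train <- d[setdiff(seq_len(n), idx), , drop = FALSE]
  rownames(held) <- rownames(train) <- NULL
  list(train = new("CompoundSet", data = train, provenance = set@provenance,
                   transform = set@transform),
       heldOut = new("CompoundSet", data = held, provenance = set@provenance,
                     transform = set@transform))
}
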