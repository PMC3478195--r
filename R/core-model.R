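# Structure accessors and PDB input/output.
#
# PDB record parsing/formatting is delegated to bio3d; the contract applied
# on top: first MODEL only, ATOM records only (no HETATM/waters), hydrogens
# dropped unless requested, alternate locations resolved to the highest
# occupancy (ties: altloc "A", then first in file).

#' Number of atoms
#' @param x a \linkS4class{ProteinStructure}.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@atoms))

#' Atom coordinate matrix (n x 3, Angstrom)
#' @param x a \linkS4class{ProteinStructure}.
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' @rdname atomCoords
#' @export
setMethod("atomCoords", "ProteinStructure", function(x)
  cbind(x = x@atoms$x, y = x@atoms$y, z = x@atoms$z))

#' ACE atom types as a 0-based integer vector (NA = untyped)
#' @param x a \linkS4class{ProteinStructure}.
#' @export
setGeneric("atomTypes", function(x) standardGeneric("atomTypes"))

#' @rdname atomTypes
#' @export
setMethod("atomTypes", "ProteinStructure", function(x) x@atoms$aceType)

#' Atom table of a structure
#' @param x a \linkS4class{ProteinStructure}.
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname atomTable
#' @export
setMethod("atomTable", "ProteinStructure", function(x) x@atoms)

#' Per-atom residue identifiers ("chain|resseq|inscode")
#' @param x a \linkS4class{ProteinStructure}.
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))

#' @rdname residueIds
#' @export
setMethod("residueIds", "ProteinStructure", function(x)
  paste(x@atoms$chain, x@atoms$resseq, x@atoms$inscode, sep = "|"))

#' Build a ProteinStructure from an atom table
#'
#' Low-level constructor used by the readers and the fixture generator.
#' @param atoms data.frame with the full atom-column set (see
#'   \linkS4class{ProteinStructure}); missing bookkeeping columns are filled
#'   with defaults.
#' @param label identifier string.
#' @export
proteinStructure <- function(atoms, label = "structure") {
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$inscode)) atoms$inscode <- ""
  if (is.null(atoms$element))
    atoms$element <- toupper(substr(gsub("[0-9 ]", "", atoms$name), 1, 1))
  if (is.null(atoms$aceType)) atoms$aceType <- NA_integer_
  atoms$aceType <- as.integer(atoms$aceType)
  atoms$resseq <- as.integer(atoms$resseq)
  rownames(atoms) <- NULL
  new("ProteinStructure", atoms = atoms, label = label)
}

#' Read a protein subunit from a PDB file
#'
#' Keeps ATOM records of the first MODEL in file order, restricted to the
#' selected chains; HETATM records (waters, ligands) are excluded. For
#' alternate locations the highest-occupancy record is kept (ties broken in
#' favour of altloc "A"). Hydrogens are dropped unless
#' \code{keepHydrogens = TRUE} (the contact-energy statistics are heavy-atom
#' based; the flag exists for I/O fidelity only).
#'
#' @param path PDB file.
#' @param chains optional character vector of chain identifiers.
#' @param keepHydrogens keep H/D atoms.
#' @param label structure label (defaults to the file name).
#' @return A \linkS4class{ProteinStructure}.
#' @export
readPDB <- function(path, chains = NULL, keepHydrogens = FALSE,
                    label = basename(path)) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # truncate to the first MODEL so downstream parsing sees one model only
  if (any(startsWith(lines, "MODEL"))) {
    endm <- which(startsWith(lines, "ENDMDL"))
    if (length(endm)) lines <- lines[seq_len(endm[1])]
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- tryCatch(bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("malformed PDB file: ", path,
                                           " (", conditionMessage(e), ")"))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records after chain selection in ", path)
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- toupper(substr(gsub("[0-9 ]", "", a$elety), 1, 1))
  elem[is.na(elem) | elem == ""] <-
    toupper(substr(gsub("[0-9 ]", "", a$elety[is.na(elem) | elem == ""]), 1, 1))
  a$element <- toupper(trimws(elem))
  if (!keepHydrogens) a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms left after hydrogen removal in ", path)
  # altloc: keep highest occupancy per (chain, resseq, inscode, atom name)
  if (any(a$alt != "")) {
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
    ord <- order(match(key, unique(key)), -a$o,
                 ifelse(a$alt == "", 0L, match(a$alt, LETTERS)))
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety, sep = "|")), ,
           drop = FALSE]
    a <- a[order(match(rownames(a), rownames(pdb$atom))), , drop = FALSE]
  }
  xyz <- suppressWarnings(cbind(as.numeric(a$x), as.numeric(a$y),
                                as.numeric(a$z)))
  if (any(!is.finite(xyz)))
    stop("malformed coordinate fields in ", path)
  proteinStructure(data.frame(serial = a$eleno, name = a$elety,
                              element = a$element, resname = a$resid,
                              resseq = a$resno, inscode = a$insert,
                              chain = a$chain,
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              aceType = NA_integer_,
                              stringsAsFactors = FALSE),
                   label = label)
}

#' Write a structure to a PDB file
#'
#' Round-trips through \code{\link{readPDB}} to within PDB coordinate
#' precision (1e-3 Angstrom) with residue and chain identity preserved.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param path output file.
#' @param transform optional \linkS4class{RigidTransform} applied on write.
#' @export
writePDB <- function(structure, path, transform = NULL) {
  stopifnot(is(structure, "ProteinStructure"))
  if (nAtoms(structure) == 0L) stop("refusing to write an empty structure")
  xyz <- atomCoords(structure)
  if (!is.null(transform)) xyz <- applyTransform(xyz, transform)
  a <- structure@atoms
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                     resno = a$resseq, resid = a$resname, eleno = a$serial,
                     elety = a$name, chain = a$chain, insert = a$inscode,
                     o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                     elesy = a$element)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("could not write PDB file: ", path)
  invisible(path)
}

#' Write the posed complex as a two-chain PDB file
#'
#' Subunit A is written transformed, subunit B as-is; atoms are renumbered
#' serially.
#' @export
writeComplexPDB <- function(A, B, transform, path) {
  xyzA <- applyTransform(atomCoords(A), transform)
  aA <- A@atoms; aA$x <- xyzA[, 1]; aA$y <- xyzA[, 2]; aA$z <- xyzA[, 3]
  ab <- rbind(aA, B@atoms)
  ab$serial <- seq_len(nrow(ab))
  writePDB(proteinStructure(ab, label = "complex"), path)
}
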