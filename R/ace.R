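# Atomic Contact Energy: the pairwise contact-energy definition, the 18x18
# table with its typing map, atom typing, contact search and the ACE score.

#' Effective contact energy of one atom-type pair
#'
#' \deqn{T_{ij} = -\ln\frac{N_{ij}/C_{ij}}{(N_{i0}/C_{i0})(N_{j0}/C_{j0})}}
#' where type 0 is the solvent, \eqn{N} are observed contact counts and
#' \eqn{C} the expected counts. Symmetric under exchange of the i- and
#' j-labelled argument blocks; decreases as \eqn{N_{ij}} grows (more
#' observed contacts, more favourable).
#'
#' @param Nij,Cij observed/expected i-j contacts (positive).
#' @param Ni0,Ci0 observed/expected i-solvent contacts (positive).
#' @param Nj0,Cj0 observed/expected j-solvent contacts (positive).
#' @return Contact energy (dimensionless log-likelihood units).
#' @export
contactEnergy <- function(Nij, Cij, Ni0, Ci0, Nj0, Cj0) {
  counts <- c(Nij = Nij, Cij = Cij, Ni0 = Ni0, Ci0 = Ci0, Nj0 = Nj0, Cj0 = Cj0)
  bad <- !is.finite(counts) | counts <= 0
  if (any(bad))
    stop("counts must be strictly positive; offending: ",
         paste(names(counts)[bad], collapse = ", "))
  -log((Nij / Cij) / ((Ni0 / Ci0) * (Nj0 / Cj0)))
}

#' Build an ACE table from raw contact counts
#'
#' @param Nij,Cij 18x18 symmetric matrices of observed/expected pair counts.
#' @param N0,C0 length-18 vectors of observed/expected solvent contacts.
#' @param typeNames character(18).
#' @param typingMap optional data.frame (resname, atom, type).
#' @return An \linkS4class{AceTable} with \code{energies[i, j] ==
#'   contactEnergy(Nij[i,j], Cij[i,j], N0[i], C0[i], N0[j], C0[j])}.
#' @export
buildAceTable <- function(Nij, Cij, N0, C0,
                          typeNames = sprintf("T%02d", 0:17),
                          typingMap = emptyTypingMap()) {
  stopifnot(all(dim(Nij) == c(18, 18)), all(dim(Cij) == c(18, 18)),
            length(N0) == 18, length(C0) == 18)
  if (max(abs(Nij - t(Nij))) > 1e-9 || max(abs(Cij - t(Cij))) > 1e-9)
    stop("pair-count matrices must be symmetric")
  E <- matrix(0, 18, 18)
  for (i in 1:18) for (j in i:18) {
    E[i, j] <- contactEnergy(Nij[i, j], Cij[i, j], N0[i], C0[i], N0[j], C0[j])
    E[j, i] <- E[i, j]
  }
  new("AceTable", energies = E, typeNames = typeNames, typingMap = typingMap)
}

emptyTypingMap <- function()
  data.frame(resname = character(), atom = character(), type = integer(),
             stringsAsFactors = FALSE)

#' Construct an ACE table directly from an energy matrix
#' @param energies 18x18 symmetric matrix.
#' @param typeNames character(18).
#' @param typingMap data.frame (resname, atom, type).
#' @export
aceTable <- function(energies, typeNames = sprintf("T%02d", 0:17),
                     typingMap = emptyTypingMap()) {
  new("AceTable", energies = energies, typeNames = typeNames,
      typingMap = typingMap)
}

#' Contact-energy matrix of a table
#' @param x an \linkS4class{AceTable}.
#' @export
setGeneric("aceEnergies", function(x) standardGeneric("aceEnergies"))

#' @rdname aceEnergies
#' @export
setMethod("aceEnergies", "AceTable", function(x) x@energies)

#' Load an ACE table file
#'
#' Plain-text format with three sections: \code{[types]} (18 names, one per
#' line), \code{[energies]} (\code{i j value} triplets, 0-based upper
#' triangle; symmetric completion on load), \code{[typing]}
#' (\code{resname atom type} lines). Lines starting with \code{#} are
#' comments. \code{saveAceTable}/\code{loadAceTable} round-trip exactly.
#'
#' @param path table file; defaults to the synthetic table shipped with the
#'   package (the published parameterisation is replaced by a synthetic
#'   stand-in; see the package vignette).
#' @export
loadAceTable <- function(path = system.file("extdata",
                                            "ace_table_synthetic.tsv",
                                            package = "aceDock")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  sec <- cumsum(grepl("^\\[", lines))
  headers <- lines[grepl("^\\[", lines)]
  blocks <- split(lines[!grepl("^\\[", lines)],
                  factor(headers[sec[!grepl("^\\[", lines)]], levels = headers))
  if (!all(c("[types]", "[energies]") %in% headers))
    stop("table file needs [types] and [energies] sections")
  typeNames <- blocks[["[types]"]]
  if (length(typeNames) != 18) stop("expected 18 type names")
  E <- matrix(NA_real_, 18, 18)
  for (ln in blocks[["[energies]"]]) {
    f <- strsplit(ln, "[ \t]+")[[1]]
    i <- as.integer(f[1]) + 1L; j <- as.integer(f[2]) + 1L
    v <- as.numeric(f[3])
    if (!is.na(E[i, j]) && abs(E[i, j] - v) > 1e-12)
      stop("asymmetric duplicate entry for pair ", i - 1L, " ", j - 1L)
    E[i, j] <- v; E[j, i] <- v
  }
  if (any(is.na(E))) stop("missing energy entries for some type pairs")
  tm <- emptyTypingMap()
  if ("[typing]" %in% headers && length(blocks[["[typing]"]])) {
    f <- strsplit(blocks[["[typing]"]], "[ \t]+")
    tm <- data.frame(resname = vapply(f, `[`, "", 1),
                     atom = vapply(f, `[`, "", 2),
                     type = as.integer(vapply(f, `[`, "", 3)),
                     stringsAsFactors = FALSE)
  }
  aceTable(E, typeNames, tm)
}

#' @rdname loadAceTable
#' @param table an \linkS4class{AceTable}.
#' @export
saveAceTable <- function(table, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("[types]", con)
  writeLines(table@typeNames, con)
  writeLines("[energies]", con)
  for (i in 1:18) for (j in i:18)
    writeLines(sprintf("%d %d %.17g", i - 1L, j - 1L, table@energies[i, j]), con)
  if (nrow(table@typingMap)) {
    writeLines("[typing]", con)
    writeLines(sprintf("%s %s %d", table@typingMap$resname,
                       table@typingMap$atom, table@typingMap$type), con)
  }
  invisible(path)
}

#' Assign ACE atom types from a table's typing map
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param table an \linkS4class{AceTable}.
#' @param unknownPolicy "skip" leaves atoms absent from the map untyped
#'   (excluded from scoring); "error" fails on the first unknown atom.
#' @export
assignAceTypes <- function(structure, table, unknownPolicy = c("skip", "error")) {
  unknownPolicy <- match.arg(unknownPolicy)
  tm <- table@typingMap
  key <- paste(structure@atoms$resname, trimws(structure@atoms$name))
  hit <- match(key, paste(tm$resname, tm$atom))
  if (unknownPolicy == "error" && anyNA(hit))
    stop("atoms without a type mapping: ",
         paste(unique(key[is.na(hit)]), collapse = ", "))
  structure@atoms$aceType <- as.integer(tm$type[hit])
  structure
}

#' Cross-subunit atom contacts within a cutoff
#'
#' Exactly the cross pairs (one atom from each set) with Euclidean distance
#' \code{<= cutoff} (inclusive), via a cell-list search that agrees exactly
#' with the all-pairs double loop.
#'
#' @param S1,S2 coordinate matrices (n x 3) or
#'   \linkS4class{ProteinStructure}s.
#' @param cutoff Angstrom.
#' @return data.frame with columns \code{i}, \code{j} (row indices into S1,
#'   S2) and \code{dist}, ordered by (i, j).
#' @export
findContacts <- function(S1, S2, cutoff) {
  stopifnot(cutoff > 0)
  c1 <- if (is(S1, "ProteinStructure")) atomCoords(S1) else S1
  c2 <- if (is(S2, "ProteinStructure")) atomCoords(S2) else S2
  if (nrow(c1) == 0L || nrow(c2) == 0L)
    return(data.frame(i = integer(), j = integer(), dist = numeric()))
  r <- cpp_contacts(c1, c2, cutoff)
  data.frame(i = r$i, j = r$j, dist = r$dist)
}

#' ACE score of a configuration
#'
#' Sum of table energies over all cross-subunit atom pairs within distance
#' \code{d} (each unordered cross pair counted once). Untyped atoms
#' contribute nothing. Symmetric in its two atom sets and invariant under
#' any joint rigid motion.
#'
#' @param S1,S2 typed \linkS4class{ProteinStructure}s, or coordinate
#'   matrices (then \code{types1}/\code{types2} must be given, 0-based,
#'   NA = untyped).
#' @param table an \linkS4class{AceTable}.
#' @param d contact cutoff in Angstrom (default 6).
#' @param types1,types2 types when coordinates are passed directly.
#' @export
aceScore <- function(S1, S2, table, d = 6, types1 = NULL, types2 = NULL) {
  if (is(S1, "ProteinStructure")) { types1 <- atomTypes(S1); S1 <- atomCoords(S1) }
  if (is(S2, "ProteinStructure")) { types2 <- atomTypes(S2); S2 <- atomCoords(S2) }
  if (nrow(S1) == 0L || nrow(S2) == 0L) return(0)
  t1 <- as.integer(ifelse(is.na(types1), -1L, types1))
  t2 <- as.integer(ifelse(is.na(types2), -1L, types2))
  cpp_ace_score(S1, t1, S2, t2, table@energies, d)
}
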