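# Grid-based surface labeling and the shared-interior clash test.
#
# Lattice anchoring: origin = componentwise floor(min coordinate) - margin,
# margin = proteinPointRadius + gridSpacing, so (at the default 1 A spacing)
# lattice points sit on integer coordinates regardless of the structure and
# no protein point can touch the box face (out-of-box neighbours count as
# empty).

gridBox <- function(coords, params) {
  margin <- params@proteinPointRadius + params@gridSpacing
  origin <- floor(apply(coords, 2, min)) - margin
  top <- ceiling(apply(coords, 2, max)) + margin
  dims <- as.integer(ceiling((top - origin) / params@gridSpacing)) + 1L
  list(origin = as.numeric(origin), dims = dims)
}

#' Label the lattice around an atom set
#'
#' A lattice point is a protein point iff it lies within
#' \code{proteinPointRadius} (inclusive) of any atom; a protein point is
#' interior iff all six axis neighbours are protein points, otherwise
#' surface; all other points are empty.
#'
#' @param atoms coordinate matrix (n x 3) or \linkS4class{ProteinStructure}.
#' @param params a \linkS4class{ScoringParams}.
#' @return A \linkS4class{LabeledGrid}.
#' @export
buildLabeledGrid <- function(atoms, params = new("ScoringParams")) {
  coords <- if (is(atoms, "ProteinStructure")) atomCoords(atoms) else atoms
  stopifnot(nrow(coords) >= 1)
  box <- gridBox(coords, params)
  labels <- cpp_label_grid(coords, box$origin, box$dims, params@gridSpacing,
                           params@proteinPointRadius)
  new("LabeledGrid", origin = box$origin, spacing = params@gridSpacing,
      dims = box$dims, labels = labels)
}

#' Lattice coordinates of the points carrying a given label
#' @param grid a \linkS4class{LabeledGrid}.
#' @param label 0 empty, 1 surface, 2 interior.
#' @export
gridPoints <- function(grid, label) {
  idx <- which(grid@labels == label) - 1L
  nz <- grid@dims[3]; ny <- grid@dims[2]
  k <- idx %% nz; j <- (idx %/% nz) %% ny; i <- idx %/% (nz * ny)
  cbind(grid@origin[1] + grid@spacing * i,
        grid@origin[2] + grid@spacing * j,
        grid@origin[3] + grid@spacing * k)
}

#' Surface/interior labels for the atoms of a structure
#'
#' An atom is a surface atom iff it lies within \code{surfaceAtomRadius}
#' (inclusive) of some surface lattice point, otherwise interior.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param grid the \linkS4class{LabeledGrid} built from this structure
#'   (rebuilt when omitted).
#' @param params a \linkS4class{ScoringParams}.
#' @return Character vector, one of "surface"/"interior" per atom.
#' @export
surfaceAtoms <- function(structure, grid = NULL, params = new("ScoringParams")) {
  coords <- atomCoords(structure)
  if (is.null(grid)) grid <- buildLabeledGrid(coords, params)
  box <- gridBox(coords, params)
  if (any(abs(box$origin - grid@origin) > 1e-9) || any(box$dims != grid@dims))
    stop("grid was not built from this structure (bounding box mismatch)")
  sp <- gridPoints(grid, 1L)
  hits <- findContacts(coords, sp, params@surfaceAtomRadius)
  ifelse(seq_len(nrow(coords)) %in% hits$i, "surface", "interior")
}

#' Clash test for a posed pair of subunits
#'
#' One shared lattice covers both atom sets; each subunit's
#' interior/surface/empty labels are computed on it independently (as if the
#' partner were absent). With X the number of interior points shared by
#' both subunits and XA, XB the subunits' interior counts, the pose clashes
#' iff \code{X > theta * min(XA, XB)}. Symmetric in (A, B).
#'
#' @param A,B coordinate matrices or \linkS4class{ProteinStructure}s (A in
#'   its posed coordinates).
#' @param params a \linkS4class{ScoringParams} (supplies theta, spacing,
#'   protein radius).
#' @return A \linkS4class{ClashReport}.
#' @export
clashCheck <- function(A, B, params = new("ScoringParams")) {
  cA <- if (is(A, "ProteinStructure")) atomCoords(A) else A
  cB <- if (is(B, "ProteinStructure")) atomCoords(B) else B
  stopifnot(nrow(cA) >= 1, nrow(cB) >= 1)
  box <- gridBox(rbind(cA, cB), params)
  lA <- cpp_label_grid(cA, box$origin, box$dims, params@gridSpacing,
                       params@proteinPointRadius)
  lB <- cpp_label_grid(cB, box$origin, box$dims, params@gridSpacing,
                       params@proteinPointRadius)
  XA <- sum(lA == 2L); XB <- sum(lB == 2L)
  X <- sum(lA == 2L & lB == 2L)
  new("ClashReport", X = as.integer(X), XA = as.integer(XA),
      XB = as.integer(XB), theta = params@clashTheta,
      clash = X > params@clashTheta * min(XA, XB))
}
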