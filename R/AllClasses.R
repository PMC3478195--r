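#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib aceDock, .registration = TRUE
NULL

# ---- ProteinStructure ---------------------------------------------------

#' Ordered atom sequence of one protein subunit
#'
#' The atom table preserves file order (restricted to selected chains); each
#' atom belongs to exactly one residue, identified by the
#' (chain, residue number, insertion code) triple. Coordinates are in
#' Angstrom. \code{aceType} holds the 0..17 ACE atom-type index, or
#' \code{NA} for untyped atoms (which never contribute to scoring).
#'
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resname}, \code{resseq}, \code{inscode},
#'   \code{chain}, \code{x}, \code{y}, \code{z}, \code{aceType}.
#' @slot label free-text identifier.
#' @export
setClass("ProteinStructure",
         representation(atoms = "data.frame", label = "character"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resseq", "inscode",
            "chain", "x", "y", "z", "aceType")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 1L) return("structure must contain at least one atom")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("atom coordinates must be finite")
  ty <- a$aceType[!is.na(a$aceType)]
  if (length(ty) && (any(ty < 0L) || any(ty > 17L)))
    return("aceType must be in 0..17 or NA")
  TRUE
})

# ---- RigidTransform -----------------------------------------------------

#' Proper rigid transform (rotation + translation)
#'
#' Acts on coordinates as \code{x' = R x + t}. The rotation must be
#' orthonormal with determinant +1 (within 1e-9).
#'
#' @slot rotation 3x3 matrix.
#' @slot translation numeric(3), Angstrom.
#' @export
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation is not orthonormal within 1e-9")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation must be proper (det +1 within 1e-9)")
  TRUE
})

# ---- AceTable -----------------------------------------------------------

#' Atomic Contact Energy parameterisation
#'
#' An 18x18 symmetric matrix of contact energies plus the
#' (residue name, atom name) to type-index map. Raw contact counts, when
#' present, allow the table to be rebuilt with \code{\link{contactEnergy}}.
#'
#' @slot energies 18x18 symmetric numeric matrix.
#' @slot typeNames character(18).
#' @slot typingMap data.frame with columns \code{resname}, \code{atom},
#'   \code{type} (0-based).
#' @export
setClass("AceTable",
         representation(energies = "matrix", typeNames = "character",
                        typingMap = "data.frame"))

setValidity("AceTable", function(object) {
  E <- object@energies
  if (!all(dim(E) == c(18L, 18L))) return("energies must be 18x18")
  if (max(abs(E - t(E))) > 1e-9) return("energies must be symmetric")
  if (length(object@typeNames) != 18L) return("need 18 type names")
  tm <- object@typingMap
  if (nrow(tm) && !all(c("resname", "atom", "type") %in% names(tm)))
    return("typingMap needs columns resname, atom, type")
  if (nrow(tm) && (any(tm$type < 0L) || any(tm$type > 17L)))
    return("typingMap types must be in 0..17")
  TRUE
})

# ---- ScoringParams ------------------------------------------------------

#' Tunable parameters of the docking pipeline
#'
#' Defaults are the published operating point: contact cutoff d = 6 A,
#' interface cutoff 4.5 A, fragment ACE threshold 400, gap penalty 1,
#' alignment score cap x = 0, window of 15 alignment columns with at least
#' 10 surface atoms per side, d-ball/cap step epsilon = 0.1 (grid pitch
#' epsilon * d), 1 degree axis rotations, clash threshold theta = 0.17,
#' 1 A lattice with 2 A protein radius and 1.5 A atom-labeling radius,
#' vdW margin 1 A for the actual interface, top 10 reported poses.
#'
#' @export
setClass("ScoringParams",
         representation(contactCutoff = "numeric", interfaceCutoff = "numeric",
                        fragmentAceThreshold = "numeric", gapPenalty = "numeric",
                        scoreCap = "numeric", windowLength = "integer",
                        windowSurfaceMin = "integer", epsilon = "numeric",
                        rotationStep = "numeric", clashTheta = "numeric",
                        gridSpacing = "numeric", proteinPointRadius = "numeric",
                        surfaceAtomRadius = "numeric", vdwMargin = "numeric",
                        topNPoses = "integer"),
         prototype(contactCutoff = 6, interfaceCutoff = 4.5,
                   fragmentAceThreshold = 400, gapPenalty = 1,
                   scoreCap = 0, windowLength = 15L, windowSurfaceMin = 10L,
                   epsilon = 0.1, rotationStep = 1, clashTheta = 0.17,
                   gridSpacing = 1, proteinPointRadius = 2,
                   surfaceAtomRadius = 1.5, vdwMargin = 1, topNPoses = 10L))

setValidity("ScoringParams", function(object) {
  pos <- c(contactCutoff = object@contactCutoff,
           interfaceCutoff = object@interfaceCutoff,
           gapPenalty = object@gapPenalty,
           windowLength = object@windowLength,
           windowSurfaceMin = object@windowSurfaceMin,
           gridSpacing = object@gridSpacing,
           proteinPointRadius = object@proteinPointRadius,
           surfaceAtomRadius = object@surfaceAtomRadius,
           topNPoses = object@topNPoses)
  if (any(pos <= 0)) return(paste("must be > 0:",
                                  paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@epsilon <= 0 || object@epsilon > 1)
    return("epsilon must be in (0, 1]")
  if (object@clashTheta < 0 || object@clashTheta >= 1)
    return("clashTheta must be in [0, 1)")
  if (object@rotationStep <= 0 || abs(360 / object@rotationStep -
                                      round(360 / object@rotationStep)) > 1e-9)
    return("rotationStep must divide 360")
  TRUE
})

# ---- LabeledGrid --------------------------------------------------------

#' Axis-aligned labelled lattice around a structure
#'
#' Per-point label: 0 = empty, 1 = surface, 2 = interior. Lattice point
#' (i, j, k) (0-based) sits at \code{origin + spacing * c(i, j, k)}.
#'
#' @slot origin numeric(3).
#' @slot spacing numeric(1), Angstrom.
#' @slot dims integer(3).
#' @slot labels integer vector of length prod(dims), index order
#'   \code{(i * dims[2] + j) * dims[3] + k + 1}.
#' @export
setClass("LabeledGrid",
         representation(origin = "numeric", spacing = "numeric",
                        dims = "integer", labels = "integer"))

setValidity("LabeledGrid", function(object) {
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be 3 positive integers")
  if (length(object@labels) != prod(object@dims))
    return("labels length must equal prod(dims)")
  if (!all(object@labels %in% 0:2)) return("labels must be 0, 1 or 2")
  TRUE
})

# ---- ClashReport --------------------------------------------------------

#' Result of the shared-interior-point clash test
#' @slot X shared interior lattice points.
#' @slot XA,XB interior points of each subunit on the shared lattice.
#' @slot theta threshold used.
#' @slot clash TRUE iff X > theta * min(XA, XB).
#' @export
setClass("ClashReport",
         representation(X = "integer", XA = "integer", XB = "integer",
                        theta = "numeric", clash = "logical"))

setValidity("ClashReport", function(object) {
  if (object@X > min(object@XA, object@XB)) return("X must be <= min(XA, XB)")
  want <- object@X > object@theta * min(object@XA, object@XB)
  if (!identical(as.logical(want), object@clash))
    return("clash flag inconsistent with X > theta * min(XA, XB)")
  TRUE
})

# ---- alignment / fragments ---------------------------------------------

#' Local aligned segment of the two atom sequences
#'
#' Columns pair an A index (or 0 for a gap) with a B index (or 0); indices
#' are strictly increasing within each sequence. The stored score equals the
#' column-wise sum: matched columns contribute the table entry for the two
#' atom types, gap columns the gap penalty.
#' @export
setClass("AlignedSegment",
         representation(columns = "matrix", score = "numeric",
                        spanA = "integer", spanB = "integer"))

setValidity("AlignedSegment", function(object) {
  cm <- object@columns
  if (ncol(cm) != 2L) return("columns must have two columns")
  ia <- cm[, 1][cm[, 1] > 0]; ib <- cm[, 2][cm[, 2] > 0]
  if (length(ia) && any(diff(ia) <= 0)) return("A indices must increase")
  if (length(ib) && any(diff(ib) <= 0)) return("B indices must increase")
  TRUE
})

#' Candidate fragment pair surviving the surface window filter
#' @export
setClass("FragmentPair",
         representation(atomsA = "integer", atomsB = "integer",
                        surfaceA = "integer", surfaceB = "integer"))

setValidity("FragmentPair", function(object) {
  if (length(object@atomsA) < 2L || length(object@atomsB) < 2L)
    return("fragments need at least two atoms (distinct anchor endpoints)")
  TRUE
})

#' Two anchor interaction pairs (a_i, b_i') and (a_j, b_j')
#' @export
setClass("AnchorPair",
         representation(ai = "integer", aj = "integer",
                        bi = "integer", bj = "integer"))

setValidity("AnchorPair", function(object) {
  if (object@ai == object@aj) return("anchor atoms on A must be distinct")
  TRUE
})

# ---- poses / results ----------------------------------------------------

#' One rigid configuration of subunit A against fixed B
#' @slot transform the rigid transform applied to A.
#' @slot ace ACE score (NA when clashing).
#' @slot clash logical.
#' @slot anchors AnchorPair used.
#' @slot gridIndex integer(3): (d-ball point, cap point, rotation) indices.
#' @export
setClass("Pose",
         representation(transform = "RigidTransform", ace = "numeric",
                        clash = "logical", anchors = "AnchorPair",
                        gridIndex = "integer"))

#' Predicted interface as a set of cross-subunit residue pairs
#'
#' Residue identifiers are "chain|resseq|inscode" strings; the per-subunit
#' sets are exactly the projections of the pair set.
#' @export
setClass("InterfaceSet",
         representation(pairs = "data.frame",
                        residuesA = "character", residuesB = "character"))

setValidity("InterfaceSet", function(object) {
  p <- object@pairs
  if (!all(c("resA", "resB") %in% names(p)))
    return("pairs needs columns resA, resB")
  if (!setequal(unique(p$resA), object@residuesA))
    return("residuesA must be the projection of pairs$resA")
  if (!setequal(unique(p$resB), object@residuesB))
    return("residuesB must be the projection of pairs$resB")
  TRUE
})

#' Full result of a docking run
#' @slot status "ok" or "no prediction".
#' @slot poses data.frame of the top-ranked clash-free poses (ascending ACE).
#' @slot bestPose best Pose (only when status == "ok").
#' @slot k number of fragment pairs surviving the ACE-threshold filter.
#' @slot interface predicted InterfaceSet of the best pose.
#' @slot counters named integer vector of per-stage counts.
#' @export
setClass("DockResult",
         representation(status = "character", poses = "data.frame",
                        bestPose = "ANY", k = "integer",
                        interface = "ANY", counters = "numeric"))

#' Toy complex with a planted, analytically known interface
#' @export
setClass("PlantedComplex",
         representation(subunitA = "ProteinStructure",
                        subunitB = "ProteinStructure",
                        nativeTransform = "RigidTransform",
                        plantedInterface = "InterfaceSet",
                        seed = "integer", construction = "list"))

# ---- show methods -------------------------------------------------------

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  cat("ProteinStructure", sQuote(object@label), "\n",
      " ", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resseq, a$inscode))), "residues,",
      "chains:", paste(unique(a$chain), collapse = " "), "\n",
      " typed atoms:", sum(!is.na(a$aceType)), "\n")
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation:", paste(round(object@translation, 4), collapse = " "), "\n")
})

setMethod("show", "AceTable", function(object) {
  cat("AceTable: 18x18 contact energies, range [",
      round(min(object@energies), 3), ",", round(max(object@energies), 3),
      "], typing map:", nrow(object@typingMap), "entries\n")
})

setMethod("show", "LabeledGrid", function(object) {
  tab <- tabulate(object@labels + 1L, 3L)
  cat("LabeledGrid", paste(object@dims, collapse = "x"),
      "at", object@spacing, "A:",
      tab[1], "empty,", tab[2], "surface,", tab[3], "interior\n")
})

setMethod("show", "ClashReport", function(object) {
  cat("ClashReport: X =", object@X, " XA =", object@XA, " XB =", object@XB,
      " theta =", object@theta, " ->", if (object@clash) "CLASH" else "no clash", "\n")
})

setMethod("show", "InterfaceSet", function(object) {
  cat("InterfaceSet:", nrow(object@pairs), "residue pairs (",
      length(object@residuesA), "on A,", length(object@residuesB), "on B )\n")
})

setMethod("show", "DockResult", function(object) {
  cat("DockResult:", object@status, "\n")
  if (object@status == "ok") {
    cat("  k =", object@k, "fragment pairs;",
        nrow(object@poses), "reported poses; best ACE =",
        round(object@poses$ace[1], 4), "\n",
        " predicted interface:", nrow(object@interface@pairs), "residue pairs\n")
  }
  if (length(object@counters))
    cat("  counters:", paste(names(object@counters), object@counters,
                             sep = "=", collapse = " "), "\n")
})

setMethod("show", "PlantedComplex", function(object) {
  cat("PlantedComplex (seed", object@seed, "):",
      nrow(object@subunitA@atoms), "A atoms,",
      nrow(object@subunitB@atoms), "B atoms,",
      nrow(object@plantedInterface@pairs), "planted interface pairs\n")
})
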