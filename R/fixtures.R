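# Seeded generator of toy subunit pairs with a planted, analytically known
# interface, plus decoy poses and toy ACE tables. Pseudo-residues carry four
# atoms (N, CA, C, O naming) so residue-level metrics, C-alpha iRMSD and PDB
# I/O all work without real chemistry.
#
# Canonical construction (before the seeded scene motion):
#  * B: a dense slab of 4-atom rows (background type), a 16-atom "floor" row
#    on top of it at z = 0 whose last 14 atoms carry the favourable B type,
#    and a rim column at x = 27 whose top atom (favourable type) sits at
#    z = pocketDepth, collinear with the patch axis.
#  * A: a 16-atom "patch" row at z = pocketDepth whose first 15 atoms carry
#    the favourable A type, with body rows stacked above.
#  * The planted pose is the stored pose itself (native transform =
#    identity): patch atom 1 sits exactly pocketDepth above floor atom 1
#    (a d-ball lattice vector whenever the grid pitch divides pocketDepth),
#    and the rim anchor lies on the ray through the patch axis, so the
#    native pose is exactly representable as d-ball point + cap pole +
#    0-degree rotation.
# Seeds vary subunit sizes are fixed by the caller; seeds vary the global
# placement (translation + axis-aligned proper rotation, both exact) and
# jitter the non-interface body/slab atoms only.

rowSpacing <- 0.0 + 1.5   # atom pitch along a row, Angstrom

# the 24 proper axis-aligned rotations, as exact signed permutation matrices
properAxisRotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    R <- matrix(0, 3, 3)
    R[1, p[1]] <- s1; R[2, p[2]] <- s2; R[3, p[3]] <- s3
    if (abs(det(R) - 1) < 1e-12) out[[length(out) + 1L]] <- R
  }
  out
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

rowAtoms <- function(x0, n, y, z, spacing = rowSpacing)
  cbind(x0 + spacing * (0:(n - 1)), y, z)

toyStructure <- function(coords, types, chain, label) {
  n <- nrow(coords)
  nres <- ceiling(n / 4)
  resseq <- rep(seq_len(nres), each = 4)[seq_len(n)]
  name <- rep(c("N", "CA", "C", "O"), nres)[seq_len(n)]
  proteinStructure(data.frame(serial = seq_len(n), name = name,
                              element = ifelse(name == "N", "N",
                                               ifelse(name == "O", "O", "C")),
                              resname = "GLY", resseq = resseq, inscode = "",
                              chain = chain,
                              x = coords[, 1], y = coords[, 2], z = coords[, 3],
                              aceType = as.integer(types),
                              stringsAsFactors = FALSE),
                   label = label)
}

#' Toy ACE table
#'
#' A symmetric 18x18 table with \code{background} everywhere except the
#' given favourable type pairs; round-trips through the table file format.
#'
#' @param favorablePairs list of 0-based type index pairs.
#' @param favorable energy of the favourable pairs (must be negative).
#' @param background energy of every other pair (must be positive).
#' @export
makeToyAceTable <- function(favorablePairs = list(c(0, 1)),
                            favorable = -20, background = 1) {
  stopifnot(favorable < 0, background > 0)
  E <- matrix(background, 18, 18)
  for (p in favorablePairs) {
    stopifnot(length(p) == 2, all(p >= 0), all(p <= 17))
    E[p[1] + 1L, p[2] + 1L] <- favorable
    E[p[2] + 1L, p[1] + 1L] <- favorable
  }
  aceTable(E, typingMap = data.frame(resname = "GLY",
                                     atom = c("N", "CA", "C", "O"),
                                     type = 2L, stringsAsFactors = FALSE))
}

#' Generate a toy complex with a planted interface
#'
#' Deterministic for a given seed. The planted pose (the stored coordinates
#' themselves; native transform = identity) is clash-free at theta = 0.17,
#' every planted-interface atom is a surface atom of its subunit, and the
#' favourable patch/floor contacts score strongly negative under the toy
#' table, so the pose survives the fragment ACE threshold. These invariants
#' are verified at construction time.
#'
#' @param seed integer seed.
#' @param nResiduesA residues of subunit A (>= 4; 4 patch residues + body).
#' @param nResiduesB residues of subunit B (>= 25; 4 floor + 1 rim + slab).
#' @param pocketDepth height of the patch above the floor, Angstrom (in
#'   (2, 6]; recovery by the pose search is exact when the d-ball pitch
#'   epsilon * d divides it, e.g. the default 3 with epsilon 0.5, d 6).
#' @param favorableTypes c(typeA, typeB): ACE types of the patch and
#'   floor/rim atoms; everything else carries the background type 2.
#' @param jitter amplitude of the uniform jitter on body/slab atoms.
#' @return A \linkS4class{PlantedComplex}.
#' @export
makePlantedComplex <- function(seed = 1L, nResiduesA = 8L, nResiduesB = 45L,
                               pocketDepth = 3, favorableTypes = c(1L, 0L),
                               jitter = 0.2) {
  stopifnot(nResiduesA >= 4L)
  if (nResiduesB < 25L)
    stop("subunit B too small for the pocket construction (need >= 25 residues)")
  if (pocketDepth <= 2 || pocketDepth > 6)
    stop("infeasible geometry: pocketDepth must be in (2, 6]")
  tA <- as.integer(favorableTypes[1]); tB <- as.integer(favorableTypes[2])
  bg <- 2L
  sp <- rowSpacing

  # ---- subunit A: patch row + body rows --------------------------------
  patch <- rowAtoms(0, 16, 0, pocketDepth)
  patchTypes <- c(rep(tA, 15), bg)
  nBody <- 4L * nResiduesA - 16L
  body <- NULL
  if (nBody > 0) {
    zs <- pocketDepth + 1.5 * (1:ceiling(nBody / 16))
    body <- do.call(rbind, lapply(zs, function(z) rowAtoms(0, 16, 0, z)))
    body <- body[seq_len(nBody), , drop = FALSE]
  }
  coordsA <- rbind(patch, body)
  typesA <- c(patchTypes, rep(bg, nBody))

  # ---- subunit B: slab + floor row + rim column ------------------------
  nSlab <- nResiduesB - 5L
  slabPos <- list()
  for (z in seq(-1.5, by = -1.5, length.out = 50))
    for (y in c(0, -1.5, 1.5, -3, 3))
      for (x0 in c(-3, 3, 9, 15))
        slabPos[[length(slabPos) + 1L]] <- c(x0, y, z)
  slab <- do.call(rbind, lapply(slabPos[seq_len(nSlab)], function(p)
    rowAtoms(p[1], 4, p[2], p[3])))
  floorRow <- rowAtoms(-3, 16, 0, 0)
  floorTypes <- c(bg, bg, rep(tB, 14))
  rim <- cbind(27, 0, pocketDepth - 1.5 * (0:3))
  rimTypes <- c(tB, bg, bg, bg)
  coordsB <- rbind(slab, floorRow, rim)
  typesB <- c(rep(bg, nrow(slab)), floorTypes, rimTypes)
  nSlabAtoms <- nrow(slab)

  # ---- seeded scene motion + body/slab jitter --------------------------
  scene <- withSeed(seed, {
    rot <- properAxisRotations()[[sample.int(24, 1)]]
    # whole-Angstrom scene shifts keep the canonical geometry's phase on the
    # 1 A labeling lattice, so the planted surface/clash analysis holds for
    # every seed
    shift <- as.numeric(sample(-15:15, 3, replace = TRUE))
    jA <- matrix(runif(3 * nrow(coordsA), -jitter, jitter), ncol = 3)
    jB <- matrix(runif(3 * nrow(coordsB), -jitter, jitter), ncol = 3)
    list(rot = rot, shift = shift, jA = jA, jB = jB)
  })
  jA <- scene$jA; jA[1:16, ] <- 0                      # patch row exact
  jB <- scene$jB
  jB[nSlabAtoms + seq_len(20), ] <- 0                  # floor + rim exact
  place <- function(coords, j)
    (coords + j) %*% t(scene$rot) +
      matrix(scene$shift, nrow(coords), 3, byrow = TRUE)
  A <- toyStructure(place(coordsA, jA), typesA, "A", sprintf("toyA_seed%d", seed))
  B <- toyStructure(place(coordsB, jB), typesB, "B", sprintf("toyB_seed%d", seed))

  table <- makeToyAceTable(list(c(tA, tB)))
  native <- identityTransform()
  planted <- predictedInterface(A, B)

  # ---- construction-time invariant checks ------------------------------
  params <- new("ScoringParams")
  cr <- clashCheck(A, B, params)
  if (cr@clash) stop("construction failed: planted pose clashes")
  runA <- 1:15
  runB <- nSlabAtoms + c(3:16, 17L)
  surfA <- surfaceAtoms(A, params = params)
  surfB <- surfaceAtoms(B, params = params)
  if (!all(surfA[runA] == "surface") || !all(surfB[runB] == "surface"))
    stop("construction failed: planted interface atoms are not all surface")
  fragAce <- aceScore(atomCoords(A)[runA, ], atomCoords(B)[runB, ], table,
                      d = params@contactCutoff,
                      types1 = typesA[runA], types2 = typesB[runB])
  if (fragAce >= 0)
    stop("construction failed: planted fragment ACE is not negative")

  new("PlantedComplex", subunitA = A, subunitB = B,
      nativeTransform = native, plantedInterface = planted,
      seed = as.integer(seed),
      construction = list(table = table, runA = runA, runB = runB,
                          anchors = new("AnchorPair",
                                        ai = 1L, aj = 15L,
                                        bi = as.integer(nSlabAtoms + 3L),
                                        bj = as.integer(nSlabAtoms + 17L)),
                          pocketDepth = pocketDepth,
                          favorableTypes = c(tA, tB),
                          fragmentAce = fragAce,
                          scene = scene[c("rot", "shift")]))
}

#' Perturbed (decoy) pose of a planted complex
#'
#' Perturbs the native transform by a rotation of \code{rotationMag}
#' degrees about a random axis through the centroid of A followed by a
#' translation of \code{translationMag} Angstrom in a random direction.
#' Magnitude 0 returns the native pose.
#'
#' @param complex a \linkS4class{PlantedComplex}.
#' @param seed integer seed for the random direction/axis.
#' @param translationMag,rotationMag perturbation magnitudes (>= 0).
#' @return A \linkS4class{Pose} (ACE under the complex's toy table, clash
#'   status at the default parameters).
#' @export
makeDecoyPose <- function(complex, seed = 1L, translationMag = 0,
                          rotationMag = 0) {
  stopifnot(translationMag >= 0, rotationMag >= 0)
  dirs <- withSeed(seed, {
    d <- stats::rnorm(3); a <- stats::rnorm(3)
    list(d = d / sqrt(sum(d^2)), a = a / sqrt(sum(a^2)))
  })
  A <- complex@subunitA
  centroid <- colMeans(atomCoords(A))
  pert <- composeTransforms(
    rigidTransform(diag(3), translationMag * dirs$d),
    rotationAboutAxis(dirs$a, rotationMag, centroid))
  tr <- composeTransforms(pert, complex@nativeTransform)
  params <- new("ScoringParams")
  Ap <- applyTransform(A, tr)
  cr <- clashCheck(Ap, complex@subunitB, params)
  ace <- aceScore(Ap, complex@subunitB, complex@construction$table,
                  d = params@contactCutoff)
  new("Pose", transform = tr, ace = ace, clash = cr@clash,
      anchors = complex@construction$anchors,
      gridIndex = c(NA_integer_, NA_integer_, NA_integer_))
}

#' Write a planted complex to disk
#'
#' Writes \code{A.pdb}, \code{B.pdb}, the native complex and a JSON sidecar
#' recording the seed, native transform and planted interface.
#'
#' @param complex a \linkS4class{PlantedComplex}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeFixtureFiles <- function(complex, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePDB(complex@subunitA, file.path(dir, "A.pdb"))
  writePDB(complex@subunitB, file.path(dir, "B.pdb"))
  writeComplexPDB(complex@subunitA, complex@subunitB,
                  complex@nativeTransform, file.path(dir, "native_complex.pdb"))
  saveAceTable(complex@construction$table, file.path(dir, "toy_ace_table.tsv"))
  jsonlite::write_json(
    list(seed = complex@seed,
         native_rotation = complex@nativeTransform@rotation,
         native_translation = complex@nativeTransform@translation,
         planted_interface = complex@plantedInterface@pairs),
    file.path(dir, "fixture.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
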