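# Stages 2-3: enumeration of rigid configurations from anchor interaction
# pairs (d-ball lattice for a_i, sphere cap for a_j, axis rotations for the
# remaining degree of freedom), fragment-pair filtering at the ACE threshold,
# and the full docking pipeline.

#' Lattice points of a d-ball
#'
#' Axis-aligned lattice of pitch \code{step} anchored at \code{center},
#' restricted to points within \code{d} of the center (inclusive). Contains
#' the center; deterministic lexicographic order of the lattice index.
#'
#' @param center numeric(3).
#' @param d ball radius, Angstrom.
#' @param step lattice pitch, Angstrom (0 < step <= 2d).
#' @export
dballGrid <- function(center, d, step) {
  stopifnot(step > 0, step <= 2 * d)
  kmax <- floor(d / step + 1e-9)
  k <- -kmax:kmax
  g <- as.matrix(expand.grid(kz = k, ky = k, kx = k))[, 3:1, drop = FALSE]
  pts <- g * step
  keep <- rowSums(pts^2) <= d^2 + 1e-9
  sweep(pts[keep, , drop = FALSE], 2, center, "+")
}

#' Lattice points on a sphere cap
#'
#' Points on the sphere of radius \code{r} about \code{p} that lie within
#' \code{d} of \code{c} (inclusive) -- the candidate positions for the
#' second anchor atom. The cap is discretised with polar axis p -> c and
#' polar/azimuthal steps of arc length about \code{step}; the cap pole (the
#' sphere point nearest to \code{c}) is always included when the cap is
#' non-empty. Empty iff the sphere and the ball are disjoint
#' (|p - c| > r + d or |p - c| < r - d). Deterministic order: increasing
#' polar ring, then azimuth.
#'
#' @param p sphere center.
#' @param r sphere radius.
#' @param c ball center.
#' @param d ball radius.
#' @param step target arc length between neighbours, Angstrom.
#' @export
sphereCapGrid <- function(p, r, c, d, step) {
  stopifnot(r > 0, step > 0)
  v <- c - p
  D <- sqrt(sum(v^2))
  if (D > r + d + 1e-9 || D < r - d - 1e-9)
    return(matrix(numeric(), 0, 3))
  if (D < 1e-9) {            # ball concentric with the sphere: full sphere
    u <- c(0, 0, 1)
    psiMax <- pi
  } else {
    u <- v / D
    cosMin <- (r^2 + D^2 - d^2) / (2 * r * D)
    psiMax <- acos(min(1, max(-1, cosMin)))
  }
  # deterministic azimuthal frame
  e1 <- vcross(u, c(1, 0, 0))
  if (sum(e1^2) < 1e-18) e1 <- vcross(u, c(0, 1, 0))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- vcross(u, e1)
  if (psiMax < 1e-12) {
    return(matrix(p + r * u, 1, 3, byrow = TRUE))
  }
  nPolar <- max(1L, ceiling(r * psiMax / step))
  pts <- list()
  for (k in 0:nPolar) {
    psi <- psiMax * k / nPolar
    rho <- r * sin(psi)
    nAz <- max(1L, ceiling(2 * pi * rho / step))
    l <- 0:(nAz - 1L)
    phi <- 2 * pi * l / nAz
    ring <- matrix(p, nAz, 3, byrow = TRUE) +
      r * cos(psi) * matrix(u, nAz, 3, byrow = TRUE) +
      rho * (cos(phi) %o% e1 + sin(phi) %o% e2)
    if (rho == 0) ring <- matrix(p + r * cos(psi) * u, 1, 3, byrow = TRUE)
    pts[[k + 1L]] <- ring
  }
  do.call(rbind, pts)
}

vcross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Transform placing two anchor atoms onto two target points
#'
#' Translates \code{ai} to \code{p}, then applies the minimal-angle rotation
#' about \code{p} taking the direction \code{aj - ai} onto \code{q - p}
#' (axis = their cross product; for antiparallel directions, a 180-degree
#' rotation about a deterministic perpendicular axis). Requires
#' \code{||p - q|| == ||ai - aj||} within 1e-6.
#'
#' @param ai,aj source points (anchor atoms of A).
#' @param p,q target points.
#' @return A \linkS4class{RigidTransform} T with \code{T(ai) == p} exactly
#'   and \code{||T(aj) - q|| <= 1e-6}.
#' @export
anchorTransform <- function(ai, aj, p, q) {
  v1 <- aj - ai; v2 <- q - p
  l1 <- sqrt(sum(v1^2)); l2 <- sqrt(sum(v2^2))
  if (abs(l1 - l2) > 1e-6)
    stop("anchor length mismatch: |ai-aj| = ", l1, " but |p-q| = ", l2)
  u1 <- v1 / l1; u2 <- v2 / l2
  ax <- vcross(u1, u2)
  s <- sqrt(sum(ax^2)); cc <- sum(u1 * u2)
  if (s < 1e-12) {
    if (cc > 0) {
      R <- diag(3)
    } else {                 # antiparallel: 180 degrees about a perpendicular
      w <- vcross(u1, c(1, 0, 0))
      if (sum(w^2) < 1e-18) w <- vcross(u1, c(0, 1, 0))
      w <- w / sqrt(sum(w^2))
      R <- 2 * (w %o% w) - diag(3)
    }
  } else {
    R <- rotationAboutAxis(ax / s, atan2(s, cc) * 180 / pi)@rotation
  }
  rigidTransform(R, as.numeric(p - R %*% ai))
}

#' Rotations about the anchor axis, composed with a base transform
#'
#' Returns the \code{360/stepDeg} transforms \code{k = 0, 1, ...} where the
#' k-th is the rotation by \code{k * stepDeg} degrees about the line through
#' \code{p} with unit direction \code{u}, composed after \code{base}. Every
#' point on the axis is fixed to 1e-9.
#' @export
axisRotations <- function(base, p, u, stepDeg) {
  n <- round(360 / stepDeg)
  stopifnot(abs(360 / stepDeg - n) < 1e-9)
  lapply(0:(n - 1L), function(k)
    composeTransforms(rotationAboutAxis(u, k * stepDeg, p), base))
}

# Candidate (p, q) placements and base transforms for one anchor pair.
# Returns NULL for degenerate anchors (|ai - aj| < 2 * step).
anchorPlacements <- function(A, B, anchors, params) {
  d <- params@contactCutoff
  step <- params@epsilon * d
  cA <- atomCoords(A); cB <- atomCoords(B)
  ai <- cA[anchors@ai, ]; aj <- cA[anchors@aj, ]
  bi <- cB[anchors@bi, ]; bj <- cB[anchors@bj, ]
  r <- sqrt(sum((ai - aj)^2))
  if (r < 2 * step) {
    warning("degenerate anchors (|ai-aj| = ", round(r, 3),
            " < 2 * grid step); skipped")
    return(NULL)
  }
  dball <- dballGrid(bi, d, step)
  P <- list(); Q <- list(); dbIdx <- list(); capIdx <- list()
  for (ii in seq_len(nrow(dball))) {
    cap <- sphereCapGrid(dball[ii, ], r, bj, d, step)
    if (nrow(cap) == 0) next
    P[[length(P) + 1L]] <- matrix(dball[ii, ], nrow(cap), 3, byrow = TRUE)
    Q[[length(Q) + 1L]] <- cap
    dbIdx[[length(dbIdx) + 1L]] <- rep(ii, nrow(cap))
    capIdx[[length(capIdx) + 1L]] <- seq_len(nrow(cap))
  }
  if (!length(P)) return(list(P = matrix(numeric(), 0, 3),
                              Q = matrix(numeric(), 0, 3),
                              dbIdx = integer(), capIdx = integer(),
                              nDball = nrow(dball), r = r))
  P <- do.call(rbind, P); Q <- do.call(rbind, Q)
  base <- lapply(seq_len(nrow(P)), function(i)
    anchorTransform(ai, aj, P[i, ], Q[i, ]))
  list(P = P, Q = Q, dbIdx = unlist(dbIdx), capIdx = unlist(capIdx),
       nDball = nrow(dball), r = r,
       baseRot = t(vapply(base, function(b) as.numeric(t(b@rotation)),
                          numeric(9))),
       baseTrans = t(vapply(base, function(b) b@translation, numeric(3))))
}

#' Enumerate candidate poses for one anchor combination
#'
#' Iterates the full product d-ball grid x sphere-cap grid x axis
#' rotations. Every pose is clash-checked on the full structures (shared
#' 1 A lattice, theta rule); clash-free poses are ACE-scored over the
#' selected score atoms (fragment atoms in stage 2, full structures in
#' stage 3). Deterministic grid order: d-ball index, cap index, rotation.
#'
#' @param A,B typed structures (B fixed).
#' @param anchors an \linkS4class{AnchorPair}.
#' @param table an \linkS4class{AceTable}.
#' @param params a \linkS4class{ScoringParams}; the pose search requires
#'   \code{gridSpacing == 1} (the clash cache lives on the unit lattice).
#' @param scoreAtomsA,scoreAtomsB atom indices scored (default: all).
#' @param BintCache optional precomputed interior points of B
#'   (\code{cpp_interior_points}); recomputed when NULL.
#' @return List with \code{poses} (data.frame: dball, cap, rot, clash, X,
#'   XA, ace in enumeration order), \code{placements}, \code{nEnumerated},
#'   \code{nClash}.
#' @export
enumeratePoses <- function(A, B, anchors, table, params = new("ScoringParams"),
                           scoreAtomsA = NULL, scoreAtomsB = NULL,
                           BintCache = NULL) {
  if (abs(params@gridSpacing - 1) > 1e-12)
    stop("the pose search requires gridSpacing = 1")
  pl <- anchorPlacements(A, B, anchors, params)
  empty <- list(poses = data.frame(), placements = pl, nEnumerated = 0L,
                nClash = 0L)
  if (is.null(pl) || nrow(pl$P) == 0) return(empty)
  nrot <- as.integer(round(360 / params@rotationStep))
  cB <- atomCoords(B)
  if (is.null(BintCache))
    BintCache <- cpp_interior_points(cB, params@proteinPointRadius)
  if (is.null(scoreAtomsA)) scoreAtomsA <- seq_len(nAtoms(A))
  if (is.null(scoreAtomsB)) scoreAtomsB <- seq_len(nAtoms(B))
  tA <- atomTypes(A); tB <- atomTypes(B)
  scan <- cpp_pose_scan(atomCoords(A), pl$baseRot, pl$baseTrans, pl$P, pl$Q,
                        nrot, params@rotationStep, BintCache,
                        params@clashTheta, params@proteinPointRadius,
                        as.integer(scoreAtomsA),
                        as.integer(ifelse(is.na(tA), -1L, tA)),
                        cB[scoreAtomsB, , drop = FALSE],
                        as.integer(ifelse(is.na(tB[scoreAtomsB]), -1L,
                                          tB[scoreAtomsB])),
                        table@energies, params@contactCutoff)
  poses <- data.frame(dball = pl$dbIdx[scan[, 1]], cap = pl$capIdx[scan[, 1]],
                      pair = as.integer(scan[, 1]), rot = as.integer(scan[, 2]),
                      clash = scan[, 3] > 0, X = as.integer(scan[, 4]),
                      XA = as.integer(scan[, 5]), ace = scan[, 6])
  list(poses = poses, placements = pl, nEnumerated = nrow(poses),
       nClash = sum(poses$clash))
}

#' Reconstruct the rigid transform of an enumerated pose
#'
#' @param enumeration result of \code{\link{enumeratePoses}}.
#' @param row row index into \code{enumeration$poses}.
#' @param params the \linkS4class{ScoringParams} used for the enumeration.
#' @export
poseTransform <- function(enumeration, row, params = new("ScoringParams")) {
  pr <- enumeration$poses[row, ]
  pl <- enumeration$placements
  i <- pr$pair
  base <- rigidTransform(matrix(pl$baseRot[i, ], 3, 3, byrow = TRUE),
                         pl$baseTrans[i, ])
  p <- pl$P[i, ]; q <- pl$Q[i, ]
  u <- (q - p) / sqrt(sum((q - p)^2))
  composeTransforms(rotationAboutAxis(u, pr$rot * params@rotationStep, p), base)
}

#' Filter fragment pairs at the ACE threshold
#'
#' For each fragment pair, anchors are its endpoint atoms (first and last of
#' each fragment, paired in alignment order); the pair survives iff some
#' clash-free enumerated pose scores the fragment atoms below
#' \code{fragmentAceThreshold}. The minimum-ACE pose is attached; input
#' order is preserved.
#'
#' @param A,B typed structures.
#' @param pairs list of \linkS4class{FragmentPair}s.
#' @param table an \linkS4class{AceTable}.
#' @param params a \linkS4class{ScoringParams}.
#' @param BintCache optional cached interior points of B.
#' @return List of \code{list(pair =, bestAce =, anchors =)} for the
#'   survivors.
#' @export
filterFragmentPairs <- function(A, B, pairs, table,
                                params = new("ScoringParams"),
                                BintCache = NULL) {
  if (is.null(BintCache))
    BintCache <- cpp_interior_points(atomCoords(B), params@proteinPointRadius)
  out <- list()
  for (fp in pairs) {
    anchors <- new("AnchorPair",
                   ai = fp@atomsA[1L], aj = fp@atomsA[length(fp@atomsA)],
                   bi = fp@atomsB[1L], bj = fp@atomsB[length(fp@atomsB)])
    en <- enumeratePoses(A, B, anchors, table, params,
                         scoreAtomsA = fp@atomsA, scoreAtomsB = fp@atomsB,
                         BintCache = BintCache)
    if (!nrow(en$poses)) next
    ok <- !en$poses$clash
    if (!any(ok)) next
    best <- min(en$poses$ace[ok])
    if (best < params@fragmentAceThreshold)
      out[[length(out) + 1L]] <- list(pair = fp, bestAce = best,
                                      anchors = anchors)
  }
  out
}

#' Dock two subunits and predict the interface
#'
#' Full pipeline: surface labeling of both subunits, minimising local
#' alignment, surface window filter, fragment-pair filtering at the ACE
#' threshold (yielding k pairs), then -- for every unordered combination of
#' two distinct endpoint interaction pairs (at most choose(2k, 2)) --
#' enumeration of all candidate configurations scored on the full
#' structures. Clash-free poses are ranked by ACE ascending (ties by
#' combination and grid index); the best pose's residue pairs within
#' \code{interfaceCutoff} are the predicted interface. Fully deterministic.
#'
#' @param A,B typed \linkS4class{ProteinStructure}s (B is held fixed; the
#'   transform of the result acts on A).
#' @param table an \linkS4class{AceTable}.
#' @param params a \linkS4class{ScoringParams}.
#' @return A \linkS4class{DockResult}; status "no prediction" when no
#'   fragment pair survives or no clash-free pose exists.
#' @export
dock <- function(A, B, table, params = new("ScoringParams")) {
  surfA <- surfaceAtoms(A, params = params)
  surfB <- surfaceAtoms(B, params = params)
  segs <- localAlignments(A, B, table, params)
  frags <- list()
  for (s in segs)
    frags <- c(frags, windowFilter(s, surfA, surfB, params))
  counters <- c(segments = length(segs), fragmentPairs = length(frags))
  noPred <- function() new("DockResult", status = "no prediction",
                           poses = data.frame(), bestPose = NULL,
                           k = 0L, interface = NULL, counters = counters)
  if (!length(frags)) return(noPred())
  Bint <- cpp_interior_points(atomCoords(B), params@proteinPointRadius)
  kept <- filterFragmentPairs(A, B, frags, table, params, BintCache = Bint)
  k <- length(kept)
  counters <- c(counters, survivingPairs = k)
  if (!k) return(noPred())
  # 2k endpoint interaction pairs, deduplicated
  ip <- unique(do.call(rbind, lapply(kept, function(x)
    rbind(c(x$anchors@ai, x$anchors@bi), c(x$anchors@aj, x$anchors@bj)))))
  combos <- if (nrow(ip) >= 2) utils::combn(nrow(ip), 2) else
    matrix(integer(), 2, 0)
  allPoses <- list(); enums <- list()
  nEnum <- 0L; nClash <- 0L
  for (ci in seq_len(ncol(combos))) {
    i1 <- combos[1, ci]; i2 <- combos[2, ci]
    if (ip[i1, 1] == ip[i2, 1]) next  # anchor atoms on A must be distinct
    anchors <- new("AnchorPair", ai = ip[i1, 1], aj = ip[i2, 1],
                   bi = ip[i1, 2], bj = ip[i2, 2])
    en <- withCallingHandlers(
      enumeratePoses(A, B, anchors, table, params, BintCache = Bint),
      warning = function(w) invokeRestart("muffleWarning"))
    nEnum <- nEnum + en$nEnumerated; nClash <- nClash + en$nClash
    if (!nrow(en$poses)) next
    enums[[as.character(ci)]] <- en
    df <- en$poses[!en$poses$clash, , drop = FALSE]
    if (!nrow(df)) next
    df$combo <- ci
    df$row <- as.integer(rownames(en$poses))[!en$poses$clash]
    allPoses[[length(allPoses) + 1L]] <- df
  }
  counters <- c(counters, posesEnumerated = nEnum, posesClashing = nClash)
  if (!length(allPoses)) {
    res <- noPred(); res@k <- as.integer(k); res@counters <- counters
    return(res)
  }
  ap <- do.call(rbind, allPoses)
  ap <- ap[order(ap$ace, ap$combo, ap$dball, ap$cap, ap$rot), , drop = FALSE]
  top <- utils::head(ap, params@topNPoses)
  rownames(top) <- NULL
  bi <- top[1, ]
  en <- enums[[as.character(bi$combo)]]
  tr <- poseTransform(en, bi$row, params)
  anchors <- new("AnchorPair", ai = ip[combos[1, bi$combo], 1],
                 aj = ip[combos[2, bi$combo], 1],
                 bi = ip[combos[1, bi$combo], 2],
                 bj = ip[combos[2, bi$combo], 2])
  best <- new("Pose", transform = tr, ace = bi$ace, clash = FALSE,
              anchors = anchors,
              gridIndex = as.integer(c(bi$dball, bi$cap, bi$rot)))
  iface <- predictedInterface(applyTransform(A, tr), B,
                              cutoff = params@interfaceCutoff)
  new("DockResult", status = "ok",
      poses = top[, c("combo", "dball", "cap", "rot", "ace", "X", "XA")],
      bestPose = best, k = as.integer(k), interface = iface,
      counters = counters)
}
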