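# d-ball / sphere-cap grids, anchor transforms, axis rotations and the
# pose enumeration machinery.

test_that("dballGrid counts and membership follow the lattice definition", {
  ctr <- c(1, -2, 3)
  expect_equal(dballGrid(ctr, d = 2, step = 4),
               matrix(ctr, 1, 3, byrow = TRUE), ignore_attr = TRUE)
  g <- dballGrid(c(0, 0, 0), d = 1, step = 1)
  expect_equal(nrow(g), 7)                       # centre + six axis neighbours
  set.seed(37)
  for (rep in 1:5) {
    d <- runif(1, 1, 6); step <- runif(1, 0.3, 1.5); c0 <- runif(3, -5, 5)
    g <- dballGrid(c0, d, step)
    expect_true(all(sqrt(rowSums(sweep(g, 2, c0)^2)) <= d + 1e-9))
    expect_true(any(rowSums(abs(sweep(g, 2, c0))) < 1e-12))   # contains centre
    # count equals the brute-force cube scan
    kmax <- floor(d / step + 1e-9)
    cube <- as.matrix(expand.grid(-kmax:kmax, -kmax:kmax, -kmax:kmax)) * step
    expect_equal(nrow(g), sum(rowSums(cube^2) <= d^2 + 1e-9))
  }
})

test_that("sphereCapGrid respects both constraints and includes the pole", {
  set.seed(41)
  for (rep in 1:30) {
    p <- runif(3, -5, 5); r <- runif(1, 1, 8)
    c0 <- p + runif(3, -6, 6); d <- runif(1, 1, 6)
    step <- runif(1, 0.5, 2)
    cap <- sphereCapGrid(p, r, c0, d, step)
    D <- sqrt(sum((c0 - p)^2))
    if (D > r + d + 1e-9 || D < r - d - 1e-9) {
      expect_equal(nrow(cap), 0)
    } else {
      expect_gt(nrow(cap), 0)
      expect_true(all(abs(sqrt(rowSums(sweep(cap, 2, p)^2)) - r) < 1e-9))
      expect_true(all(sqrt(rowSums(sweep(cap, 2, c0)^2)) <= d + 1e-6))
      pole <- p + r * (c0 - p) / D
      expect_lt(min(sqrt(rowSums(sweep(cap, 2, pole)^2))), 1e-9)
    }
  }
  # ball centre on the sphere: the pole is the ball centre itself
  cap <- sphereCapGrid(c(0, 0, 0), 5, c(5, 0, 0), 2, 1)
  expect_lt(min(sqrt(rowSums(sweep(cap, 2, c(5, 0, 0))^2))), 1e-9)
  expect_equal(nrow(sphereCapGrid(c(0, 0, 0), 1, c(10, 0, 0), 2, 1)), 0)
})

test_that("sphereCapGrid density tracks a rejection-sampling estimate", {
  # area fraction of the cap vs count of emitted points at fine step
  p <- c(0, 0, 0); r <- 4; c0 <- c(5, 0, 0); d <- 3; step <- 0.25
  cap <- sphereCapGrid(p, r, c0, d, step)
  set.seed(43)
  u <- matrix(rnorm(3 * 40000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * r
  frac <- mean(sqrt(rowSums(sweep(u, 2, c0)^2)) <= d)
  expected <- 4 * pi * r^2 * frac / step^2
  expect_gt(nrow(cap), 0.5 * expected)
  expect_lt(nrow(cap), 2 * expected)
})

test_that("anchorTransform satisfies its mapping and rigidity contracts", {
  set.seed(47)
  for (rep in 1:100) {
    ai <- runif(3, -5, 5); aj <- ai + runif(3, -4, 4)
    r <- sqrt(sum((aj - ai)^2))
    p <- runif(3, -5, 5)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    q <- p + r * dir
    tr <- anchorTransform(ai, aj, p, q)
    expect_lt(max(abs(applyTransform(matrix(ai, 1, 3), tr) - p)), 1e-9)
    expect_lt(max(abs(applyTransform(matrix(aj, 1, 3), tr) - q)), 1e-6)
    R <- tr@rotation
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-6)
    expect_equal(det(R), 1, tolerance = 1e-6)
  }
  ai <- c(1, 2, 3); aj <- c(4, 5, 6)
  idt <- anchorTransform(ai, aj, ai, aj)
  expect_equal(idt@rotation, diag(3))
  expect_equal(idt@translation, c(0, 0, 0))
  sh <- anchorTransform(ai, aj, ai + 2, aj + 2)       # pure shift
  expect_equal(sh@rotation, diag(3))
  expect_equal(sh@translation, c(2, 2, 2))
  # antiparallel case still honours the contract
  ap <- anchorTransform(ai, aj, ai, ai - (aj - ai))
  expect_lt(max(abs(applyTransform(matrix(aj, 1, 3), ap) -
                      (ai - (aj - ai)))), 1e-6)
  expect_error(anchorTransform(ai, aj, ai, aj * 3), "length mismatch")
})

test_that("axisRotations fix the axis and sweep circles", {
  base <- randomTransform()
  p <- c(1, 1, 1); u <- c(0, 0, 1)
  rots <- axisRotations(base, p, u, 90)
  expect_length(rots, 4)
  expect_equal(rots[[1]]@rotation, base@rotation)
  expect_equal(rots[[1]]@translation, base@translation)
  onAxis <- matrix(p + c(0, 0, 5), 1, 3)
  baseImg <- applyTransform(onAxis, base)
  # image of an axis point under each k equals rotating the base image about
  # the axis; the axis itself is fixed by the post-rotation
  for (k in 1:4) {
    post <- rotationAboutAxis(u, (k - 1) * 90, p)
    expect_equal(applyTransform(onAxis, rots[[k]]),
                 applyTransform(baseImg, post), tolerance = 1e-9)
  }
  axisPt <- matrix(p, 1, 3)
  for (k in 1:4) {
    post <- rotationAboutAxis(u, (k - 1) * 90, p)
    expect_lt(max(abs(applyTransform(axisPt, post) - p)), 1e-9)
  }
  # an off-axis point stays at constant distance from the axis line
  off <- matrix(p + c(2, 0, 0), 1, 3)
  dists <- vapply(1:4, function(k) {
    img <- applyTransform(off, rotationAboutAxis(u, (k - 1) * 90, p))
    v <- img[1, ] - p
    sqrt(sum(v^2) - sum(v * u)^2)
  }, 0)
  expect_lt(diff(range(dists)), 1e-9)
})

coarseParams <- new("ScoringParams", epsilon = 0.5, rotationStep = 120)

test_that("enumeratePoses yields the analytic grid product", {
  pc <- makePlantedComplex(seed = 2L)
  anchors <- pc@construction$anchors
  en <- enumeratePoses(pc@subunitA, pc@subunitB, anchors,
                       pc@construction$table, coarseParams)
  pl <- en$placements
  d <- coarseParams@contactCutoff; step <- coarseParams@epsilon * d
  cB <- atomCoords(pc@subunitB)
  dball <- dballGrid(cB[anchors@bi, ], d, step)
  capSum <- 0
  for (i in seq_len(nrow(dball)))
    capSum <- capSum + nrow(sphereCapGrid(dball[i, ], pl$r,
                                          cB[anchors@bj, ], d, step))
  expect_equal(en$nEnumerated, capSum * (360 / coarseParams@rotationStep))
  # every reported clash-free pose really is clash-free per clashCheck
  free <- which(!en$poses$clash)[1:3]
  for (row in free) {
    tr <- poseTransform(en, row, coarseParams)
    cr <- clashCheck(applyTransform(pc@subunitA, tr), pc@subunitB, coarseParams)
    expect_false(cr@clash)
    expect_equal(cr@X, en$poses$X[row])
    expect_equal(cr@XA, en$poses$XA[row])
  }
  # and its ACE is recomputable from the transform
  row <- free[1]
  tr <- poseTransform(en, row, coarseParams)
  expect_equal(aceScore(applyTransform(pc@subunitA, tr), pc@subunitB,
                        pc@construction$table, d),
               en$poses$ace[row], tolerance = 1e-6)
})

test_that("an engulfed anchor region leaves no clash-free pose", {
  # B: dense 9x9x9 block; anchors deep inside it force A into the interior
  blk <- as.matrix(expand.grid(x = 0:8, y = 0:8, z = 0:8)) * 1.2
  B <- toyFromCoords(blk, rep(0L, nrow(blk)), chain = "B")
  rod <- cbind(seq(0, 9, by = 1.5), 0, 0)
  A <- toyFromCoords(rod, rep(1L, nrow(rod)), chain = "A")
  centre <- which.min(rowSums(sweep(blk, 2, colMeans(blk))^2))
  nb <- order(rowSums(sweep(blk, 2, blk[centre, ])^2))[7]
  anchors <- new("AnchorPair", ai = 1L, aj = nrow(rod),
                 bi = as.integer(centre), bj = as.integer(nb))
  tab <- makeToyAceTable()
  en <- enumeratePoses(A, B, anchors, tab, coarseParams)
  expect_gt(en$nEnumerated, 0)
  expect_equal(en$nClash, en$nEnumerated)
})

test_that("fragment filter keeps the planted pair and honours thresholds", {
  pc <- makePlantedComplex(seed = 3L)
  fp <- new("FragmentPair",
            atomsA = pc@construction$runA, atomsB = pc@construction$runB,
            surfaceA = 15L, surfaceB = 15L)
  params <- new("ScoringParams", epsilon = 0.5, rotationStep = 60)
  kept <- filterFragmentPairs(pc@subunitA, pc@subunitB, list(fp),
                              pc@construction$table, params)
  expect_length(kept, 1)
  expect_lt(kept[[1]]$bestAce, 400)
  # threshold -Inf discards everything; +Inf keeps any pair with a
  # clash-free pose
  pInf <- params; pInf@fragmentAceThreshold <- -Inf
  expect_length(filterFragmentPairs(pc@subunitA, pc@subunitB, list(fp),
                                    pc@construction$table, pInf), 0)
  pSup <- params; pSup@fragmentAceThreshold <- Inf
  expect_length(filterFragmentPairs(pc@subunitA, pc@subunitB, list(fp),
                                    pc@construction$table, pSup), 1)
})

test_that("dock recovers a planted complex and reports honest minimality", {
  pc <- makePlantedComplex(seed = 4L)
  params <- new("ScoringParams", epsilon = 0.5, rotationStep = 60)
  res <- dock(pc@subunitA, pc@subunitB, pc@construction$table, params)
  expect_equal(res@status, "ok")
  expect_identical(interfacePairs(res@interface),
                   interfacePairs(pc@plantedInterface))
  # best pose ACE is minimal among all re-enumerated clash-free poses
  en <- enumeratePoses(pc@subunitA, pc@subunitB, res@bestPose@anchors,
                       pc@construction$table, params)
  expect_lte(res@poses$ace[1], min(en$poses$ace[!en$poses$clash]) + 1e-9)
  # determinism: identical inputs give identical results
  res2 <- dock(pc@subunitA, pc@subunitB, pc@construction$table, params)
  expect_identical(res2@poses, res@poses)
  expect_identical(interfacePairs(res2@interface), interfacePairs(res@interface))
})

test_that("an all-repulsive table propagates to a no-prediction result", {
  pc <- makePlantedComplex(seed = 5L)
  repulsive <- aceTable(matrix(1, 18, 18))
  params <- new("ScoringParams", epsilon = 0.5, rotationStep = 120)
  res <- dock(pc@subunitA, pc@subunitB, repulsive, params)
  expect_equal(res@status, "no prediction")
  expect_equal(unname(res@counters["segments"]), 0)
})

test_that("docking is equivariant under translations of the fixed subunit", {
  pc <- makePlantedComplex(seed = 6L)
  params <- new("ScoringParams", epsilon = 0.5, rotationStep = 60)
  res <- dock(pc@subunitA, pc@subunitB, pc@construction$table, params)
  shift <- rigidTransform(diag(3), c(7, -4, 11))
  Bmoved <- applyTransform(pc@subunitB, shift)
  res2 <- dock(pc@subunitA, Bmoved, pc@construction$table, params)
  expect_equal(res2@poses$ace[1], res@poses$ace[1], tolerance = 1e-6)
  expect_identical(interfacePairs(res2@interface), interfacePairs(res@interface))
  # the best transform is conjugated by the shift
  want <- composeTransforms(shift, res@bestPose@transform)
  expect_equal(res2@bestPose@transform@rotation, want@rotation,
               tolerance = 1e-6)
  expect_equal(res2@bestPose@transform@translation, want@translation,
               tolerance = 1e-6)
})
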