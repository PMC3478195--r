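# Interface extraction and the evaluation statistics.

test_that("predictedInterface equals the quadratic oracle", {
  set.seed(53)
  # two far single-residue subunits: empty
  A1 <- toyFromCoords(matrix(c(0, 0, 0), 1, 3))
  B1 <- toyFromCoords(matrix(c(10, 0, 0), 1, 3), chain = "B")
  expect_equal(nrow(interfacePairs(predictedInterface(A1, B1))), 0L)
  # closest atoms at 4.4 A: exactly one pair
  B2 <- toyFromCoords(matrix(c(4.4, 0, 0), 1, 3), chain = "B")
  expect_equal(nrow(interfacePairs(predictedInterface(A1, B2))), 1L)
  # random toy complexes match brute force at residue level
  for (rep in 1:8) {
    cA <- matrix(runif(36, 0, 12), 12, 3); cB <- matrix(runif(36, 0, 12), 12, 3)
    A <- toyFromCoords(cA); B <- toyFromCoords(cB, chain = "B")
    got <- interfacePairs(predictedInterface(A, B))
    ct <- bruteContacts(cA, cB, 4.5)
    want <- unique(data.frame(resA = residueIds(A)[ct$i],
                              resB = residueIds(B)[ct$j]))
    want <- want[order(want$resA, want$resB), ]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("actualInterface applies the strict vdW + margin rule", {
  mkC <- function(x) proteinStructure(data.frame(
    serial = 1, name = "CA", element = "C", resname = "GLY", resseq = 1,
    inscode = "", chain = "A", x = x, y = 0, z = 0, aceType = NA_integer_))
  A <- mkC(0)
  B45 <- mkC(4.5); B45@atoms$chain <- "B"
  B43 <- mkC(4.3); B43@atoms$chain <- "B"
  # two carbons: threshold 1.7 + 1.7 + 1 = 4.4, strict "less than"
  expect_equal(nrow(interfacePairs(actualInterface(A, B45))), 0L)
  expect_equal(nrow(interfacePairs(actualInterface(A, B43))), 1L)
  # margin monotonicity: margin-0 pairs are a subset of margin-1 pairs
  set.seed(59)
  cA <- matrix(runif(30, 0, 10), 10, 3); cB <- matrix(runif(30, 0, 10), 10, 3)
  Ar <- toyFromCoords(cA); Br <- toyFromCoords(cB, chain = "B")
  p0 <- interfacePairs(actualInterface(Ar, Br, margin = 0))
  p1 <- interfacePairs(actualInterface(Ar, Br, margin = 1))
  expect_true(all(paste(p0$resA, p0$resB) %in% paste(p1$resA, p1$resB)))
  # brute-force agreement with per-element radii
  radii <- vdwRadii()
  eA <- atomTable(Ar)$element; eB <- atomTable(Br)$element
  keep <- NULL
  for (i in 1:10) for (j in 1:10) {
    d <- sqrt(sum((cA[i, ] - cB[j, ])^2))
    if (d < radii[eA[i]] + radii[eB[j]] + 1)
      keep <- rbind(keep, data.frame(resA = residueIds(Ar)[i],
                                     resB = residueIds(Br)[j]))
  }
  keep <- unique(keep); keep <- keep[order(keep$resA, keep$resB), ]
  rownames(keep) <- NULL
  expect_equal(p1, keep)
})

test_that("accuracy, coverage and the F-score follow their definitions", {
  r <- accuracyCoverage(letters[1:4], letters[1:4])
  expect_equal(c(r$accuracy, r$coverage), c(100, 100))
  r <- accuracyCoverage(letters[1:3], letters[10:12])
  expect_equal(c(r$accuracy, r$coverage), c(0, 0))
  r <- accuracyCoverage(paste0("p", 1:20), c(paste0("p", 1:8), paste0("x", 1:2)))
  expect_equal(r$accuracy, 40)
  expect_equal(r$coverage, 80)
  expect_equal(r$correct, 8)
  expect_true(accuracyCoverage(character(), letters[1:3])$emptyPrediction)
  expect_true(is.na(accuracyCoverage(letters[1:3], character())$coverage))
  # harmonic mean on the 0-1 scale
  expect_equal(fScore(40, 80), 2 * 40 * 80 / 120 / 100)
  expect_equal(fScore(0, 0), 0)
  expect_equal(fScore(37, 37), 0.37)
  expect_equal(fScore(30, 70), fScore(70, 30))
  f <- fScore(44.3, 70.5)
  expect_lte(f, max(44.3, 70.5) / 100)
  expect_gte(f, 0)
})

test_that("success counts cases with accuracy at least 50, inclusive", {
  expect_equal(successRate(c(100, 100, 100)), 100)
  expect_equal(successRate(c(50, 49.9)), 50)
  expect_equal(successRate(c(60, 40, 55, 10)), 50)
  expect_equal(successRate(c(NA, 80)), 50)        # undefined counts as failure
  expect_error(successRate(numeric()), "no cases")
})

test_that("iRMSD is zero on self, rigid-invariant, and matches a hand case", {
  pc <- makePlantedComplex(seed = 7L)
  A <- pc@subunitA; B <- pc@subunitB
  iface <- predictedInterface(A, B)
  expect_equal(irmsd(A, B, A, B, interface = iface), 0, tolerance = 1e-9)
  # joint rigid motion of the predicted complex changes nothing
  g <- randomTransform()
  expect_equal(irmsd(applyTransform(A, g), applyTransform(B, g), A, B,
                     interface = iface), 0, tolerance = 1e-6)
  # rectangular 4-residue toy: the cross-covariance of the centred sets is
  # diagonal and positive, so the optimal Kabsch rotation is the identity
  # and the fit reduces to the centroid shift (+1 of the +2 one-sided
  # displacement); every CA then misses by exactly 1 and the RMSD is 1
  mk <- function(xs, ys, chain) proteinStructure(data.frame(
    serial = seq_along(xs), name = "CA", element = "C", resname = "GLY",
    resseq = seq_along(xs), inscode = "", chain = chain,
    x = xs, y = ys, z = 0, aceType = NA_integer_))
  natA <- mk(c(0, 0), c(0, 2), "A"); natB <- mk(c(8, 8), c(0, 2), "B")
  ifc <- new("InterfaceSet",
             pairs = data.frame(resA = residueIds(natA)[1:2],
                                resB = residueIds(natB)[1:2]),
             residuesA = unique(residueIds(natA)),
             residuesB = unique(residueIds(natB)))
  predA <- mk(c(2, 2), c(0, 2), "A")
  expect_equal(irmsd(predA, natB, natA, natB, interface = ifc), 1,
               tolerance = 1e-6)
})

test_that("native contact fraction is 100 on self, 0 far away, monotone", {
  pc <- makePlantedComplex(seed = 8L)
  A <- pc@subunitA; B <- pc@subunitB
  expect_equal(nativeContactFraction(A, B, A, B), 100)
  Afar <- applyTransform(A, rigidTransform(diag(3), c(100, 0, 0)))
  expect_equal(nativeContactFraction(Afar, B, A, B), 0)
  fr <- vapply(seq(0, 10, by = 2), function(dz)
    nativeContactFraction(applyTransform(A, rigidTransform(diag(3), c(0, 0, dz))),
                          B, A, B), 0)
  expect_true(all(diff(fr) <= 0))
})

test_that("a half-preserved construction scores 50 percent native contacts", {
  # native: two residues of A touch two residues of B; prediction keeps one
  mkRes <- function(xs, chain) toyFromCoords(cbind(xs, 0, 0), chain = chain)
  natA <- mkRes(c(0, 1, 2, 3, 20, 21, 22, 23), "A")
  natB <- mkRes(c(6, 7, 8, 5.5, 26, 27, 28, 25.5), "B")
  # native contacts: res1A-res1B (3 to 5.5 = 2.5) and res2A-res2B (2.5)
  natPairs <- aceDock:::residuePairMinDist(natA, natB, 4.5)
  expect_equal(nrow(natPairs[natPairs$dist < 4.5, ]), 2L)
  predA <- mkRes(c(0, 1, 2, 3, 40, 41, 42, 43), "A")  # second contact broken
  expect_equal(nativeContactFraction(predA, natB, natA, natB), 50)
})
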