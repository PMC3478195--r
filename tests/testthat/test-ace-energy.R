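# Contact-energy definition, table handling, typing, contacts and scoring.

test_that("contactEnergy matches hand evaluation and its symmetries", {
  expect_equal(contactEnergy(5, 5, 5, 5, 5, 5), 0)          # all ratios 1
  expect_equal(contactEnergy(10, 20, 5, 10, 5, 10), -log(2))
  expect_equal(contactEnergy(10, 20, 5, 10, 5, 10),
               contactEnergy(10, 20, 5, 10, 5, 10 + 0))     # deterministic
  # exchanging the i- and j-labelled blocks leaves the value unchanged
  expect_equal(contactEnergy(3, 7, 2, 9, 4, 5),
               contactEnergy(3, 7, 4, 5, 2, 9))
  expect_error(contactEnergy(0, 1, 1, 1, 1, 1), "Nij")
  expect_error(contactEnergy(1, 1, 1, -2, 1, 1), "Ci0")
  # more observed i-j contacts: more favourable (monotone decrease)
  vals <- vapply(1:6, function(n) contactEnergy(n, 5, 2, 3, 4, 5), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("buildAceTable equals elementwise hand evaluation and is symmetric", {
  set.seed(3)
  Nij <- matrix(runif(324, 1, 50), 18, 18); Nij <- (Nij + t(Nij)) / 2
  Cij <- matrix(runif(324, 1, 50), 18, 18); Cij <- (Cij + t(Cij)) / 2
  N0 <- runif(18, 1, 50); C0 <- runif(18, 1, 50)
  tab <- buildAceTable(Nij, Cij, N0, C0)
  E <- aceEnergies(tab)
  expect_equal(E, t(E))
  for (idx in list(c(1, 1), c(3, 17), c(18, 2)))
    expect_equal(E[idx[1], idx[2]],
                 -log((Nij[idx[1], idx[2]] / Cij[idx[1], idx[2]]) /
                        ((N0[idx[1]] / C0[idx[1]]) * (N0[idx[2]] / C0[idx[2]]))))
  # uniform counts give the all-zero table
  u <- matrix(4, 18, 18)
  expect_true(all(aceEnergies(buildAceTable(u, u, rep(4, 18), rep(4, 18))) == 0))
})

test_that("ACE table files round-trip exactly and reject bad input", {
  set.seed(5)
  E <- matrix(rnorm(324), 18, 18); E <- (E + t(E)) / 2
  tab <- aceTable(E, typingMap = data.frame(resname = "ALA", atom = "CB",
                                            type = 5L))
  f <- withr::local_tempfile(fileext = ".tsv")
  saveAceTable(tab, f)
  tab2 <- loadAceTable(f)
  expect_identical(aceEnergies(tab2), aceEnergies(tab))
  expect_identical(tab2@typingMap, tab@typingMap)
  expect_error(aceTable(matrix(rnorm(324), 18, 18)), "symmetric")
  # the shipped synthetic table loads and covers the 20 standard residues
  shipped <- loadAceTable()
  expect_equal(dim(aceEnergies(shipped)), c(18L, 18L))
  expect_setequal(unique(shipped@typingMap$resname),
                  c("GLY", "ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "TRP",
                    "MET", "CYS", "SER", "THR", "TYR", "ASN", "GLN", "ASP",
                    "GLU", "LYS", "ARG", "HIS"))
})

test_that("assignAceTypes types standard atoms and honours the unknown policy", {
  tab <- loadAceTable()
  ala <- proteinStructure(data.frame(
    serial = 1:5, name = c("N", "CA", "C", "O", "CB"),
    element = c("N", "C", "C", "O", "C"), resname = "ALA", resseq = 1,
    inscode = "", chain = "A", x = 1:5, y = 0, z = 0, aceType = NA_integer_))
  typed <- assignAceTypes(ala, tab)
  expect_false(anyNA(atomTypes(typed)))
  lig <- proteinStructure(data.frame(
    serial = 1, name = "FE", element = "FE", resname = "HEM", resseq = 1,
    inscode = "", chain = "A", x = 0, y = 0, z = 0, aceType = NA_integer_))
  expect_true(is.na(atomTypes(assignAceTypes(lig, tab, "skip"))))
  expect_error(assignAceTypes(lig, tab, "error"), "HEM")
  # typing is deterministic
  expect_identical(atomTypes(assignAceTypes(ala, tab)),
                   atomTypes(assignAceTypes(ala, tab)))
})

test_that("findContacts is inclusive at the cutoff and matches brute force", {
  two <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  expect_equal(nrow(findContacts(two(6.01)[1, , drop = FALSE],
                                 two(6.01)[2, , drop = FALSE], 6)), 0L)
  expect_equal(nrow(findContacts(matrix(0, 1, 3), matrix(c(5, 0, 0), 1, 3), 6)),
               1L)
  set.seed(17)
  for (rep in 1:25) {
    c1 <- matrix(runif(150, 0, 20), 50, 3)
    c2 <- matrix(runif(150, 0, 20), 50, 3)
    cutoff <- runif(1, 2, 8)
    got <- findContacts(c1, c2, cutoff)
    want <- bruteContacts(c1, c2, cutoff)
    expect_identical(got[, c("i", "j")], want[, c("i", "j")])
    expect_equal(got$dist, want$dist)
  }
})

test_that("aceScore matches brute force, is symmetric and rigid-invariant", {
  set.seed(19)
  tab <- makeToyAceTable(list(c(0, 1), c(2, 3)), favorable = -3, background = 0.5)
  for (rep in 1:10) {
    c1 <- matrix(runif(9, 0, 8), 3, 3); t1 <- sample(0:3, 3, TRUE)
    c2 <- matrix(runif(9, 0, 8), 3, 3); t2 <- sample(0:3, 3, TRUE)
    expect_equal(aceScore(c1, c2, tab, 6, types1 = t1, types2 = t2),
                 bruteAce(c1, t1, c2, t2, aceEnergies(tab), 6))
    expect_equal(aceScore(c1, c2, tab, 6, types1 = t1, types2 = t2),
                 aceScore(c2, c1, tab, 6, types1 = t2, types2 = t1))
    g <- randomTransform()
    expect_equal(aceScore(applyTransform(c1, g), applyTransform(c2, g), tab, 6,
                          types1 = t1, types2 = t2),
                 aceScore(c1, c2, tab, 6, types1 = t1, types2 = t2),
                 tolerance = 1e-9)
  }
  # empty set and out-of-range sets score zero; untyped atoms are skipped
  expect_equal(aceScore(matrix(numeric(), 0, 3), matrix(0, 1, 3), tab, 6,
                        types1 = integer(), types2 = 0L), 0)
  expect_equal(aceScore(matrix(0, 1, 3), matrix(c(100, 0, 0), 1, 3), tab, 6,
                        types1 = 0L, types2 = 1L), 0)
  expect_equal(aceScore(matrix(0, 1, 3), matrix(c(1, 0, 0), 1, 3), tab, 6,
                        types1 = NA_integer_, types2 = 1L), 0)
})
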