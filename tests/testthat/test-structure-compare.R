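test_that("identical coordinate sets superpose to the identity", {
  x <- coords(buildHelixBundle(1, 12))
  r <- superpose(x, x)
  expect_equal(r@rmsd, 0, tolerance = 1e-12)
  expect_equal(r@rotation, diag(3), tolerance = 1e-10)
  expect_equal(r@translation, c(0, 0, 0), tolerance = 1e-10)
})

test_that("an applied rigid transform is recovered exactly", {
  set.seed(8)
  ref <- coords(buildHelixBundle(2, 10))
  ax <- c(1, 2, -0.5); ax <- ax / sqrt(sum(ax^2))
  R0 <- clampscope:::rotAxis(ax, 37)
  mob <- sweep(ref %*% t(R0), 2, c(5, -3, 11), `+`)
  r <- superpose(ref, mob)
  expect_equal(r@rmsd, 0, tolerance = 1e-9)
  # recovered rotation undoes the applied one
  expect_equal(r@rotation %*% R0, diag(3), tolerance = 1e-9)
})

test_that("superposition RMSD agrees with an independent implementation", {
  set.seed(13)
  ref <- matrix(rnorm(60, sd = 6), ncol = 3)
  mob <- sweep(ref %*% t(randomRotation()), 2, c(3, 1, -2), `+`) +
    matrix(rnorm(60, sd = 0.3), ncol = 3)
  mine <- superpose(ref, mob)@rmsd
  oracle <- bio3d::rmsd(as.vector(t(ref)), as.vector(t(mob)),
                        fit = TRUE)          # reported to 3 decimals
  expect_equal(round(mine, 3), oracle)
})

test_that("superposition RMSD is symmetric in its arguments", {
  set.seed(14)
  a <- matrix(rnorm(45, sd = 5), ncol = 3)
  b <- a + matrix(rnorm(45, sd = 0.5), ncol = 3)
  expect_equal(superpose(a, b)@rmsd, superpose(b, a)@rmsd,
               tolerance = 1e-10)
})

test_that("degenerate or mismatched inputs are rejected", {
  line <- cbind(1:10, 0, 0)
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(matrix(rnorm(9), 3), matrix(rnorm(12), 4)),
               "same number")
})

test_that("a model compared to itself gives zero RMSD", {
  b <- buildHelixBundle(2, 15)
  r <- rmsdBetweenModels(b, atomSelection(atomNames = c("N", "CA", "C", "O")))
  expect_equal(r@rmsd, 0, tolerance = 1e-12)
  expect_equal(r@nAtoms, 2L * 15L * 4L)
})

test_that("per-coordinate noise produces the expected RMSD", {
  set.seed(19)
  b <- buildHelixBundle(4, 30)
  a <- atoms(b)
  sigma <- 0.1
  a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] +
    matrix(rnorm(3 * nrow(a), sd = sigma), ncol = 3)
  noisy <- modelFromAtoms(a)
  r <- rmsdBetweenModels(b, atomSelection(), noisy, atomSelection())
  expect_equal(r@rmsd, sigma * sqrt(3), tolerance = 0.1)
})

test_that("by_residue_number pairing names unmatched residues", {
  b <- buildHelixBundle(1, 10)
  a <- atoms(b)
  shorter <- modelFromAtoms(a[a$resno <= 8, ])
  expect_error(
    rmsdBetweenModels(b, atomSelection(atomNames = "CA"), shorter,
                      atomSelection(atomNames = "CA"),
                      pairing = "by_residue_number"),
    "unmatched")
  # matching subsets succeed
  r <- rmsdBetweenModels(
    b, atomSelection(resnoRange = c(1, 8), atomNames = "CA"), shorter,
    atomSelection(atomNames = "CA"), pairing = "by_residue_number")
  expect_equal(r@rmsd, 0, tolerance = 1e-12)
})

lysGluModel <- function(dist) {
  lys <- sideChainResidue("A", 10, "LYS", "NZ", c(0, 0, 0))
  glu <- sideChainResidue("B", 20, "GLU", "OE1", c(dist, 0, 0),
                          offset = c(0, -20, 0))
  modelFromAtoms(rbind(lys, glu))
}

test_that("a close Lys-Glu pair across chains is one salt bridge", {
  br <- findSaltBridges(lysGluModel(3.0), "A", "B")
  expect_equal(nrow(br), 1)
  expect_equal(br$resnameBasic, "LYS")
  expect_equal(br$atomAcidic, "OE1")
  expect_equal(br$distance, 3.0, tolerance = 1e-9)
  expect_equal(nrow(findSaltBridges(lysGluModel(6.0), "A", "B")), 0)
})

test_that("salt-bridge counts are monotone non-decreasing in the cutoff", {
  rows <- rbind(
    sideChainResidue("A", 1, "LYS", "NZ", c(0, 0, 0)),
    sideChainResidue("A", 2, "ARG", "NH1", c(0, 8, 0)),
    sideChainResidue("B", 1, "GLU", "OE1", c(3.2, 0, 0)),
    sideChainResidue("B", 2, "ASP", "OD2", c(4.8, 8, 0),
                     offset = c(0, -25, 0)))
  m <- modelFromAtoms(rows)
  counts <- vapply(c(2, 3, 3.5, 4, 5, 6),
                   function(ct) nrow(findSaltBridges(m, "A", "B",
                                                     cutoff = ct)),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[4], 1)   # only the 3.2 A pair at the 4.0 default
  expect_equal(counts[6], 2)
})

test_that("overlapping chain groups are rejected", {
  expect_error(findSaltBridges(lysGluModel(3), c("A", "B"), "B"),
               "disjoint")
})

test_that("phosphate-contact inventories respect the cutoff", {
  dna <- buildBDNA("ACGTACGT")
  a <- atoms(dna)
  op1 <- a[a$elety == "OP1" & a$chain == "A" & a$resno == 4, ]
  target <- c(op1$x, op1$y, op1$z)
  place <- function(d) {
    lys <- sideChainResidue("P", 34, "LYS", "NZ",
                            target + c(0, 0, d), offset = c(0, 30, 0))
    combineModels(dna, modelFromAtoms(lys))
  }
  hit <- dnaContactResidues(place(4.0), "P", c("A", "B"))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$resno, 34)
  expect_equal(hit$minDistance, 4.0, tolerance = 1e-6)
  expect_equal(nrow(dnaContactResidues(place(7.0), "P", c("A", "B"))), 0)
})

test_that("contact lists are empty at zero cutoff and total at infinity", {
  prot <- local({
    p <- atoms(buildHelixBundle(1, 6))
    p$chain <- "Q"
    modelFromAtoms(p)
  })
  m <- combineModels(buildBDNA("ACGTACGT"),
                     transformModel(prot, diag(3), c(30, 0, 0)))
  expect_equal(nrow(dnaContactResidues(m, "Q", c("A", "B"), cutoff = 0,
                                       atoms = "all")), 0)
  got <- dnaContactResidues(m, "Q", c("A", "B"), cutoff = 1e9)
  expect_equal(nrow(got), 6)
})
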