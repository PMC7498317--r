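test_that("strand pairing follows the antiparallel register", {
  p <- pairStrands(buildBDNA("AT"), "A", "B")
  expect_equal(nrow(p), 2)
  p16 <- pairStrands(buildBDNA("CCGAAAAAAAAAACGC"), "A", "B")
  expect_equal(p16$designedType[4], "A:T")
  expect_equal(p16$resno2, 16:1)
  expect_true(all(p16$c1c1 < 15))
})

test_that("strands of unequal length are rejected", {
  dna <- buildBDNA("ACGTACGTACGT")
  a <- atoms(dna)
  trimmed <- modelFromAtoms(a[!(a$chain == "B" & a$resno == 1), ])
  expect_error(pairStrands(trimmed, "A", "B"), "length")
})

test_that("a shifted register fails validation with guidance", {
  dna <- buildBDNA("ACGTACGTACGT")
  a <- atoms(dna)
  b <- a$chain == "B"
  a$resno[b] <- ((a$resno[b] + 5) %% 12) + 1   # scramble strand-2 numbering
  expect_error(pairStrands(modelFromAtoms(a), "A", "B"), "register")
})

test_that("canonical bond inventories have the right multiplicity", {
  inv <- hbondInventory(buildBDNA("AG"), pairStrands(buildBDNA("AG"),
                                                     "A", "B"))
  expect_equal(inv$pairs$nBondsCanonical, c(2, 3))  # A.T then G.C
  expect_true(all(inv$pairs$nBondsPresent == inv$pairs$nBondsCanonical))
  expect_true(all(inv$hbonds$distance > 2.5 & inv$hbonds$distance < 3.2))
})

test_that("classification is monotone in the cutoff", {
  rank <- c(absent = 0, non_watson_crick = 1, watson_crick = 2)
  dna <- perturbPair(buildBDNA("CCGAAAAAAAAAACGC"), 5, opening = -30)
  dna <- perturbPair(dna, 9, displacement = c(0, -3, 0))
  pairs <- pairStrands(dna, "A", "B")
  cuts <- c(2.2, 2.8, 3.5, 4.5, 6)
  cls <- sapply(cuts, function(ct)
    rank[hbondInventory(dna, pairs, cutoff = ct)$pairs$classification])
  for (i in seq_len(nrow(cls)))
    expect_true(all(diff(cls[i, ]) >= 0))
})

test_that("missing base atoms degrade gracefully with a warning", {
  dna <- buildBDNA("ACGT")
  a <- atoms(dna)
  a <- a[!(a$chain == "B" & a$resno == 4 & a$elety == "O4"), ]  # pair 1 T
  m <- modelFromAtoms(a)
  expect_warning(inv <- hbondInventory(m, pairStrands(m, "A", "B")),
                 "missing")
  expect_equal(inv$pairs$classification[1], "non_watson_crick")
})

test_that("base frames are antiparallel and centred for an ideal pair", {
  dna <- buildBDNA("ACGT")
  f <- clampscope:::pairFrames(dna,
                               pairStrands(dna, "A", "B")[1, ])
  # strand-2 frame after the flip convention shares the strand-1 z axis
  cosz <- sum(f$R1[, 3] * f$R2[, 3])
  expect_gt(cosz, cos(1 * pi / 180))
  # first pair of the builder sits at the global origin with identity frame
  expect_equal(f$origin, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(f$R, diag(3), tolerance = 1e-6)
})

test_that("a designed base rotation is recovered by the frame fit", {
  dna <- buildBDNA("CCGAAAAAAAAAACGC")
  bent <- perturbPair(dna, 7, opening = 25)
  g <- pairStepParameters(bent, pairStrands(bent, "A", "B"))
  expect_equal(abs(g$pairs$opening[7]), 25, tolerance = 0.5 / 25)
})

test_that("twist and opening are invariant under rigid-body motion", {
  set.seed(4)
  dna <- buildBDNA("ACGTACGTAC", twist = 34)
  moved <- transformModel(dna, randomRotation(), t = c(-20, 14, 9))
  g1 <- pairStepParameters(dna, pairStrands(dna, "A", "B"))
  g2 <- pairStepParameters(moved, pairStrands(moved, "A", "B"))
  expect_equal(g2$steps$twist, g1$steps$twist, tolerance = 1e-6)
  expect_equal(g2$pairs$opening, g1$pairs$opening, tolerance = 1e-6)
  gr1 <- grooveWidths(dna, "A", "B")
  gr2 <- grooveWidths(moved, "A", "B")
  expect_equal(gr2$minorWidth, gr1$minorWidth, tolerance = 1e-6)
})

test_that("step twists over one full helical repeat sum to 360 degrees", {
  dna <- buildBDNA("ACGTACGTACG")   # 11 bp -> 10 steps of 36 deg
  g <- pairStepParameters(dna, pairStrands(dna, "A", "B"))
  expect_equal(sum(g$steps$twist), 360, tolerance = 0.5 / 360)
})

test_that("groove widths are constant along an ideal duplex interior", {
  gr <- grooveWidths(buildBDNA("CCGAAAAAAAAAACGC"), "A", "B")
  expect_true(all(!gr$minorDefined[1:4]))   # window leaves the duplex
  minor <- gr$minorWidth[gr$minorDefined]
  major <- gr$majorWidth[gr$majorDefined]
  expect_lt(diff(range(minor)), 0.2)
  expect_lt(diff(range(major)), 0.2)
  expect_gt(mean(major), mean(minor))   # B-form: major groove wider
})

test_that("groove widths equal an exhaustive cross-strand P-P oracle", {
  dna <- buildBDNA("CCGAAAAAAAAAACGC")
  gr <- grooveWidths(dna, "A", "B")
  # independent literal oracle over the same stagger windows
  pairs <- pairStrands(dna, "A", "B")
  a <- atoms(dna)
  getP <- function(ch, rn) {
    r <- a[a$chain == ch & a$resno == rn & a$elety == "P", ]
    if (!nrow(r)) NULL else c(r$x, r$y, r$z)
  }
  L <- nrow(pairs)
  for (i in seq_len(L)) {
    for (set in list(c(-4, -3, -2), c(3, 4, 5))) {
      ds <- c()
      ok <- TRUE
      for (o in set) {
        j <- i + o
        if (j < 1 || j > L) { ok <- FALSE; break }
        p1 <- getP("A", pairs$resno1[i]); p2 <- getP("B", pairs$resno2[j])
        if (is.null(p1) || is.null(p2)) { ok <- FALSE; break }
        ds <- c(ds, sqrt(sum((p1 - p2)^2)))
      }
      expected <- if (ok) max(0, min(ds) - 5.8) else NA_real_
      got <- if (identical(set, c(-4, -3, -2))) gr$minorWidth[i] else
        gr$majorWidth[i]
      expect_equal(got, expected, tolerance = 1e-9)
    }
  }
})

test_that("too few phosphates is an error", {
  dna <- buildBDNA("ACGT")
  expect_error(grooveWidths(dna, "A", "B"), "4 phosphates")
})

test_that("the full geometry report is coherent", {
  g <- dnaGeometry(buildBDNA("CCGAAAAAAAAAACGC"), "A", "B")
  expect_named(g, c("pairs", "hbonds", "steps", "grooves"))
  expect_equal(nrow(g$pairs), 16)
  expect_equal(nrow(g$steps), 15)
  expect_equal(nrow(g$grooves), 16)
  expect_equal(sum(g$hbonds$present), sum(g$pairs$nBondsPresent))
})
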