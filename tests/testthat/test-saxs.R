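qGridTest <- seq(0, 0.3, by = 0.01)

test_that("a single carbon atom scatters as its squared form factor", {
  m <- pointModel(matrix(0, 1, 3), element = "C")
  p <- debyeProfile(m, q = qGridTest)
  # forward scattering = (electron count)^2 within tabulation accuracy
  expect_equal(intensities(p)[1], 36, tolerance = 0.2 / 36)
  f <- clampscope:::elementFormFactors("C", qGridTest, "vacuum")[, 1]
  expect_equal(intensities(p), unname(f^2), tolerance = 1e-12)
})

test_that("two unit point scatterers follow the closed form", {
  m <- pointModel(rbind(c(0, 0, 0), c(0, 0, 10)), element = "X")
  p <- debyeProfile(m, q = qGridTest)
  q <- qValues(p)
  expected <- 2 * (1 + ifelse(q == 0, 1, sin(10 * q) / (10 * q)))
  expect_equal(intensities(p), expected, tolerance = 1e-12)
})

test_that("the Debye calculator matches a literal double-sum oracle", {
  set.seed(42)
  n <- 50
  xyz <- matrix(rnorm(3 * n, sd = 8), ncol = 3)
  els <- sample(c("C", "N", "O", "P", "S"), n, replace = TRUE)
  m <- modelFromAtoms(data.frame(
    chain = "A", resno = seq_len(n), resname = "UNK", kind = "other",
    elety = els, element = els, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  p <- debyeProfile(m, q = qGridTest)
  # independent oracle: literal O(N^2) double sum
  F <- clampscope:::elementFormFactors(unique(els), qGridTest, "vacuum")
  oracle <- vapply(seq_along(qGridTest), function(k) {
    q <- qGridTest[k]
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      sinc <- if (q * r < 1e-12) 1 else sin(q * r) / (q * r)
      s <- s + F[k, els[i]] * F[k, els[j]] * sinc
    }
    s
  }, numeric(1))
  expect_equal(intensities(p), oracle, tolerance = 1e-10)
})

test_that("the Debye profile is invariant under rigid motion", {
  set.seed(1)
  m <- buildHelixBundle(2, 10)
  m2 <- transformModel(m, randomRotation(), t = c(12, -7, 30))
  p1 <- intensities(debyeProfile(m, q = qGridTest))
  p2 <- intensities(debyeProfile(m2, q = qGridTest))
  expect_equal(p2, p1, tolerance = 1e-9)
})

test_that("excluded-volume contrast reduces the effective scattering", {
  m <- buildHelixBundle(1, 10)
  iv <- intensities(debyeProfile(m, q = qGridTest))
  ie <- intensities(debyeProfile(m, q = qGridTest,
                                 contrast = "excluded_volume"))
  expect_lt(ie[1], iv[1])
  expect_true(all(is.finite(ie)))
})

test_that("all-unknown-element models are rejected", {
  m <- modelFromAtoms(data.frame(
    chain = "A", resno = 1, resname = "UNK", kind = "other",
    elety = "Q1", element = "Qq", x = 0, y = 0, z = 0))
  expect_error(suppressWarnings(debyeProfile(m)), "known element")
})

test_that("coordinate Rg matches closed-form cases", {
  two <- pointModel(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(coordinateRg(two, "uniform"), 5)
  shell <- pointModel(spherePoints(500, R = 10))
  expect_equal(coordinateRg(shell, "uniform"), 10, tolerance = 1e-3)
  expect_equal(coordinateRg(two, "uniform", shellDelta = 1.5), 6.5)
})

test_that("Guinier fit is exact on an exact Guinier-law profile", {
  q <- seq(0.002, 0.2, by = 0.002)
  p <- scatteringProfile(q, 250 * exp(-q^2 * 28.6^2 / 3))
  g <- guinierFit(p)
  expect_equal(g@rg, 28.6, tolerance = 1e-8)
  expect_equal(g@i0, 250, tolerance = 1e-8)
  expect_lte(g@qRange[2] * g@rg, 1.3 + 1e-9)
})

test_that("Guinier analysis of a uniform sphere gives sqrt(3/5) R", {
  g <- guinierFit(sphereProfile(R = 10))
  expect_equal(g@rg, sqrt(3 / 5) * 10, tolerance = 0.02)
})

test_that("Guinier analysis recovers a Gaussian-coil Rg", {
  # a coil departs from the Guinier law sooner than a globule: restrict
  # the window to q Rg <= 0.4 where the law holds to ~1 percent
  g <- guinierFit(coilProfile(rg = 27), qrgMax = 0.4)
  expect_equal(g@rg, 27, tolerance = 0.3 / 27)
})

test_that("Guinier errors are raised for unusable windows", {
  q <- seq(0.002, 0.05, by = 0.002)
  I <- 100 * exp(-q^2 * 28^2 / 3)
  I[3] <- -1                      # a bad point inside any low-q window
  expect_error(guinierFit(scatteringProfile(q, I)), "non-positive")
  expect_error(guinierFit(scatteringProfile(c(0.01, 0.02), c(1, 0.9))),
               "too few")
})

test_that("Guinier Rg of a computed profile matches the coordinate Rg", {
  for (spec in list(c(4, 12, 9), c(7, 10, 9))) {
    m <- buildHelixBundle(spec[1], spec[2], spacing = spec[3])
    p <- debyeProfile(m, q = seq(0.002, 0.12, by = 0.002))
    expect_equal(guinierFit(p)@rg, coordinateRg(m, "electron"),
                 tolerance = 0.02)
  }
})

test_that("chi-square is zero for a purely rescaled profile", {
  q <- seq(0.01, 0.3, length.out = 100)
  calc <- scatteringProfile(q, 50 * exp(-q^2 * 20^2 / 3))
  exper <- scatteringProfile(q, 2.5 * intensities(calc),
                             sigma = 0.01 * intensities(calc))
  r <- chi2Compare(exper, calc)
  expect_equal(r$chi2, 0, tolerance = 1e-20)
  expect_equal(r$scale, 2.5)
})

test_that("chi-square is near one for noise drawn at sigma", {
  set.seed(11)
  q <- seq(0.005, 0.3, length.out = 1000)
  I <- 1e4 * exp(-q^2 * 25^2 / 3)
  sig <- 0.02 * I
  exper <- scatteringProfile(q, I + rnorm(1000, 0, sig), sigma = sig)
  r <- chi2Compare(exper, scatteringProfile(q, I))
  expect_equal(r$chi2, 1, tolerance = 3 * sqrt(2 / 1000))
})

test_that("a mismatched conformer fits far worse than the matched one", {
  q <- seq(0.005, 0.25, length.out = 150)
  closed <- scatteringProfile(q, 1e4 * exp(-q^2 * 26.9^2 / 3))
  open <- scatteringProfile(q, 1e4 * exp(-q^2 * 32.2^2 / 3))
  exper <- simulateMixtureProfile(closed, open, 0, noiseLevel = 0.01,
                                  seed = 3)
  matched <- chi2Compare(exper, closed)$chi2
  mismatched <- chi2Compare(exper, open)$chi2
  expect_lt(matched, 3)
  expect_gt(mismatched, 10)
  expect_gt(mismatched, matched)
})

test_that("missing sigma is a guided error", {
  q <- seq(0.01, 0.1, length.out = 20)
  p <- scatteringProfile(q, exp(-q^2))
  expect_error(chi2Compare(p, p), "sigma")
})

test_that("two-state fit returns the endpoints for pure profiles", {
  q <- seq(0.005, 0.25, length.out = 100)
  closed <- scatteringProfile(q, 1e4 * exp(-q^2 * 26.9^2 / 3))
  open <- scatteringProfile(q, 1e4 * exp(-q^2 * 32.2^2 / 3))
  asExp <- function(p) scatteringProfile(q, intensities(p),
                                         sigma = 0.01 * intensities(p))
  expect_equal(twoStateFit(asExp(closed), closed, open)@fractionOpen, 0)
  expect_equal(twoStateFit(asExp(open), closed, open)@fractionOpen, 1)
})

test_that("the returned fraction is a local minimum of the chi2 grid", {
  q <- seq(0.005, 0.25, length.out = 100)
  closed <- scatteringProfile(q, 1e4 * exp(-q^2 * 26.9^2 / 3))
  open <- scatteringProfile(q, 1e4 * exp(-q^2 * 32.2^2 / 3))
  m <- simulateMixtureProfile(closed, open, 0.2, noiseLevel = 0.02, seed = 5)
  fit <- twoStateFit(m, closed, open)
  g <- fit@chi2Grid
  i <- which(g$fraction == fit@fractionOpen)
  if (i > 1) expect_lte(g$chi2[i], g$chi2[i - 1])
  if (i < nrow(g)) expect_lte(g$chi2[i], g$chi2[i + 1])
})

test_that("N-state fit reduces to chi2Compare for one component", {
  q <- seq(0.005, 0.25, length.out = 100)
  calc <- scatteringProfile(q, 1e4 * exp(-q^2 * 26.9^2 / 3))
  exper <- simulateMixtureProfile(calc, calc, 0, noiseLevel = 0.02, seed = 2)
  ns <- nStateFit(exper, list(calc))
  cc <- chi2Compare(exper, calc)
  expect_equal(ns$weights, 1)
  expect_equal(ns$chi2, cc$chi2, tolerance = 1e-10)
  expect_equal(ns$scale, cc$scale, tolerance = 1e-10)
})

test_that("N-state fit recovers three known weights exactly at zero noise", {
  q <- seq(0.005, 0.25, length.out = 120)
  comps <- lapply(c(22, 27, 34), function(rg)
    scatteringProfile(q, 1e4 * exp(-q^2 * rg^2 / 3)))
  w <- c(0.7, 0.2, 0.1)
  I <- Reduce(`+`, Map(function(p, wi) wi * intensities(p), comps, w))
  exper <- scatteringProfile(q, I, sigma = 0.01 * I)
  ns <- nStateFit(exper, comps)
  expect_equal(ns$weights, w, tolerance = 1e-6)
  expect_equal(ns$scale, 1, tolerance = 1e-6)
})

test_that("two-component N-state fit agrees with the grid scan", {
  q <- seq(0.005, 0.25, length.out = 100)
  closed <- scatteringProfile(q, 1e4 * exp(-q^2 * 26.9^2 / 3))
  open <- scatteringProfile(q, 1e4 * exp(-q^2 * 32.2^2 / 3))
  m <- simulateMixtureProfile(closed, open, 0.15, noiseLevel = 0.02,
                              seed = 9)
  ns <- nStateFit(m, list(closed, open))
  ts <- twoStateFit(m, closed, open)
  expect_lt(abs(ns$weights[2] - ts@fractionOpen), 0.005)  # the grid step
})

test_that("the apparent-Rg mixture formula behaves as printed", {
  expect_equal(rgMix(87.5, 12.5, 26.9, 32.2), 27.618, tolerance = 1e-3)
  expect_equal(rgMix(30, 70, 26.9, 26.9), 26.9)
  expect_equal(rgMix(87.5, 0, 26.9, 32.2), 26.9)
  expect_error(rgMix(0, 0, 26.9, 32.2))
})

test_that("apparent Rg brackets the components and is monotone in C_B", {
  set.seed(21)
  for (k in 1:20) {
    rgA <- runif(1, 15, 30); rgB <- runif(1, 15, 40)
    cA <- runif(1, 0, 100); cB <- runif(1, 0, 100)
    if (cA + cB == 0) next
    r <- rgMix(cA, cB, rgA, rgB)
    expect_gte(r, min(rgA, rgB) - 1e-12)
    expect_lte(r, max(rgA, rgB) + 1e-12)
  }
  # more of the larger minor conformer -> larger apparent Rg
  fr <- vapply(seq(0, 50, by = 10), function(cb)
    rgMix(100 - cb, cb, 26.9, 32.2), numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("profile files round-trip through the 3-column ASCII format", {
  q <- seq(0.01, 0.2, length.out = 30)
  p <- scatteringProfile(q, 1e3 * exp(-q^2 * 25^2 / 3),
                         sigma = 10 * exp(-q^2 * 25^2 / 6))
  f <- tempfile(fileext = ".dat")
  writeProfile(p, f, comment = "test profile")
  p2 <- readProfile(f)
  expect_equal(qValues(p2), qValues(p), tolerance = 1e-6)
  expect_equal(intensities(p2), intensities(p), tolerance = 1e-6)
  expect_equal(sigmas(p2), sigmas(p), tolerance = 1e-6)
})
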