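## Coordinate-based small-angle scattering: Debye-formula profiles, radii
## of gyration, Guinier analysis, chi-square comparison and conformer
## decomposition.
##
## The Debye double sum I(q) = sum_i sum_j f_i(q) f_j(q) sin(q r_ij)/(q r_ij)
## is evaluated exactly (O(N^2) over atom pairs); the structures this
## package targets are a few thousand heavy atoms, for which the exact sum
## takes seconds on one CPU.

DEFAULT_Q_GRID <- seq(0, 0.30, length.out = 301)
SOLVENT_EDENSITY <- 0.334  # e / A^3, bulk water

## atomic form factors f(q) for a vector of elements; matrix q x elements.
## Four-Gaussian coefficients use the s = q/(4 pi) convention.  With
## excluded-volume contrast the displaced-solvent term
## rho_s V exp(-pi V^(2/3) q^2) is subtracted.
elementFormFactors <- function(elements, q,
                               contrast = c("vacuum", "excluded_volume"),
                               solventDensity = SOLVENT_EDENSITY) {
  contrast <- match.arg(contrast)
  s2 <- (q / (4 * pi))^2
  out <- matrix(NA_real_, length(q), length(elements),
                dimnames = list(NULL, elements))
  for (el in elements) {
    d <- ELEMENT_DATA[el, ]
    f <- d$c + colSums(d$a[[1]] * exp(-outer(d$b[[1]], s2)))
    if (contrast == "excluded_volume")
      f <- f - solventDensity * d$volume * exp(-pi * d$volume^(2 / 3) * q^2)
    out[, el] <- f
  }
  out
}

## drop atoms unusable for scattering/mass computations
scatteringAtoms <- function(model, includeHydrogens = FALSE) {
  a <- atoms(model)
  if (!includeHydrogens) a <- a[a$element != "H", , drop = FALSE]
  known <- a$element %in% knownElements()
  if (!any(known)) stop("no atoms with a known element in the model")
  if (any(!known))
    warning(sum(!known), " atom(s) with unknown element dropped from the ",
            "calculation: ", paste(unique(a$element[!known]), collapse = ", "))
  a[known, , drop = FALSE]
}

#' Theoretical scattering profile from coordinates (Debye formula)
#'
#' Computes the orientationally averaged intensity
#' \deqn{I(q) = \sum_i \sum_j f_i(q) f_j(q) \frac{\sin(q r_{ij})}{q r_{ij}}}
#' with tabulated four-Gaussian atomic form factors.  With
#' \code{contrast = "excluded_volume"} each form factor is reduced by the
#' displaced-solvent term \eqn{\rho_s V_i \exp(-\pi V_i^{2/3} q^2)}.
#' Hydrogens are excluded by default (crystal structures typically have
#' none).  The result is deterministic and invariant under rigid motion of
#' the model.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param q momentum-transfer grid (1/Angstrom); may include q = 0, where
#'   the sinc limit gives \eqn{I(0) = (\sum_i f_i(0))^2}.
#' @param contrast \code{"vacuum"} (atomic factors as tabulated) or
#'   \code{"excluded_volume"}.
#' @param includeHydrogens include H atoms if present.
#' @param solventDensity bulk solvent electron density (e/A^3).
#' @returns A \linkS4class{ScatteringProfile} (no sigma).
#' @examples
#' bundle <- buildHelixBundle(2, 12)
#' prof <- debyeProfile(bundle, q = seq(0, 0.3, by = 0.01))
#' @seealso [guinierFit()], [coordinateRg()]
#' @export
debyeProfile <- function(model, q = DEFAULT_Q_GRID,
                         contrast = c("vacuum", "excluded_volume"),
                         includeHydrogens = FALSE,
                         solventDensity = SOLVENT_EDENSITY) {
  contrast <- match.arg(contrast)
  stopifnot(all(is.finite(q)), all(q >= 0))
  a <- scatteringAtoms(model, includeHydrogens)
  n <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  els <- unique(a$element)
  F <- elementFormFactors(els, q, contrast, solventDensity)
  ei <- match(a$element, els)
  I <- numeric(length(q))
  if (n == 1) {
    I <- F[, ei[1]]^2
    return(scatteringProfile(q, I))
  }
  d <- as.vector(stats::dist(xyz))
  pi_ <- rep(seq_len(n - 1), times = (n - 1):1)
  pj_ <- sequence((n - 1):1, from = 2:n)
  li <- ei[pi_]; lj <- ei[pj_]
  for (k in seq_along(q)) {
    fq <- F[k, ]
    qd <- q[k] * d
    sinc <- ifelse(qd < 1e-12, 1, sin(qd) / qd)
    I[k] <- sum(fq[ei]^2) + 2 * sum(fq[li] * fq[lj] * sinc)
  }
  scatteringProfile(q, I)
}

#' Radius of gyration from coordinates
#'
#' \eqn{R_g^2 = \sum w_i |r_i - \bar r|^2 / \sum w_i} with the weighted
#' centroid \eqn{\bar r}; weights are electron counts, atomic masses or
#' uniform.  Hydrogens are excluded by default.
#'
#' An optional uniform hydration-shell correction \code{shellDelta}
#' (Angstrom, default 0) is added to the returned value: program suites
#' that fit a hydration layer report slightly larger calculated Rg than
#' the bare-coordinate value, and comparisons against such values should
#' allow about 1 Angstrom.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param weighting \code{"electron"}, \code{"mass"} or \code{"uniform"}.
#' @param includeHydrogens include H atoms if present.
#' @param shellDelta additive hydration correction in Angstrom.
#' @returns Rg in Angstrom.
#' @examples
#' coordinateRg(buildHelixBundle(4, 20, spacing = 12))
#' @export
coordinateRg <- function(model, weighting = c("electron", "mass", "uniform"),
                         includeHydrogens = FALSE, shellDelta = 0) {
  weighting <- match.arg(weighting)
  a <- if (weighting == "uniform") {
    aa <- atoms(model)
    if (!includeHydrogens) aa <- aa[aa$element != "H", , drop = FALSE]
    aa
  } else scatteringAtoms(model, includeHydrogens)
  if (nrow(a) < 2) stop("need at least 2 atoms for a radius of gyration")
  w <- switch(weighting,
    electron = ELEMENT_DATA[a$element, "electrons"],
    mass = ELEMENT_DATA[a$element, "mass"],
    uniform = rep(1, nrow(a)))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ctr <- colSums(xyz * w) / sum(w)
  dev2 <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(w * dev2) / sum(w)) + shellDelta
}

#' Guinier analysis of a scattering profile
#'
#' Weighted linear fit of \eqn{\ln I} versus \eqn{q^2} over the largest
#' low-q window satisfying \eqn{q R_g \le} \code{qrgMax}, iterated to
#' self-consistency; \eqn{R_g = \sqrt{-3 \times \mathrm{slope}}}.
#'
#' @param profile a \linkS4class{ScatteringProfile}; if sigma is present
#'   the fit is weighted by \eqn{(I/\sigma)^2}.
#' @param qrgMax upper limit of \eqn{q R_g} for the fitted window
#'   (default 1.3, the conventional globular-particle limit).
#' @param minPoints minimum number of points required in the window.
#' @returns A \linkS4class{GuinierFit}.
#' @examples
#' qs <- seq(0.005, 0.2, by = 0.002)
#' p <- scatteringProfile(qs, 100 * exp(-qs^2 * 28.6^2 / 3))
#' guinierFit(p)
#' @export
guinierFit <- function(profile, qrgMax = 1.3, minPoints = 5L) {
  q <- profile@q; I <- profile@intensity
  s <- if (length(profile@sigma)) profile@sigma else NULL
  pos <- q > 0
  q <- q[pos]; I <- I[pos]; if (!is.null(s)) s <- s[pos]
  if (length(q) < minPoints) stop("too few points for a Guinier fit")
  fitWindow <- function(n) {
    qw <- q[1:n]; Iw <- I[1:n]
    if (any(Iw <= 0))
      stop("non-positive intensities in the Guinier window")
    w <- if (!is.null(s)) (Iw / s[1:n])^2 else rep(1, n)
    fit <- stats::lm(log(Iw) ~ I(qw^2), weights = w)
    slope <- stats::coef(fit)[2]
    if (!is.finite(slope) || slope >= 0)
      stop("Guinier fit has non-negative slope; profile is not ",
           "monotone at low q")
    list(rg = sqrt(-3 * slope), i0 = exp(stats::coef(fit)[1]),
         r2 = suppressWarnings(summary(fit)$r.squared))
  }
  n <- min(length(q), max(minPoints, 10L))
  f <- fitWindow(n)
  for (iter in 1:100) {
    nNew <- max(minPoints, sum(q * f$rg <= qrgMax))
    nNew <- min(nNew, length(q))
    if (nNew == n) break
    n <- nNew
    f <- fitWindow(n)
  }
  if (q[n] * f$rg > qrgMax && n <= minPoints)
    stop("admissible Guinier window (q Rg <= ", qrgMax, ") holds fewer ",
         "than ", minPoints, " points")
  new("GuinierFit", rg = unname(f$rg), i0 = unname(f$i0),
      qRange = c(q[1], q[n]), rSquared = f$r2, nPoints = as.integer(n))
}

## analytic weighted-least-squares scale and reduced chi-square
chi2Scale <- function(Iexp, Icalc, sigma) {
  c <- sum(Iexp * Icalc / sigma^2) / sum(Icalc^2 / sigma^2)
  chi2 <- sum(((Iexp - c * Icalc) / sigma)^2) / (length(Iexp) - 1)
  list(chi2 = chi2, scale = c)
}

#' Chi-square agreement between an experimental and a calculated profile
#'
#' \deqn{\chi^2 = \frac{1}{N-1} \sum_k
#'   \left(\frac{I_{exp}(q_k) - c I_{calc}(q_k)}{\sigma(q_k)}\right)^2}
#' with the scale \eqn{c} minimizing \eqn{\chi^2} in closed form.  When the
#' two q grids differ, the calculated profile is linearly interpolated onto
#' the experimental grid.
#'
#' @param experimental a \linkS4class{ScatteringProfile} with sigma.
#' @param calculated a \linkS4class{ScatteringProfile}.
#' @returns list with \code{chi2} and \code{scale}.
#' @export
chi2Compare <- function(experimental, calculated) {
  if (!length(experimental@sigma))
    stop("experimental profile has no sigma; supply uncertainties or ",
         "estimate them (e.g. with simulateMixtureProfile)")
  Icalc <- if (length(calculated@q) == length(experimental@q) &&
               all(abs(calculated@q - experimental@q) < 1e-9))
    calculated@intensity
  else {
    if (min(calculated@q) > min(experimental@q) ||
        max(calculated@q) < max(experimental@q))
      stop("calculated profile does not cover the experimental q range")
    stats::approx(calculated@q, calculated@intensity,
                  xout = experimental@q)$y
  }
  chi2Scale(experimental@intensity, Icalc, experimental@sigma)
}

#' Two-state decomposition of a scattering profile
#'
#' Fits the experimental profile as a scaled linear combination
#' \eqn{c[(1-w) I_{closed} + w I_{open}]} by exhaustive scan of the
#' fraction \eqn{w} over [0, 1] with per-fraction analytic scale; returns
#' the global minimum (ties resolved towards the smaller, more parsimonious
#' open fraction).
#'
#' @param experimental a \linkS4class{ScatteringProfile} with sigma.
#' @param closedCalc,openCalc calculated component profiles on the
#'   experimental q grid (closed = major/compact, open = minor/extended).
#' @param gridStep fraction grid step (default 0.005).
#' @returns A \linkS4class{TwoStateFit}.
#' @examples
#' qs <- seq(0.01, 0.25, length.out = 100)
#' closed <- scatteringProfile(qs, 100 * exp(-qs^2 * 26.9^2 / 3))
#' open <- scatteringProfile(qs, 100 * exp(-qs^2 * 32.2^2 / 3))
#' mix <- simulateMixtureProfile(closed, open, 0.125)
#' twoStateFit(mix, closed, open)
#' @export
twoStateFit <- function(experimental, closedCalc, openCalc,
                        gridStep = 0.005) {
  stopifnot(gridStep > 0, gridStep <= 0.5)
  for (p in list(closedCalc, openCalc))
    if (length(p@q) != length(experimental@q) ||
        any(abs(p@q - experimental@q) > 1e-9))
      stop("all three profiles must share one q grid")
  if (!length(experimental@sigma))
    stop("experimental profile has no sigma")
  ws <- seq(0, 1, by = gridStep)
  if (ws[length(ws)] < 1) ws <- c(ws, 1)
  chi2s <- vapply(ws, function(w) {
    Im <- (1 - w) * closedCalc@intensity + w * openCalc@intensity
    chi2Scale(experimental@intensity, Im, experimental@sigma)$chi2
  }, numeric(1))
  best <- which.min(chi2s)                 # ties -> smallest w (first)
  wBest <- ws[best]
  Im <- (1 - wBest) * closedCalc@intensity + wBest * openCalc@intensity
  sc <- chi2Scale(experimental@intensity, Im, experimental@sigma)
  tryRg <- function(p) tryCatch(guinierFit(p)@rg, error = function(e) NA_real_)
  new("TwoStateFit", fractionOpen = wBest, scale = sc$scale,
      chi2 = sc$chi2, rgClosed = tryRg(closedCalc), rgOpen = tryRg(openCalc),
      chi2Grid = data.frame(fraction = ws, chi2 = chi2s))
}

#' N-state decomposition by non-negative least squares
#'
#' Fits the experimental profile as a non-negative combination of
#' component profiles (sigma-weighted NNLS); the component coefficients
#' are normalized to weights summing to 1 plus an overall scale.  With two
#' components this agrees with [twoStateFit()] to within its grid step.
#'
#' @param experimental a \linkS4class{ScatteringProfile} with sigma.
#' @param components list of \linkS4class{ScatteringProfile}s on the
#'   experimental q grid.
#' @returns list with \code{weights} (non-negative, summing to 1),
#'   \code{scale} and \code{chi2}.
#' @export
nStateFit <- function(experimental, components) {
  stopifnot(length(components) >= 1)
  if (!length(experimental@sigma))
    stop("experimental profile has no sigma")
  for (p in components)
    if (length(p@q) != length(experimental@q) ||
        any(abs(p@q - experimental@q) > 1e-9))
      stop("all component profiles must share the experimental q grid")
  A <- vapply(components, function(p) p@intensity / experimental@sigma,
              numeric(length(experimental@q)))
  b <- experimental@intensity / experimental@sigma
  fit <- pracma::lsqnonneg(A, b)
  a <- fit$x
  if (sum(a) <= 0) stop("degenerate fit: all component coefficients zero")
  chi2 <- sum((b - as.vector(A %*% a))^2) / (length(b) - 1)
  list(weights = a / sum(a), scale = sum(a), chi2 = chi2)
}

#' Apparent radius of gyration of a two-conformer mixture
#'
#' For a mixture of conformers A and B at mass concentrations
#' \eqn{C_A, C_B} with radii of gyration \eqn{R_{gA}, R_{gB}},
#' \deqn{R_{g,app} = \sqrt{(C_A R_{gA}^2 + C_B R_{gB}^2)/(C_A + C_B)}.}
#' The result always lies between the two component radii, and increases
#' with \eqn{C_B} whenever \eqn{R_{gB} > R_{gA}}: an apparent Rg larger
#' than the major conformer's proves the minor conformer is larger still.
#'
#' @param cA,cB mass concentrations of the major (A) and minor (B)
#'   conformers (any common unit); non-negative, not both zero.
#' @param rgA,rgB component radii of gyration (Angstrom).
#' @returns Apparent Rg in Angstrom.
#' @examples
#' rgMix(87.5, 12.5, 26.9, 32.2)
#' @export
rgMix <- function(cA, cB, rgA, rgB) {
  stopifnot(cA >= 0, cB >= 0, rgA > 0, rgB > 0)
  if (cA + cB == 0) stop("concentrations must not both be zero")
  sqrt((cA * rgA^2 + cB * rgB^2) / (cA + cB))
}
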