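## Scattering-profile I/O and the mixture-profile simulator.

#' Read a 3-column ASCII scattering profile
#'
#' Expects the de facto SAXS exchange format: whitespace-separated columns
#' q (1/Angstrom), I and optionally sigma; lines starting with \code{#}
#' are comments.
#'
#' @param path file path.
#' @returns A \linkS4class{ScatteringProfile}.
#' @seealso [writeProfile()]
#' @export
readProfile <- function(path) {
  d <- utils::read.table(path, comment.char = "#", header = FALSE,
                         col.names = c("q", "I", "sigma")[1:3],
                         fill = TRUE)
  if (ncol(d) < 2) stop("profile must have at least two columns (q, I)")
  sig <- if (ncol(d) >= 3 && !all(is.na(d[[3]]))) d[[3]] else NULL
  scatteringProfile(d[[1]], d[[2]], sig)
}

#' Write a scattering profile as 3-column ASCII
#'
#' @param profile a \linkS4class{ScatteringProfile}.
#' @param path output file path.
#' @param comment optional header comment (written with a \code{#} prefix).
#' @returns \code{path}, invisibly.
#' @export
writeProfile <- function(profile, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines("# q(1/A)  I(q)  sigma", con)
  s <- if (length(profile@sigma)) profile@sigma else
    rep(NA_real_, length(profile@q))
  writeLines(sprintf("%.6e %.6e %s", profile@q, profile@intensity,
                     ifelse(is.na(s), "", sprintf("%.6e", s))), con)
  invisible(path)
}

#' Simulate a noisy two-component mixture scattering profile
#'
#' Generates \eqn{I(q) = (1-w) I_A(q) + w I_B(q)} plus zero-mean Gaussian
#' noise with standard deviation \code{noiseLevel * I(q)}.  This is the
#' generative counterpart of [twoStateFit()]: the mixing fraction \code{w}
#' is the known ground truth for recovery tests.  The sigma column is
#' populated with \code{noiseLevel * I(q)}; when \code{noiseLevel} is zero
#' a nominal 1 percent sigma is recorded so the profile remains usable in
#' chi-square fitting (the noise draw itself is still exactly zero).
#'
#' @param profileA,profileB component profiles on a common q grid
#'   (conventionally A = major/closed, B = minor/open).
#' @param fractionOpen mass fraction w of component B, in [0, 1].
#' @param noiseLevel relative noise level (sigma = noiseLevel * I).
#' @param seed optional integer seed for a reproducible noise draw.
#' @returns A \linkS4class{ScatteringProfile} with sigma set.
#' @examples
#' qs <- seq(0.01, 0.3, length.out = 50)
#' a <- scatteringProfile(qs, exp(-qs^2 * 26.9^2 / 3))
#' b <- scatteringProfile(qs, exp(-qs^2 * 32.2^2 / 3))
#' simulateMixtureProfile(a, b, fractionOpen = 0.125)
#' @export
simulateMixtureProfile <- function(profileA, profileB, fractionOpen,
                                   noiseLevel = 0, seed = NULL) {
  stopifnot(fractionOpen >= 0, fractionOpen <= 1, noiseLevel >= 0)
  if (length(profileA@q) != length(profileB@q) ||
      any(abs(profileA@q - profileB@q) > 1e-9))
    stop("component profiles must share one q grid")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  I <- (1 - fractionOpen) * profileA@intensity +
    fractionOpen * profileB@intensity
  sigma <- pmax(noiseLevel, 0.01) * abs(I)
  noise <- if (noiseLevel > 0) stats::rnorm(length(I), 0, noiseLevel * abs(I))
           else 0
  scatteringProfile(profileA@q, I + noise, sigma)
}
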