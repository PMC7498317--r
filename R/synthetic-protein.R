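## Toy helical protein assemblies: poly-alanine alpha helices on a regular
## lattice.  Used as ground-truth inputs for superposition, RMSD and
## scattering tests (a crude stand-in for coiled-coil bundles).

## ideal peptide geometry
PEP <- list(bNCa = 1.458, bCaC = 1.525, bCN = 1.329, bCO = 1.231,
            bCaCb = 1.530, aNCaC = 111.2, aCaCN = 116.2, aCNCa = 121.7,
            aCaCO = 120.8, aNCaCb = 110.4,
            phi = -57, psi = -47, omega = 180)

## one poly-Ala helix of m residues, principal axis aligned to z,
## centroid at origin; returns list of per-residue named coordinate rows
polyAlaHelix <- function(m) {
  N <- matrix(NA_real_, m, 3); CA <- N; C <- N; O <- N; CB <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(PEP$bNCa, 0, 0)
  C[1, ] <- placeAtom(c(-1, 1, 0), N[1, ], CA[1, ], PEP$bCaC, PEP$aNCaC, 60)
  for (i in seq_len(m)) {
    if (i < m) {
      N[i + 1, ] <- placeAtom(N[i, ], CA[i, ], C[i, ], PEP$bCN, PEP$aCaCN,
                              PEP$psi)
      CA[i + 1, ] <- placeAtom(CA[i, ], C[i, ], N[i + 1, ], PEP$bNCa,
                               PEP$aCNCa, PEP$omega)
      C[i + 1, ] <- placeAtom(C[i, ], N[i + 1, ], CA[i + 1, ], PEP$bCaC,
                              PEP$aNCaC, PEP$phi)
    }
    O[i, ] <- placeAtom(N[i, ], CA[i, ], C[i, ], PEP$bCO, PEP$aCaCO,
                        PEP$psi + 180)
    CB[i, ] <- placeAtom(C[i, ], N[i, ], CA[i, ], PEP$bCaCb, PEP$aNCaCb,
                         122.5)
  }
  xyz <- rbind(N, CA, C, O, CB)
  ## align principal axis of the CA trace with z
  ctr <- colMeans(CA)
  s <- svd(sweep(CA, 2, ctr))
  ax <- s$v[, 1]
  if (ax[3] < 0) ax <- -ax
  rot <- if (abs(sum(ax * c(0, 0, 1))) > 1 - 1e-12) diag(3) else
    rotAxis(pracma::cross(ax, c(0, 0, 1)),
            acos(sum(ax * c(0, 0, 1))) * 180 / pi)
  xyz <- t(rot %*% (t(xyz) - ctr))
  list(N = xyz[1:m, , drop = FALSE], CA = xyz[m + 1:m, , drop = FALSE],
       C = xyz[2 * m + 1:m, , drop = FALSE],
       O = xyz[3 * m + 1:m, , drop = FALSE],
       CB = xyz[4 * m + 1:m, , drop = FALSE])
}

#' Build a toy bundle of ideal poly-alanine alpha helices
#'
#' Generates \code{nHelices} identical poly-Ala helices (5 heavy atoms per
#' residue: N, CA, C, O, CB; ideal helical backbone with about 1.5
#' Angstrom rise and 100 degrees rotation per residue) placed on a regular
#' square lattice with the given spacing.  Deterministic; chains are
#' labelled A, B, C, ...
#'
#' @param nHelices number of helices (>= 1).
#' @param residuesPerHelix residues per helix (>= 2).
#' @param spacing lattice spacing between helix axes (Angstrom).
#' @returns A \linkS4class{StructureModel}.
#' @examples
#' buildHelixBundle(4, 20, spacing = 11)
#' @export
buildHelixBundle <- function(nHelices, residuesPerHelix, spacing = 10) {
  stopifnot(nHelices >= 1, residuesPerHelix >= 2, spacing > 0)
  h <- polyAlaHelix(residuesPerHelix)
  k <- ceiling(sqrt(nHelices))
  rows <- vector("list", nHelices)
  atomNames <- c("N", "CA", "C", "O", "CB")
  for (j in seq_len(nHelices)) {
    off <- c(((j - 1) %% k) * spacing, ((j - 1) %/% k) * spacing, 0)
    per <- lapply(seq_len(residuesPerHelix), function(i) {
      xyz <- rbind(h$N[i, ], h$CA[i, ], h$C[i, ], h$O[i, ], h$CB[i, ])
      xyz <- sweep(xyz, 2, off, `+`)
      data.frame(chain = LETTERS[j], resno = i, insert = "",
                 resname = "ALA", kind = "amino_acid", elety = atomNames,
                 element = c("N", "C", "C", "O", "C"),
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
                 stringsAsFactors = FALSE)
    })
    rows[[j]] <- do.call(rbind, per)
  }
  newStructureModel(do.call(rbind, rows), id = "helix_bundle",
                    metadata = list(nHelices = nHelices,
                                    residuesPerHelix = residuesPerHelix,
                                    spacing = spacing))
}
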