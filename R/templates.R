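## Internal chemical reference data: residue classification tables, atomic
## form factors and masses, standard base geometries and the idealized
## B-form sugar-phosphate backbone used by the duplex builder.

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "MSE", "PHE", "PRO", "SER", "THR",
            "TRP", "TYR", "VAL")
NUC_NAMES <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "T", "U",
               "ADE", "CYT", "GUA", "THY", "URA")

residueKind <- function(resname) {
  rn <- toupper(trimws(resname))
  out <- rep("other", length(rn))
  out[rn %in% AMINO3] <- "amino_acid"
  out[rn %in% NUC_NAMES] <- "nucleotide"
  out
}

## one-letter base code from a nucleotide residue name
baseCode <- function(resname) {
  rn <- toupper(trimws(resname))
  map <- c(DA = "A", DC = "C", DG = "G", DT = "T", DU = "U",
           A = "A", C = "C", G = "G", T = "T", U = "U",
           ADE = "A", CYT = "C", GUA = "G", THY = "T", URA = "U")
  unname(map[rn])
}

## ---- element data ------------------------------------------------------
## Four-Gaussian X-ray form-factor coefficients f(q) = c + sum a_k
## exp(-b_k (q/4pi)^2) (International Tables vol. C convention), electron
## counts, average atomic masses (u) and displaced solvent volumes (A^3,
## Fraser-style).  "X" is a unit point scatterer (f = 1) used for analytic
## test cases.
ELEMENT_DATA <- local({
  d <- data.frame(
    element = c("H", "C", "N", "O", "P", "S", "X"),
    electrons = c(1, 6, 7, 8, 15, 16, 1),
    mass = c(1.008, 12.011, 14.007, 15.999, 30.974, 32.06, 1),
    volume = c(5.15, 16.44, 2.49, 9.13, 5.73, 19.86, 0)
  )
  d$a <- list(
    c(0.489918, 0.262003, 0.196767, 0.049879),
    c(2.31000, 1.02000, 1.58860, 0.865000),
    c(12.2126, 3.13220, 2.01250, 1.16630),
    c(3.04850, 2.28680, 1.54630, 0.867000),
    c(6.43450, 4.17910, 1.78000, 1.49080),
    c(6.90530, 5.20340, 1.43790, 1.58630),
    c(0, 0, 0, 0))
  d$b <- list(
    c(20.6593, 7.74039, 49.5519, 2.20159),
    c(20.8439, 10.2075, 0.568700, 51.6512),
    c(0.005700, 9.89330, 28.9975, 0.582600),
    c(13.2771, 5.70110, 0.323900, 32.9089),
    c(1.90670, 27.1570, 0.526000, 68.1645),
    c(1.46790, 22.2151, 0.253600, 56.1720),
    c(0, 0, 0, 0))
  d$c <- c(0.001305, 0.215600, -11.529, 0.250800, 1.11490, 0.866900, 1)
  rownames(d) <- d$element
  d
})

knownElements <- function() ELEMENT_DATA$element

## guess element from a PDB atom name when the element column is absent
elementFromName <- function(elety) {
  e <- toupper(sub("^[0-9']*", "", trimws(elety)))
  first <- substr(e, 1, 1)
  ifelse(first %in% c("C", "N", "O", "P", "S", "H"), first, e)
}

## ---- average residue masses (u) ---------------------------------------
## Amino acid residue masses are taken from seqinr at call time; DNA uses
## standard average nucleotide-monophosphate residue masses with 5'-OH
## termini (the convention for synthetic oligonucleotides):
## MW(strand) = sum(residue) - 61.96.
NUCLEOTIDE_MASS <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)
OLIGO_5OH_CORRECTION <- 61.96

## ---- standard base geometries -----------------------------------------
## Heavy-atom coordinates of the four bases (plus the attached C1') in the
## standard base-pair reference frame: the base lies in the z = 0 plane,
## x points into the major groove along the pseudo-dyad, y along the long
## axis towards strand 1, and the complementary base of a Watson-Crick pair
## is obtained by the 180-degree rotation about x, i.e. (x, -y, -z).
BASE_TEMPLATES <- list(
  A = rbind(
    `C1'` = c(-2.479, 5.346, 0), N9 = c(-1.291, 4.498, 0),
    C8 = c(0.024, 4.897, 0), N7 = c(0.877, 3.902, 0),
    C5 = c(0.071, 2.771, 0), C6 = c(0.369, 1.398, 0),
    N6 = c(1.611, 0.909, 0), N1 = c(-0.668, 0.532, 0),
    C2 = c(-1.912, 1.023, 0), N3 = c(-2.320, 2.290, 0),
    C4 = c(-1.267, 3.124, 0)),
  G = rbind(
    `C1'` = c(-2.477, 5.399, 0), N9 = c(-1.289, 4.551, 0),
    C8 = c(0.023, 4.962, 0), N7 = c(0.870, 3.969, 0),
    C5 = c(0.071, 2.833, 0), C6 = c(0.424, 1.460, 0),
    O6 = c(1.554, 0.955, 0), N1 = c(-0.700, 0.641, 0),
    C2 = c(-1.999, 1.087, 0), N2 = c(-2.949, 0.139, 0),
    N3 = c(-2.342, 2.364, 0), C4 = c(-1.265, 3.177, 0)),
  C = rbind(
    `C1'` = c(-2.477, 5.402, 0), N1 = c(-1.285, 4.542, 0),
    C2 = c(-1.472, 3.158, 0), O2 = c(-2.628, 2.709, 0),
    N3 = c(-0.391, 2.344, 0), C4 = c(0.837, 2.868, 0),
    N4 = c(1.875, 2.027, 0), C5 = c(1.056, 4.275, 0),
    C6 = c(-0.023, 5.068, 0)),
  T = rbind(
    `C1'` = c(-2.481, 5.354, 0), N1 = c(-1.284, 4.500, 0),
    C2 = c(-1.462, 3.135, 0), O2 = c(-2.562, 2.608, 0),
    N3 = c(-0.298, 2.407, 0), C4 = c(0.994, 2.897, 0),
    O4 = c(1.944, 2.119, 0), C5 = c(1.106, 4.338, 0),
    C7 = c(2.466, 4.961, 0), C6 = c(-0.024, 5.057, 0))
)

## ring atoms used for least-squares base-frame fitting
BASE_RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6"))

WC_COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

## canonical Watson-Crick hydrogen bonds, written donor-acceptor with the
## strand carrying each atom ("1" = purine strand side of the designed
## type's first letter).  Labels follow the usual purine-pyrimidine order.
WC_HBONDS <- list(
  # A.T: N6(A)-O4(T) and N1(A)-N3(T) (N3 of T is the donor)
  `A:T` = data.frame(label = c("N1-N3", "N6-O4"),
                     atom1 = c("N1", "N6"), atom2 = c("N3", "O4"),
                     donorSide = c(2L, 1L)),
  # G.C: O6(G)-N4(C), N1(G)-N3(C) (N1 of G donor), N2(G)-O2(C)
  `G:C` = data.frame(label = c("N1-N3", "O6-N4", "N2-O2"),
                     atom1 = c("N1", "O6", "N2"), atom2 = c("N3", "N4", "O2"),
                     donorSide = c(1L, 2L, 1L))
)

## ---- idealized B-form sugar-phosphate backbone -------------------------
## Local base-pair-frame coordinates of the strand-1 backbone heavy atoms of
## one nucleotide, derived once by restrained least-squares under the
## 36 deg / 3.38 A helical symmetry: standard bond lengths and angles,
## C2'-endo-like sugar, anti glycosidic torsion, chain closure
## O3'(i)-P(i+1) = 1.60 A, canonical phosphate radius and canonical
## cross-strand phosphate separations (11.5 A minor side, 17.7 A major
## side).  Strand 2 uses the (x, -y, -z) image.  C1' here supersedes the
## per-base C1' of BASE_TEMPLATES so that all four residue types share one
## backbone.
BACKBONE_TEMPLATE <- rbind(
  P     = c(-1.6315, 9.1155, -0.9518),
  OP1   = c(-1.6251, 10.4427, -0.2858),
  OP2   = c(-1.9943, 9.0174, -2.3885),
  `O5'` = c(-2.5826, 8.1638, -0.1360),
  `C5'` = c(-2.3242, 8.0648, 1.2460),
  `C4'` = c(-2.8920, 6.8119, 1.8127),
  `O4'` = c(-2.0157, 5.8880, 1.2321),
  `C3'` = c(-4.2420, 6.3404, 1.3229),
  `O3'` = c(-5.0883, 6.6149, 2.4683),
  `C2'` = c(-3.8884, 5.0331, 0.5131),
  `C1'` = c(-2.4800, 5.3500, 0.0000))

DNA_BACKBONE_ATOMS <- rownames(BACKBONE_TEMPLATE)

## phosphate-group atoms used for protein-DNA contact inventories
PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "O5'", "O3'")

## protein backbone heavy atoms
BACKBONE_PROTEIN <- c("N", "CA", "C", "O")
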