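## Synthetic B-form DNA duplex builder.  Residues are assembled from
## standard-reference-frame base geometries plus an idealized
## sugar-phosphate backbone, placed on an ideal helix.  The generator is the
## ground-truth oracle for the DNA geometry module: designed twist, rise,
## propeller and opening are recovered exactly by construction.

## local heavy-atom template (named matrix) for one residue of given base,
## strand 1, in the base-pair reference frame
residueTemplate <- function(base) {
  b <- BASE_TEMPLATES[[base]]
  rbind(BACKBONE_TEMPLATE, b[setdiff(rownames(b), "C1'"), , drop = FALSE])
}

dnaElementFromAtom <- function(elety) substr(elety, 1, 1)

#' Build an ideal (optionally perturbed) B-form DNA duplex
#'
#' Constructs a full-heavy-atom double helix for an arbitrary sequence.
#' Strand 1 is the given sequence 5' to 3' (chain \code{A}, residues
#' numbered 1..L); strand 2 is its Watson-Crick complement, antiparallel
#' (chain \code{B}, also numbered 5' to 3', so residue j of strand 2 pairs
#' with residue L+1-j of strand 1).  Each base pair is placed on an ideal
#' helix with the given per-step twist and rise; per-pair propeller and
#' opening perturbations are applied symmetrically to the two bases of a
#' pair.  5' termini carry no phosphate group (synthetic-oligonucleotide
#' convention).  In the unperturbed duplex every designed pair forms all of
#' its canonical Watson-Crick hydrogen bonds within 3.5 Angstrom.
#'
#' @param sequence strand-1 sequence, 5' to 3', over \code{A C G T}.
#' @param twist helical twist per step in degrees; scalar or length L-1.
#'   Default 36, the canonical B-form value.
#' @param rise rise per step in Angstrom; scalar or length L-1.  Default
#'   3.38 (canonical B-form).
#' @param propeller per-pair propeller twist perturbation in degrees;
#'   scalar or length L.  Default 0.
#' @param opening per-pair opening perturbation in degrees; scalar or
#'   length L.  Default 0.
#' @param chains length-2 character, chain ids for the two strands.
#' @param id model identifier.
#' @returns A \linkS4class{StructureModel}.
#' @examples
#' dna <- buildBDNA("CCGAAAAAAAAAACGC")
#' dna
#' @seealso [perturbPair()], [dnaGeometry()]
#' @export
buildBDNA <- function(sequence, twist = 36, rise = 3.38, propeller = 0,
                      opening = 0, chains = c("A", "B"), id = "bdna") {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(seq1) < 2) stop("sequence must have at least 2 bases")
  bad <- setdiff(unique(seq1), c("A", "C", "G", "T"))
  if (length(bad)) stop("invalid base(s) in sequence: ",
                        paste(bad, collapse = ", "))
  L <- length(seq1)
  comp <- WC_COMPLEMENT[seq1]          # complement base at each pair level
  expand <- function(x, n, what) {
    if (length(x) == 1) rep(x, n)
    else if (length(x) == n) x
    else stop(what, " must be scalar or length ", n)
  }
  twist <- expand(twist, L - 1, "twist")
  rise <- expand(rise, L - 1, "rise")
  propeller <- expand(propeller, L, "propeller")
  opening <- expand(opening, L, "opening")
  theta <- cumsum(c(0, twist))
  zoff <- cumsum(c(0, rise))
  FLIP <- diag(c(1, -1, -1))

  rows <- vector("list", 2 * L)
  for (i in seq_len(L)) {
    G <- rotZ(theta[i])
    shift <- c(0, 0, zoff[i])
    for (strand in 1:2) {
      base <- if (strand == 1) seq1[i] else comp[i]
      tpl <- residueTemplate(base)
      loc <- if (strand == 1) tpl else t(FLIP %*% t(tpl))
      isBase <- !(rownames(tpl) %in% DNA_BACKBONE_ATOMS)
      half <- if (strand == 1) 0.5 else -0.5
      pert <- rotAxis(c(0, 0, 1), half * opening[i]) %*%
        rotAxis(c(0, 1, 0), half * propeller[i])
      loc[isBase, ] <- t(pert %*% t(loc[isBase, , drop = FALSE]))
      glob <- t(G %*% t(loc) + shift)
      resno <- if (strand == 1) i else L + 1L - i
      isP5 <- rownames(tpl) %in% c("P", "OP1", "OP2")
      keep <- if ((strand == 1 && i == 1) || (strand == 2 && i == L))
        !isP5 else rep(TRUE, nrow(tpl))   # 5'-OH termini
      rows[[(i - 1) * 2 + strand]] <- data.frame(
        chain = chains[strand], resno = resno, insert = "",
        resname = paste0("D", base), kind = "nucleotide",
        elety = rownames(tpl)[keep],
        element = dnaElementFromAtom(rownames(tpl)[keep]),
        x = glob[keep, 1], y = glob[keep, 2], z = glob[keep, 3],
        occ = 1, b = 0, stringsAsFactors = FALSE)
    }
  }
  a <- do.call(rbind, rows)
  ## file order: strand 1 residues 1..L, then strand 2 residues 1..L
  a <- a[order(match(a$chain, chains), a$resno), ]
  newStructureModel(a, id = id,
                    metadata = list(sequence = sequence, twist = twist,
                                    rise = rise, chains = chains))
}

#' Rigidly displace or rotate one base of a duplex pair
#'
#' Creates broken or distorted base pairs with known ground truth: the
#' named base (default: the strand-2 base) of one designed pair is moved as
#' a rigid unit while every other atom is left untouched.  A displacement
#' is applied in the base-pair reference frame of the unperturbed pair
#' (x into the major groove, y along the long axis, z along the helix);
#' a rotation (\code{opening}) is applied about the pair z axis through
#' the pair origin.
#'
#' @param model a duplex built by [buildBDNA()] (two nucleotide chains).
#' @param pairIndex 1-based pair position along strand 1.
#' @param displacement optional numeric(3) displacement in Angstrom (pair
#'   frame).
#' @param opening optional rotation in degrees about the pair z axis.
#' @param strand which base of the pair to move (1 or 2).
#' @returns A new \linkS4class{StructureModel}.
#' @examples
#' dna <- buildBDNA("CCGAAAAAAAAAACGC")
#' broken <- perturbPair(dna, 3, displacement = c(0, 5, 0))
#' @export
perturbPair <- function(model, pairIndex, displacement = NULL,
                        opening = NULL, strand = 2) {
  stopifnot(is(model, "StructureModel"))
  ch <- model@metadata$chains
  if (is.null(ch)) {
    ch <- unique(atoms(model)$chain[atoms(model)$kind == "nucleotide"])
    if (length(ch) != 2) stop("model must contain exactly two DNA strands")
  }
  a <- atoms(model)
  L <- sum(a$chain == ch[1] & a$elety == "C1'")
  if (pairIndex < 1 || pairIndex > L) stop("pair index out of range [1, ", L, "]")
  resno <- if (strand == 1) pairIndex else L + 1L - pairIndex
  chain <- ch[strand]
  sel <- a$chain == chain & a$resno == resno &
    !(a$elety %in% DNA_BACKBONE_ATOMS)
  if (!any(sel)) stop("no base atoms found for pair ", pairIndex,
                      " on strand ", strand)
  frame <- pairReferenceFrame(model, ch[1], ch[2], pairIndex)
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  if (!is.null(opening)) {
    Rloc <- rotAxis(c(0, 0, 1), opening)
    Rg <- frame$R %*% Rloc %*% t(frame$R)
    xyz <- t(Rg %*% (t(xyz) - frame$origin) + frame$origin)
  }
  if (!is.null(displacement)) {
    stopifnot(length(displacement) == 3)
    xyz <- sweep(xyz, 2, as.vector(frame$R %*% displacement), `+`)
  }
  a[sel, c("x", "y", "z")] <- xyz
  newStructureModel(a, id = model@id, metadata = model@metadata)
}
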