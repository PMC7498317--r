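## Rigid-body superposition and RMSD over arbitrary selections, plus
## interface inventories: inter-chain salt bridges and protein residues in
## contact with DNA phosphate groups.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two correspondence-ordered coordinate sets.
#'
#' @param reference,mobile numeric n x 3 matrices (or atom tables from
#'   [selectAtoms()]), row i of one corresponding to row i of the other;
#'   n >= 3 and not collinear.
#' @returns A \linkS4class{SuperpositionResult}; applying
#'   \code{rotation \%*\% x + translation} to the mobile coordinates
#'   reproduces the reported RMSD against the reference.
#' @examples
#' m <- coords(buildHelixBundle(1, 10))
#' superpose(m, m)
#' @export
superpose <- function(reference, mobile) {
  asXYZ <- function(x) {
    if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
    stopifnot(is.numeric(x), ncol(x) == 3)
    unname(x)
  }
  ref <- asXYZ(reference); mob <- asXYZ(mobile)
  if (nrow(ref) != nrow(mob))
    stop("reference and mobile must have the same number of atoms (",
         nrow(ref), " vs ", nrow(mob), ")")
  if (nrow(ref) < 3) stop("need at least 3 atom pairs")
  sv <- svd(sweep(ref, 2, colMeans(ref)))$d
  if (sv[2] < 1e-8 * sv[1])
    stop("degenerate (collinear) reference coordinates")
  k <- kabsch(mob, ref)
  fitted <- sweep(mob %*% t(k$R), 2, k$t, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - ref)^2)))
  new("SuperpositionResult", rotation = k$R, translation = k$t,
      rmsd = rmsd, nAtoms = nrow(ref))
}

#' RMSD between selections of two models
#'
#' Builds the atom correspondence from two selections and superposes them.
#' With \code{pairing = "by_order"} atoms are paired in file order (the
#' two selections must have equal size); with \code{"by_residue_number"}
#' atoms are matched on (residue number, insertion code, atom name) --
#' and on chain id when a selection spans several chains -- and unmatched
#' residues raise an error naming them.
#'
#' @param model1,model2 \linkS4class{StructureModel}s (reference, mobile).
#' @param sel1,sel2 [atomSelection()]s applied to each model.
#' @param pairing correspondence rule.
#' @returns A \linkS4class{SuperpositionResult}.
#' @examples
#' b <- buildHelixBundle(2, 10)
#' bb <- atomSelection(atomNames = c("N", "CA", "C", "O"))
#' rmsdBetweenModels(b, bb, b, bb)
#' @export
rmsdBetweenModels <- function(model1, sel1 = atomSelection(),
                              model2 = model1, sel2 = sel1,
                              pairing = c("by_order", "by_residue_number")) {
  pairing <- match.arg(pairing)
  a1 <- selectAtoms(model1, sel1)
  a2 <- selectAtoms(model2, sel2)
  if (!nrow(a1) || !nrow(a2)) stop("empty selection")
  if (pairing == "by_order") {
    if (nrow(a1) != nrow(a2))
      stop("selections resolve to different atom counts (", nrow(a1),
           " vs ", nrow(a2), ") under by_order pairing")
  } else {
    useChain <- length(unique(a1$chain)) > 1 || length(unique(a2$chain)) > 1
    key <- function(a) if (useChain)
      paste(a$chain, a$resno, a$insert, a$elety) else
      paste(a$resno, a$insert, a$elety)
    k1 <- key(a1); k2 <- key(a2)
    common <- intersect(k1, k2)
    miss <- c(setdiff(k1, k2), setdiff(k2, k1))
    if (length(miss))
      stop("unmatched atoms under by_residue_number pairing: ",
           paste(utils::head(miss, 10), collapse = "; "),
           if (length(miss) > 10) " ...")
    a1 <- a1[match(common, k1), ]
    a2 <- a2[match(common, k2), ]
  }
  superpose(a1, a2)
}

SALT_BASIC <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
SALT_BASIC_HIS <- list(HIS = c("ND1", "NE2"))
SALT_ACIDIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Inter-group salt bridges
#'
#' Detects residue-pair salt bridges between two disjoint chain groups:
#' a basic side-chain nitrogen (Lys NZ; Arg NE/NH1/NH2; optionally His
#' ND1/NE2) within \code{cutoff} of an acidic side-chain oxygen (Asp
#' OD1/OD2; Glu OE1/OE2; optionally the C-terminal OXT).  One bridge is
#' reported per (basic residue, acidic residue) pair, with the closest
#' qualifying atom pair; ordering is deterministic (chain, residue
#' number).
#'
#' @param model a \linkS4class{StructureModel}.
#' @param groupA,groupB disjoint character vectors of chain ids.
#' @param cutoff nitrogen-oxygen distance cutoff in Angstrom (default 4.0,
#'   a widely used convention).
#' @param includeHis count histidine as a basic partner (default FALSE:
#'   protonation is usually unknown).
#' @param includeTermini count C-terminal OXT as an acidic partner.
#' @returns data.frame, one row per bridge: residue identifiers of both
#'   partners, closest atom names and their distance.
#' @export
findSaltBridges <- function(model, groupA, groupB, cutoff = 4.0,
                            includeHis = FALSE, includeTermini = FALSE) {
  stopifnot(cutoff > 0)
  if (length(intersect(groupA, groupB)))
    stop("chain groups must be disjoint")
  a <- atoms(model)
  basicDef <- c(SALT_BASIC, if (includeHis) SALT_BASIC_HIS)
  pick <- function(chains, def) {
    keep <- a$chain %in% chains & a$kind == "amino_acid" &
      mapply(function(rn, at) at %in% (def[[rn]] %||% character()),
             a$resname, a$elety)
    a[keep, , drop = FALSE]
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  basic <- rbind(pick(groupA, basicDef), pick(groupB, basicDef))
  acidic <- rbind(pick(groupA, SALT_ACIDIC), pick(groupB, SALT_ACIDIC))
  if (includeTermini) {
    oxt <- a[a$chain %in% c(groupA, groupB) & a$elety == "OXT", ,
             drop = FALSE]
    acidic <- rbind(acidic, oxt)
  }
  out <- list()
  if (nrow(basic) && nrow(acidic)) {
    groupOf <- function(ch) ifelse(ch %in% groupA, "A", "B")
    D <- pracma::distmat(as.matrix(basic[, c("x", "y", "z")]),
                         as.matrix(acidic[, c("x", "y", "z")]))
    hits <- which(D <= cutoff, arr.ind = TRUE)
    if (nrow(hits)) {
      df <- data.frame(
        chainBasic = basic$chain[hits[, 1]],
        resnoBasic = basic$resno[hits[, 1]],
        resnameBasic = basic$resname[hits[, 1]],
        atomBasic = basic$elety[hits[, 1]],
        chainAcidic = acidic$chain[hits[, 2]],
        resnoAcidic = acidic$resno[hits[, 2]],
        resnameAcidic = acidic$resname[hits[, 2]],
        atomAcidic = acidic$elety[hits[, 2]],
        distance = D[hits], stringsAsFactors = FALSE)
      df <- df[groupOf(df$chainBasic) != groupOf(df$chainAcidic), ,
               drop = FALSE]
      if (nrow(df)) {
        key <- paste(df$chainBasic, df$resnoBasic, df$chainAcidic,
                     df$resnoAcidic)
        df <- df[order(key, df$distance), ]
        df <- df[!duplicated(paste(df$chainBasic, df$resnoBasic,
                                   df$chainAcidic, df$resnoAcidic)), ]
        out <- df[order(df$chainBasic, df$resnoBasic, df$chainAcidic,
                        df$resnoAcidic), ]
      }
    }
  }
  if (!length(out))
    out <- data.frame(chainBasic = character(), resnoBasic = integer(),
                      resnameBasic = character(), atomBasic = character(),
                      chainAcidic = character(), resnoAcidic = integer(),
                      resnameAcidic = character(), atomAcidic = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Protein residues contacting DNA phosphate groups
#'
#' Lists every protein residue with a qualifying atom within \code{cutoff}
#' of any DNA phosphate-group atom (P, OP1, OP2, O5', O3'), with its
#' minimum distance; sorted by chain then residue number.  With
#' \code{atoms = "side_chain"} the protein backbone (N, CA, C, O) is
#' excluded, matching the electrostatics-driven reading of such contacts.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param proteinChains,dnaChains chain id vectors.
#' @param cutoff contact distance cutoff in Angstrom (default 5.5).
#' @param atoms \code{"side_chain"} or \code{"all"}.
#' @returns data.frame: \code{chain}, \code{resno}, \code{resname},
#'   \code{minDistance}.
#' @export
dnaContactResidues <- function(model, proteinChains, dnaChains,
                               cutoff = 5.5,
                               atoms = c("side_chain", "all")) {
  atoms <- match.arg(atoms)
  stopifnot(cutoff >= 0)
  a <- model@atoms
  phos <- a[a$chain %in% dnaChains & a$kind == "nucleotide" &
              a$elety %in% PHOSPHATE_ATOMS, , drop = FALSE]
  if (!nrow(phos)) stop("no phosphate-group atoms found in DNA chains")
  prot <- a[a$chain %in% proteinChains & a$kind == "amino_acid", ,
            drop = FALSE]
  if (atoms == "side_chain")
    prot <- prot[!(prot$elety %in% BACKBONE_PROTEIN), , drop = FALSE]
  if (!nrow(prot))
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), minDistance = numeric()))
  D <- pracma::distmat(as.matrix(prot[, c("x", "y", "z")]),
                       as.matrix(phos[, c("x", "y", "z")]))
  dmin <- apply(D, 1, min)
  key <- paste(prot$chain, prot$resno, prot$insert)
  agg <- tapply(dmin, key, min)
  first <- !duplicated(key)
  res <- data.frame(chain = prot$chain[first], resno = prot$resno[first],
                    resname = prot$resname[first],
                    minDistance = as.numeric(agg[key[first]]),
                    stringsAsFactors = FALSE)
  res <- res[res$minDistance <= cutoff, , drop = FALSE]
  res <- res[order(res$chain, res$resno), ]
  rownames(res) <- NULL
  res
}
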