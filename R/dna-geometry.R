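## DNA duplex geometry: base pairing, Watson-Crick hydrogen-bond
## inventories, base-pair and step parameters (opening, propeller, twist,
## rise) from standard-reference-frame base fitting, and phosphate-based
## groove widths.
##
## Convention: base frames are obtained by least-squares superposition of
## the standard reference base onto the observed base ring atoms; pair and
## step parameters use the conventional mid-frame angular decomposition
## (the 3DNA-style scheme).  Groove widths use the refined
## phosphate-phosphate convention: minimal cross-strand P-P distance within
## the characteristic stagger window minus 5.8 A backbone correction.

GROOVE_BACKBONE_CORRECTION <- 5.8
GROOVE_MINOR_OFFSETS <- c(-4, -3, -2)
GROOVE_MAJOR_OFFSETS <- c(3, 4, 5)

#' Pair the residues of two antiparallel DNA strands
#'
#' Residue i of strand 1 (in 5'-3' order of ascending residue number) is
#' paired with residue L+1-i of strand 2.  The register is validated by
#' requiring a C1'-C1' distance below 15 Angstrom for the majority of
#' pairs.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param chain1,chain2 chain ids of the two strands.
#' @returns data.frame with one row per designed pair: \code{index},
#'   residue identifiers of both partners, one-letter base codes,
#'   \code{designedType} (e.g. \code{"A:T"}) and the C1'-C1' distance.
#' @examples
#' pairStrands(buildBDNA("ACGT"), "A", "B")
#' @export
pairStrands <- function(model, chain1, chain2) {
  a <- atoms(model)
  res <- function(ch) {
    r <- unique(a[a$chain == ch & a$kind == "nucleotide",
                  c("chain", "resno", "insert", "resname")])
    if (!nrow(r)) stop("chain ", ch, " has no nucleotide residues")
    r[order(r$resno), ]
  }
  r1 <- res(chain1); r2 <- res(chain2)
  if (nrow(r1) != nrow(r2))
    stop("strands differ in length (", nrow(r1), " vs ", nrow(r2), ")")
  L <- nrow(r1)
  r2 <- r2[L:1, ]                      # antiparallel register
  b1 <- baseCode(r1$resname); b2 <- baseCode(r2$resname)
  c1c1 <- vapply(seq_len(L), function(i) {
    p1 <- residueCoords(model, chain1, r1$resno[i], r1$insert[i])
    p2 <- residueCoords(model, chain2, r2$resno[i], r2$insert[i])
    if (!("C1'" %in% rownames(p1)) || !("C1'" %in% rownames(p2)))
      return(NA_real_)
    vnorm(p1["C1'", ] - p2["C1'", ])
  }, numeric(1))
  ok <- sum(c1c1 < 15, na.rm = TRUE)
  if (ok <= L / 2)
    stop("antiparallel register validation failed (only ", ok, "/", L,
         " pairs with C1'-C1' < 15 A); supply an explicit register offset ",
         "by renumbering or trimming the strands")
  data.frame(index = seq_len(L),
             chain1 = chain1, resno1 = r1$resno, insert1 = r1$insert,
             resname1 = r1$resname, base1 = b1,
             chain2 = chain2, resno2 = r2$resno, insert2 = r2$insert,
             resname2 = r2$resname, base2 = b2,
             designedType = paste0(b1, ":", b2), c1c1 = c1c1,
             stringsAsFactors = FALSE)
}

## canonical bond table for a designed pair, oriented to strands 1/2
canonicalBonds <- function(base1, base2) {
  purineFirst <- base1 %in% c("A", "G")
  key <- if (purineFirst) paste0(base1, ":", base2)
         else paste0(base2, ":", base1)
  tab <- WC_HBONDS[[key]]
  if (is.null(tab)) return(NULL)
  if (purineFirst) {
    data.frame(label = tab$label, atomOn1 = tab$atom1, atomOn2 = tab$atom2,
               donorSide = tab$donorSide)
  } else {
    data.frame(label = tab$label, atomOn1 = tab$atom2, atomOn2 = tab$atom1,
               donorSide = 3L - tab$donorSide)
  }
}

#' Inventory Watson-Crick hydrogen bonds and classify base pairs
#'
#' For every designed pair the canonical donor-acceptor distances are
#' measured (A.T: N1-N3, N6-O4; G.C: N1-N3, N2-O2, O6-N4) and a bond is
#' counted as present when its distance is at or below \code{cutoff}.
#' Classification: \code{watson_crick} when all canonical bonds are
#' present, \code{absent} when none is, otherwise
#' \code{non_watson_crick}.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param pairs data.frame from [pairStrands()].
#' @param cutoff acceptor-donor distance cutoff in Angstrom (default 3.5).
#' @returns list with \code{pairs} (input plus \code{nBondsPresent},
#'   \code{nBondsCanonical}, \code{classification}) and \code{hbonds}
#'   (one row per canonical bond: pair index, label, donor and acceptor
#'   atom references, distance, present flag).
#' @export
hbondInventory <- function(model, pairs, cutoff = 3.5) {
  stopifnot(cutoff > 0)
  hb <- vector("list", nrow(pairs))
  cls <- character(nrow(pairs))
  nPresent <- integer(nrow(pairs)); nCanon <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    bonds <- canonicalBonds(p$base1, p$base2)
    if (is.null(bonds)) {
      warning("pair ", p$index, " (", p$designedType,
              ") is not a canonical Watson-Crick combination; ",
              "classified absent")
      cls[i] <- "absent"; nPresent[i] <- 0L; nCanon[i] <- 0L
      next
    }
    c1 <- residueCoords(model, p$chain1, p$resno1, p$insert1)
    c2 <- residueCoords(model, p$chain2, p$resno2, p$insert2)
    d <- vapply(seq_len(nrow(bonds)), function(k) {
      a1 <- bonds$atomOn1[k]; a2 <- bonds$atomOn2[k]
      if (!(a1 %in% rownames(c1)) || !(a2 %in% rownames(c2))) {
        warning("pair ", p$index, ": atom ", a1, " or ", a2,
                " missing; bond ", bonds$label[k], " recorded absent")
        return(NA_real_)
      }
      vnorm(c1[a1, ] - c2[a2, ])
    }, numeric(1))
    present <- !is.na(d) & d <= cutoff
    donor <- ifelse(bonds$donorSide == 1L,
                    paste0(p$chain1, "/", p$resno1, "/", bonds$atomOn1),
                    paste0(p$chain2, "/", p$resno2, "/", bonds$atomOn2))
    acceptor <- ifelse(bonds$donorSide == 1L,
                       paste0(p$chain2, "/", p$resno2, "/", bonds$atomOn2),
                       paste0(p$chain1, "/", p$resno1, "/", bonds$atomOn1))
    hb[[i]] <- data.frame(index = p$index, label = bonds$label,
                          donor = donor, acceptor = acceptor,
                          distance = d, present = present,
                          stringsAsFactors = FALSE)
    nPresent[i] <- sum(present); nCanon[i] <- nrow(bonds)
    cls[i] <- if (nPresent[i] == nCanon[i]) "watson_crick"
              else if (nPresent[i] == 0L) "absent" else "non_watson_crick"
  }
  pairs$nBondsPresent <- nPresent
  pairs$nBondsCanonical <- nCanon
  pairs$classification <- cls
  list(pairs = pairs, hbonds = do.call(rbind, hb))
}

## least-squares fit of the standard reference base onto observed ring
## atoms; returns the base frame (rotation columns = x, y, z axes) and
## origin in global coordinates
fitBaseFrame <- function(obs, base) {
  ring <- intersect(BASE_RING_ATOMS[[base]], rownames(obs))
  if (length(ring) < 6)
    stop("fewer than 6 canonical base ring atoms present (",
         length(ring), ") for base ", base)
  tpl <- BASE_TEMPLATES[[base]][ring, , drop = FALSE]
  k <- kabsch(tpl, obs[ring, , drop = FALSE])
  list(R = k$R, origin = k$t)
}

## frames of both bases of one pair plus the averaged pair frame; strand-2
## frame is flipped by 180 degrees about its x axis (standard convention)
pairFrames <- function(model, pair) {
  c1 <- residueCoords(model, pair$chain1, pair$resno1, pair$insert1)
  c2 <- residueCoords(model, pair$chain2, pair$resno2, pair$insert2)
  f1 <- fitBaseFrame(c1, pair$base1)
  f2 <- fitBaseFrame(c2, pair$base2)
  FLIP <- diag(c(1, -1, -1))
  R2p <- f2$R %*% FLIP
  Rm <- averageRotation(f1$R, R2p)
  list(R1 = f1$R, o1 = f1$origin, R2 = R2p, o2 = f2$origin,
       R = Rm, origin = (f1$origin + f2$origin) / 2)
}

#' Base-pair reference frame of one designed pair
#'
#' @param model a \linkS4class{StructureModel} holding a duplex.
#' @param chain1,chain2 strand chain ids.
#' @param pairIndex 1-based pair position along strand 1.
#' @returns list with \code{R} (3x3 rotation; columns are the pair x, y, z
#'   axes in global coordinates) and \code{origin}.
#' @export
pairReferenceFrame <- function(model, chain1, chain2, pairIndex) {
  pairs <- pairStrands(model, chain1, chain2)
  if (pairIndex < 1 || pairIndex > nrow(pairs))
    stop("pair index out of range")
  f <- pairFrames(model, pairs[pairIndex, ])
  list(R = f$R, origin = f$origin)
}

## mid-frame angular decomposition between two frames: rotation split into
## (tilt, roll, twist) about the mid-frame (x, y, z); displacement into
## (shift, slide, rise).  Used both for step parameters (frame1 = pair i,
## frame2 = pair i+1) and for pair parameters (frame1 = flipped strand-2
## base, frame2 = strand-1 base), where the triplet reads (buckle,
## propeller, opening) / (shear, stretch, stagger).
frameStepParams <- function(R1, o1, R2, o2) {
  z1 <- R1[, 3]; z2 <- R2[, 3]
  cg <- max(-1, min(1, sum(z1 * z2)))
  gamma <- acos(cg) * 180 / pi
  hinge <- pracma::cross(z1, z2)
  if (vnorm(hinge) < 1e-12) {
    A <- R1; B <- R2
    hinge <- R1[, 2]                    # arbitrary; gamma ~ 0
  } else {
    hinge <- unitv(hinge)
    A <- rotAxis(hinge, gamma / 2) %*% R1
    B <- rotAxis(hinge, -gamma / 2) %*% R2
  }
  Rm <- averageRotation(A, B)
  zm <- Rm[, 3]
  twist <- signedAngle(A[, 1], B[, 1], zm)
  phi <- signedAngle(hinge, Rm[, 2], zm)
  roll <- gamma * cos(phi * pi / 180)
  tilt <- gamma * sin(phi * pi / 180)
  d <- as.vector(t(Rm) %*% (o2 - o1))
  c(tilt = tilt, roll = roll, twist = twist,
    shift = d[1], slide = d[2], rise = d[3])
}

#' Base-pair and step parameters of a duplex
#'
#' Computes for every designed pair the intra-pair parameters (signed
#' \code{opening} about the pair z axis, \code{propeller}, \code{buckle})
#' and for every dinucleotide step the inter-pair parameters
#' (\code{twist}, \code{roll}, \code{tilt}, \code{rise}).  Angles are in
#' degrees, distances in Angstrom.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param pairs data.frame from [pairStrands()] (or from
#'   [hbondInventory()]).
#' @returns list with \code{pairs} (input plus \code{buckle},
#'   \code{propeller}, \code{opening}, \code{absOpening}) and \code{steps}
#'   (one row per step: \code{stepIndex}, \code{tilt}, \code{roll},
#'   \code{twist}, \code{rise}).
#' @examples
#' g <- pairStepParameters(buildBDNA("ACGTACGT", twist = 30), pairs =
#'   pairStrands(buildBDNA("ACGTACGT", twist = 30), "A", "B"))
#' g$steps$twist
#' @export
pairStepParameters <- function(model, pairs) {
  n <- nrow(pairs)
  frames <- lapply(seq_len(n), function(i) pairFrames(model, pairs[i, ]))
  pp <- t(vapply(frames, function(f)
    frameStepParams(f$R2, f$o2, f$R1, f$o1), numeric(6)))
  pairs$buckle <- pp[, "tilt"]
  pairs$propeller <- pp[, "roll"]
  pairs$opening <- pp[, "twist"]
  pairs$absOpening <- abs(pp[, "twist"])
  steps <- if (n > 1) {
    sp <- t(vapply(seq_len(n - 1), function(i)
      frameStepParams(frames[[i]]$R, frames[[i]]$origin,
                      frames[[i + 1]]$R, frames[[i + 1]]$origin),
      numeric(6)))
    data.frame(stepIndex = seq_len(n - 1), tilt = sp[, "tilt"],
               roll = sp[, "roll"], twist = sp[, "twist"],
               rise = sp[, "rise"])
  } else data.frame(stepIndex = integer(), tilt = numeric(),
                    roll = numeric(), twist = numeric(), rise = numeric())
  list(pairs = pairs, steps = steps)
}

#' Minor and major groove widths of a duplex
#'
#' Per base-pair level, the minor (major) groove width is the minimal
#' cross-strand phosphorus-phosphorus distance within the characteristic
#' stagger window, minus a 5.8 Angstrom backbone correction (floored at
#' zero).  Levels whose window reaches past the ends of the duplex (or
#' where phosphates are missing, e.g. 5' termini) are flagged undefined
#' (NA), never zero-filled.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param chain1,chain2 strand chain ids.
#' @returns data.frame with one row per level: \code{level},
#'   \code{minorWidth}, \code{majorWidth} (Angstrom, NA when undefined)
#'   and \code{minorDefined}/\code{majorDefined} flags.
#' @export
grooveWidths <- function(model, chain1, chain2) {
  pairs <- pairStrands(model, chain1, chain2)
  L <- nrow(pairs)
  getP <- function(chain, resno, insert) {
    m <- residueCoords(model, chain, resno, insert)
    if ("P" %in% rownames(m)) m["P", ] else c(NA_real_, NA_real_, NA_real_)
  }
  P1 <- t(vapply(seq_len(L), function(i)
    getP(pairs$chain1[i], pairs$resno1[i], pairs$insert1[i]), numeric(3)))
  P2 <- t(vapply(seq_len(L), function(i)
    getP(pairs$chain2[i], pairs$resno2[i], pairs$insert2[i]), numeric(3)))
  if (sum(stats::complete.cases(P1)) < 4 || sum(stats::complete.cases(P2)) < 4)
    stop("need at least 4 phosphates per strand for groove widths")
  width <- function(i, offsets) {
    js <- i + offsets
    if (any(js < 1 | js > L)) return(NA_real_)
    d <- vapply(js, function(j) vnorm(P1[i, ] - P2[j, ]), numeric(1))
    if (any(is.na(d))) return(NA_real_)
    max(0, min(d) - GROOVE_BACKBONE_CORRECTION)
  }
  minor <- vapply(seq_len(L), width, numeric(1),
                  offsets = GROOVE_MINOR_OFFSETS)
  major <- vapply(seq_len(L), width, numeric(1),
                  offsets = GROOVE_MAJOR_OFFSETS)
  data.frame(level = seq_len(L), minorWidth = minor, majorWidth = major,
             minorDefined = !is.na(minor), majorDefined = !is.na(major))
}

#' Full DNA geometry report for one duplex
#'
#' Convenience wrapper running [pairStrands()], [hbondInventory()],
#' [pairStepParameters()] and [grooveWidths()].
#'
#' @inheritParams grooveWidths
#' @param cutoff hydrogen-bond acceptor-donor cutoff (Angstrom).
#' @returns list with elements \code{pairs}, \code{hbonds}, \code{steps},
#'   \code{grooves}.
#' @examples
#' geom <- dnaGeometry(buildBDNA("CCGAAAAAAAAAACGC"), "A", "B")
#' table(geom$pairs$classification)
#' mean(geom$steps$twist)
#' @export
dnaGeometry <- function(model, chain1, chain2, cutoff = 3.5) {
  pairs <- pairStrands(model, chain1, chain2)
  inv <- hbondInventory(model, pairs, cutoff = cutoff)
  geo <- pairStepParameters(model, inv$pairs)
  grooves <- tryCatch(grooveWidths(model, chain1, chain2),
    error = function(e) {
      # too short / too few phosphates: every level undefined
      data.frame(level = pairs$index, minorWidth = NA_real_,
                 majorWidth = NA_real_, minorDefined = FALSE,
                 majorDefined = FALSE)
    })
  list(pairs = geo$pairs, hbonds = inv$hbonds, steps = geo$steps,
       grooves = grooves)
}
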