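## Central S4 containers.
##
## A StructureModel stores one atomic model as a flat, file-ordered atom
## table (chains -> residues -> atoms recoverable from the chain/resno/insert
## columns).  A ScatteringProfile is the unit exchanged between the SAXS
## calculator, simulator and fitters.

ATOM_COLS <- c("chain", "resno", "insert", "resname", "kind",
               "elety", "element", "x", "y", "z", "occ", "b")

#' StructureModel: a hierarchical atomic coordinate model
#'
#' Atoms are stored as a flat data frame in file order; the chain/residue
#' hierarchy is encoded by the \code{chain}, \code{resno} and \code{insert}
#' columns.  Coordinates are in Angstrom.
#'
#' @slot id character(1), model identifier (e.g. PDB code or a label).
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resname}, \code{kind} (one of \code{"amino_acid"},
#'   \code{"nucleotide"}, \code{"other"}), \code{elety} (atom name),
#'   \code{element}, \code{x}, \code{y}, \code{z}, \code{occ}, \code{b}.
#' @slot metadata named list of free-form metadata (title, resolution, ...).
#'
#' @seealso [readStructure()], [selectAtoms()], [buildBDNA()]
#' @export
setClass("StructureModel",
  representation(id = "character", atoms = "data.frame", metadata = "list"),
  prototype(id = NA_character_,
            atoms = structure(
              list(chain = character(), resno = integer(),
                   insert = character(), resname = character(),
                   kind = character(), elety = character(),
                   element = character(), x = numeric(), y = numeric(),
                   z = numeric(), occ = numeric(), b = numeric()),
              class = "data.frame", row.names = integer()),
            metadata = list()))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  if (!all(ATOM_COLS %in% names(a)))
    return(paste("atoms table must contain columns:",
                 paste(setdiff(ATOM_COLS, names(a)), collapse = ", ")))
  xyz <- c(a$x, a$y, a$z)
  if (length(xyz) && !all(is.finite(xyz)))
    return("atom coordinates must be finite")
  if (length(a$kind) &&
      !all(a$kind %in% c("amino_acid", "nucleotide", "other")))
    return("kind must be amino_acid, nucleotide or other")
  # residue identity (chain, resno, insert) must map to a single residue name
  if (nrow(a)) {
    key <- paste(a$chain, a$resno, a$insert, sep = "\r")
    if (anyDuplicated(unique(data.frame(key, name = a$resname))$key))
      return("residue (chain, seq number, insertion code) not unique")
  }
  TRUE
})

#' ScatteringProfile: a small-angle scattering curve
#'
#' @slot q numeric, strictly increasing momentum transfer values (1/Angstrom).
#' @slot intensity numeric, scattered intensity (arbitrary units).
#' @slot sigma numeric, per-point uncertainties; length 0 when absent.
#'
#' @seealso [debyeProfile()], [readProfile()], [chi2Compare()]
#' @export
setClass("ScatteringProfile",
  representation(q = "numeric", intensity = "numeric", sigma = "numeric"),
  prototype(q = numeric(), intensity = numeric(), sigma = numeric()))

setValidity("ScatteringProfile", function(object) {
  if (length(object@q) != length(object@intensity))
    return("q and intensity must have equal length")
  if (length(object@sigma) &&
      length(object@sigma) != length(object@q))
    return("sigma must be empty or match q in length")
  if (length(object@q)) {
    if (any(object@q < 0)) return("q values must be >= 0")
    if (any(diff(object@q) <= 0)) return("q must be strictly increasing")
  }
  if (length(object@sigma) && any(object@sigma <= 0))
    return("sigma values must be positive")
  TRUE
})

#' GuinierFit: result of a Guinier analysis
#'
#' @slot rg numeric(1), radius of gyration (Angstrom).
#' @slot i0 numeric(1), extrapolated forward scattering.
#' @slot qRange numeric(2), q window used for the fit.
#' @slot rSquared numeric(1), coefficient of determination of the linear fit.
#' @slot nPoints integer(1), number of points in the fitted window.
#' @export
setClass("GuinierFit",
  representation(rg = "numeric", i0 = "numeric", qRange = "numeric",
                 rSquared = "numeric", nPoints = "integer"))

#' TwoStateFit: two-conformer decomposition of a scattering profile
#'
#' @slot fractionOpen numeric(1), mass fraction of the second (minor/open)
#'   component.
#' @slot scale numeric(1), overall scale factor applied to the combination.
#' @slot chi2 numeric(1), reduced chi-square at the optimum.
#' @slot rgClosed,rgOpen numeric(1), Guinier radii of the two component
#'   profiles (NA when a component window cannot be fit).
#' @slot chi2Grid data.frame with the scanned \code{fraction} and \code{chi2}
#'   values (for diagnostics).
#' @export
setClass("TwoStateFit",
  representation(fractionOpen = "numeric", scale = "numeric",
                 chi2 = "numeric", rgClosed = "numeric", rgOpen = "numeric",
                 chi2Grid = "data.frame"))

#' SuperpositionResult: least-squares rigid-body superposition
#'
#' @slot rotation 3x3 proper rotation matrix applied to the mobile set.
#' @slot translation numeric(3), translation applied after rotation.
#' @slot rmsd numeric(1), root-mean-square deviation after superposition.
#' @slot nAtoms integer(1), number of atom pairs used.
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nAtoms = "integer"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthonormal")
  if (det(R) < 0) return("rotation must be proper (det +1)")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

#' ThermoRecord: binding thermodynamics derived from a dissociation constant
#'
#' @slot kd numeric(1), dissociation constant (molar).
#' @slot deltaH numeric(1), binding enthalpy (kJ/mol).
#' @slot temperature numeric(1), temperature (K).
#' @slot deltaG numeric(1), standard binding free energy RT ln Kd (kJ/mol).
#' @slot tDeltaS numeric(1), entropic term deltaH - deltaG (kJ/mol).
#' @slot entropyDriven logical(1), TRUE when deltaH > 0 and tDeltaS > 0
#'   (endothermic, entropy-driven binding).
#' @export
setClass("ThermoRecord",
  representation(kd = "numeric", deltaH = "numeric", temperature = "numeric",
                 deltaG = "numeric", tDeltaS = "numeric",
                 entropyDriven = "logical"))

## ---- show methods ------------------------------------------------------

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel", if (!is.na(object@id)) sQuote(object@id) else "",
      "\n", sep = " ")
  if (!nrow(a)) { cat("  (empty)\n"); return(invisible(NULL)) }
  ch <- unique(a$chain)
  nres <- nrow(unique(a[c("chain", "resno", "insert")]))
  cat(sprintf("  %d atoms, %d residues, %d chain%s (%s)\n", nrow(a), nres,
              length(ch), if (length(ch) > 1) "s" else "",
              paste(ch, collapse = ", ")))
  kk <- table(factor(a$kind, c("amino_acid", "nucleotide", "other")))
  cat(sprintf("  atoms by kind: amino_acid %d, nucleotide %d, other %d\n",
              kk[1], kk[2], kk[3]))
  invisible(NULL)
})

setMethod("show", "ScatteringProfile", function(object) {
  n <- length(object@q)
  cat(sprintf("ScatteringProfile: %d points", n))
  if (n) cat(sprintf(", q in [%.4g, %.4g] 1/A", min(object@q), max(object@q)))
  cat(if (length(object@sigma)) ", with sigma\n" else ", no sigma\n")
  invisible(NULL)
})

setMethod("show", "GuinierFit", function(object) {
  cat(sprintf("GuinierFit: Rg = %.2f A, I(0) = %.4g (%d pts, q %.4g-%.4g, R2 %.4f)\n",
              object@rg, object@i0, object@nPoints,
              object@qRange[1], object@qRange[2], object@rSquared))
  invisible(NULL)
})

setMethod("show", "TwoStateFit", function(object) {
  cat(sprintf("TwoStateFit: open fraction %.3f (closed %.3f), chi2 = %.4g, scale = %.4g\n",
              object@fractionOpen, 1 - object@fractionOpen, object@chi2,
              object@scale))
  invisible(NULL)
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd = %.3f A over %d atoms\n",
              object@rmsd, object@nAtoms))
  invisible(NULL)
})

setMethod("show", "ThermoRecord", function(object) {
  cat(sprintf(
    "ThermoRecord: Kd = %.3g M at %.2f K\n  deltaG = %.2f, deltaH = %.2f, TdeltaS = %.2f kJ/mol%s\n",
    object@kd, object@temperature, object@deltaG, object@deltaH,
    object@tDeltaS,
    if (object@entropyDriven) "  (endothermic, entropy-driven)" else ""))
  invisible(NULL)
})

## ---- accessors ---------------------------------------------------------

#' @describeIn StructureModel-accessors atom table of a model (file order)
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Accessors for StructureModel and ScatteringProfile
#'
#' @param x a \linkS4class{StructureModel} or
#'   \linkS4class{ScatteringProfile}.
#' @name StructureModel-accessors
#' @returns \code{atoms}: the atom data frame; \code{chainIds}: character
#'   vector of chain identifiers; \code{nAtoms}: integer atom count;
#'   \code{coords}: numeric n x 3 coordinate matrix; \code{qValues},
#'   \code{intensities}, \code{sigmas}: the profile columns.
NULL

#' @rdname StructureModel-accessors
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @describeIn StructureModel-accessors chain identifiers in file order
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname StructureModel-accessors
#' @export
setMethod("chainIds", "StructureModel", function(x) unique(x@atoms$chain))

#' @describeIn StructureModel-accessors number of atoms
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname StructureModel-accessors
#' @export
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))

#' @describeIn StructureModel-accessors coordinate matrix (n x 3, Angstrom)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname StructureModel-accessors
#' @export
setMethod("coords", "StructureModel", function(x)
  as.matrix(x@atoms[, c("x", "y", "z")]))

#' @describeIn StructureModel-accessors q grid of a profile
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname StructureModel-accessors
#' @export
setMethod("qValues", "ScatteringProfile", function(x) x@q)

#' @describeIn StructureModel-accessors intensities of a profile
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname StructureModel-accessors
#' @export
setMethod("intensities", "ScatteringProfile", function(x) x@intensity)

#' @describeIn StructureModel-accessors per-point uncertainties (may be empty)
#' @export
setGeneric("sigmas", function(x) standardGeneric("sigmas"))

#' @rdname StructureModel-accessors
#' @export
setMethod("sigmas", "ScatteringProfile", function(x) x@sigma)

## internal constructors --------------------------------------------------

newStructureModel <- function(atoms, id = NA_character_, metadata = list()) {
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$insert <- as.character(atoms$insert)
  rownames(atoms) <- NULL
  new("StructureModel", id = id, atoms = atoms[, ATOM_COLS], metadata = metadata)
}

#' Construct a scattering profile
#'
#' @param q numeric, strictly increasing momentum transfer grid (1/Angstrom).
#' @param intensity numeric intensities, same length as \code{q}.
#' @param sigma optional numeric uncertainties (positive, same length) or
#'   \code{NULL}.
#' @returns A \linkS4class{ScatteringProfile}.
#' @examples
#' scatteringProfile(q = c(0.01, 0.02), intensity = c(10, 9.5))
#' @export
scatteringProfile <- function(q, intensity, sigma = NULL) {
  new("ScatteringProfile", q = as.numeric(q), intensity = as.numeric(intensity),
      sigma = if (is.null(sigma)) numeric() else as.numeric(sigma))
}
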