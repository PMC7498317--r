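## Reading, writing and selecting from atomic structure models.  Parsing of
## the PDB and mmCIF dialects is delegated to bio3d; this layer resolves
## alternate locations, classifies residues and builds the StructureModel
## container.

#' Read an atomic structure model from PDB or mmCIF
#'
#' Parses all ATOM/HETATM records with positive occupancy.  Alternate
#' locations are resolved to the highest-occupancy conformer (ties broken by
#' file order).  Waters and ligands are retained with kind \code{"other"}.
#' Atoms whose element cannot be matched to the internal form-factor/mass
#' tables are kept but flagged with a warning.
#'
#' @param path path to a coordinate file.
#' @param format \code{"pdb"}, \code{"mmcif"} or \code{"auto"} (by file
#'   extension; \code{.cif} means mmCIF).
#' @param id model identifier; defaults to the file base name.
#' @returns A \linkS4class{StructureModel}.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writeLines(paste0("ATOM      1  CA  GLY A   1      11.104   6.134",
#'                   "  -6.504  1.00  0.00           C"), f)
#' readStructure(f)
#' @seealso [writeStructure()], [selectAtoms()]
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "cif") "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("failed to parse ", format, " file ", path,
                             ": ", conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  a$chain[is.na(a$chain)] <- " "
  a$insert[is.na(a$insert)] <- ""
  a$o[is.na(a$o)] <- 1
  a <- a[a$o > 0, , drop = FALSE]
  ## altloc resolution: highest occupancy, ties -> first in file
  a$alt[is.na(a$alt)] <- ""
  if (any(a$alt != "")) {
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
    ord <- order(key, -a$o, seq_len(nrow(a)))
    keep <- ord[!duplicated(key[ord])]
    a <- a[sort(keep), , drop = FALSE]
  }
  element <- if ("elesy" %in% names(a)) trimws(a$elesy) else
    rep("", nrow(a))
  element[is.na(element)] <- ""
  blank <- element == ""
  element[blank] <- elementFromName(a$elety[blank])
  element <- ifelse(toupper(element) %in% knownElements(),
                    toupper(element), element)
  unknown <- !(element %in% knownElements())
  if (any(unknown))
    warning(sum(unknown), " atom(s) with element outside the form-factor/",
            "mass tables (kept, flagged unknown): ",
            paste(unique(element[unknown]), collapse = ", "))
  atoms <- data.frame(
    chain = a$chain, resno = a$resno, insert = a$insert,
    resname = trimws(a$resid), kind = residueKind(a$resid),
    elety = trimws(a$elety), element = element,
    x = a$x, y = a$y, z = a$z, occ = a$o,
    b = ifelse(is.na(a$b), 0, a$b), stringsAsFactors = FALSE)
  newStructureModel(atoms, id = if (is.null(id))
    sub("\\.[^.]*$", "", basename(path)) else id)
}

#' Write a structure model in PDB format
#'
#' Coordinates are written at the standard PDB precision (3 decimals), so a
#' write/read round trip reproduces them to 0.001 Angstrom.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param path output file path.
#' @returns \code{path}, invisibly.
#' @seealso [readStructure()]
#' @export
writeStructure <- function(model, path) {
  a <- atoms(model)
  if (!nrow(a)) stop("cannot write an empty model")
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$kind == "other", "HETATM", "ATOM"),
    resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
    elety = a$elety, chain = ifelse(a$chain == " ", "", a$chain),
    insert = a$insert, o = a$occ, b = a$b,
    elesy = ifelse(a$element %in% knownElements(), a$element, ""))
  invisible(path)
}

#' Describe an atom selection
#'
#' A selection is the conjunction of the supplied filters; \code{NULL}
#' means "no constraint".  The vocabulary matches the usual structural
#' bioinformatics idiom, e.g. backbone heavy atoms of residues 16-65:
#' \code{atomSelection(resnoRange = c(16, 65),
#' atomNames = c("N", "CA", "C", "O"))}.
#'
#' @param chains optional character vector of chain ids.
#' @param resnoRange optional inclusive \code{c(start, end)} residue-number
#'   range.
#' @param atomNames optional character vector of atom names.
#' @param elements optional character vector of element symbols.
#' @returns An object of class \code{"AtomSelection"} (a list).
#' @export
atomSelection <- function(chains = NULL, resnoRange = NULL, atomNames = NULL,
                          elements = NULL) {
  if (!is.null(resnoRange)) {
    stopifnot(length(resnoRange) == 2, resnoRange[1] <= resnoRange[2])
  }
  structure(list(chains = chains, resnoRange = resnoRange,
                 atomNames = atomNames, elements = elements),
            class = "AtomSelection")
}

#' Select atoms from a model
#'
#' @param model a \linkS4class{StructureModel}.
#' @param selection an [atomSelection()].  The result is independent of the
#'   order in which the selection fields were specified and is returned in
#'   file order.  An empty result is a zero-row table, not an error.
#' @returns The selected rows of \code{atoms(model)}; row names hold the
#'   original atom indices.
#' @examples
#' m <- buildHelixBundle(1, 3)
#' selectAtoms(m, atomSelection(atomNames = "CA"))
#' @export
selectAtoms <- function(model, selection = atomSelection()) {
  stopifnot(is(model, "StructureModel"), inherits(selection, "AtomSelection"))
  a <- atoms(model)
  keep <- rep(TRUE, nrow(a))
  if (!is.null(selection$chains)) keep <- keep & a$chain %in% selection$chains
  if (!is.null(selection$resnoRange))
    keep <- keep & a$resno >= selection$resnoRange[1] &
      a$resno <= selection$resnoRange[2]
  if (!is.null(selection$atomNames)) keep <- keep & a$elety %in% selection$atomNames
  if (!is.null(selection$elements)) keep <- keep & a$element %in% selection$elements
  rownames(a) <- seq_len(nrow(a))
  a[keep, , drop = FALSE]
}

#' Remove all residues of one kind from a model
#'
#' Typical use: strip the DNA from a protein/DNA complex before computing
#' the scattering profile of the free protein.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param kind \code{"nucleotide"}, \code{"amino_acid"} or \code{"other"}.
#' @returns A new \linkS4class{StructureModel}; the input is unmodified.
#' @export
stripComponent <- function(model, kind = c("nucleotide", "amino_acid",
                                           "other")) {
  kind <- match.arg(kind)
  a <- atoms(model)
  newStructureModel(a[a$kind != kind, , drop = FALSE], id = model@id,
                    metadata = model@metadata)
}

## extract coordinates of one residue's atoms as a named matrix
residueCoords <- function(model, chain, resno, insert = "") {
  a <- atoms(model)
  sel <- a$chain == chain & a$resno == resno & a$insert == insert
  m <- as.matrix(a[sel, c("x", "y", "z")])
  rownames(m) <- a$elety[sel]
  m
}
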