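# Shared fixtures: all inputs are generated in code at test time.

# one fixed-column PDB ATOM/HETATM line
pdbLine <- function(serial, name, resname, chain, resno, x, y, z,
                    occ = 1, b = 0, element = substr(name, 1, 1),
                    alt = " ", record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), alt, resname, chain, resno,
          x, y, z, occ, b, element)
}

writePdbFixture <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

# minimal structure model straight from an atom table
modelFromAtoms <- function(df, id = "fixture") {
  defaults <- list(insert = "", occ = 1, b = 0)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  if (is.null(df$kind)) df$kind <- clampscope:::residueKind(df$resname)
  if (is.null(df$element)) df$element <- substr(df$elety, 1, 1)
  clampscope:::newStructureModel(df, id = id)
}

# combine the atom tables of several models into one
combineModels <- function(..., id = "combined") {
  clampscope:::newStructureModel(do.call(rbind, lapply(list(...), atoms)),
                                 id = id)
}

# apply a rigid rotation + translation to every atom of a model
transformModel <- function(model, R, t = c(0, 0, 0)) {
  a <- atoms(model)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a[, c("x", "y", "z")] <- sweep(xyz, 2, t, `+`)
  clampscope:::newStructureModel(a, id = model@id, metadata = model@metadata)
}

randomRotation <- function() {
  ax <- rnorm(3)
  clampscope:::rotAxis(ax / sqrt(sum(ax^2)), runif(1, 0, 360))
}

# analytic sphere scattering: amplitude of a uniform sphere of radius R
sphereProfile <- function(R = 10, q = seq(0.001, 0.12, by = 0.001)) {
  x <- q * R
  F <- 3 * (sin(x) - x * cos(x)) / x^3
  scatteringProfile(q, F^2)
}

# Gaussian-coil (Debye-function) profile with known Rg
coilProfile <- function(rg = 27, q = seq(0.001, 0.12, by = 0.001)) {
  x <- (q * rg)^2
  scatteringProfile(q, 2 * (exp(-x) + x - 1) / x^2)
}

# near-uniform points on a sphere surface (Fibonacci lattice)
spherePoints <- function(n, R = 10) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(R * sin(phi) * cos(theta), R * sin(phi) * sin(theta), R * cos(phi))
}

pointModel <- function(xyz, element = "X") {
  modelFromAtoms(data.frame(
    chain = "A", resno = seq_len(nrow(xyz)), resname = "UNK", kind = "other",
    elety = element, element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# single protein residue with one named side-chain atom at a given position
sideChainResidue <- function(chain, resno, resname, atomName, pos,
                             offset = c(0, 0, 0)) {
  data.frame(chain = chain, resno = resno, resname = resname,
             kind = "amino_acid",
             elety = c("N", "CA", "C", "O", atomName),
             element = c("N", "C", "C", "O", substr(atomName, 1, 1)),
             x = c(pos[1] + 10 + offset[1] + c(0, 1, 2, 3), pos[1]),
             y = c(pos[2] + 10 + offset[2] + c(0, 0, 0, 0), pos[2]),
             z = c(pos[3] + offset[3] + c(0, 0, 0, 0), pos[3]))
}
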