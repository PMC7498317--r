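# clampscope

Structural and thermodynamic analysis of DNA-clamping protein assemblies,
built around the biology of GapR, an essential nucleoid-associated protein
of *Caulobacter crescentus*. GapR forms a homotetramer that encircles
duplex DNA; in solution the free tetramer exchanges between a closed clamp
conformation and more open conformers, and DNA binding widens the minor
groove of AT-rich DNA. `clampscope` provides the computational machinery
needed to establish and quantify that picture from coordinates and from
published constants:

- **Structure handling** — PDB/mmCIF parsing into an S4 `StructureModel`
  (altloc resolution, residue-kind classification), atom selections
  (`--chains A,B --resi 16-65 --atoms N,CA,C,O` style), component
  stripping, PDB writing.
- **Small-angle X-ray scattering** — exact Debye-formula profiles from
  coordinates, `I(q) = Σᵢ Σⱼ fᵢ(q) fⱼ(q) sin(q rᵢⱼ)/(q rᵢⱼ)`, with
  tabulated four-Gaussian atomic form factors and optional excluded-volume
  contrast; Guinier analysis (`ln I` vs `q²`, window iterated to
  `q·Rg ≤ 1.3`, `Rg = √(−3·slope)`); reduced χ² comparison with analytic
  scale; two-state decomposition of a profile into closed/open conformer
  contributions by exhaustive fraction scan; N-state non-negative
  least-squares decomposition; and the apparent-Rg mixture rule
  `Rg_app = √((C_A Rg_A² + C_B Rg_B²)/(C_A + C_B))`.
- **DNA geometry** — Watson–Crick hydrogen-bond inventories at a 3.5 Å
  acceptor–donor cutoff (A·T: N1–N3, N6–O4; G·C: N1–N3, N2–O2, O6–N4)
  with watson_crick / non_watson_crick / absent classification; base-pair
  opening and propeller and step twist/rise from standard-reference-frame
  base fitting; minor/major groove widths from cross-strand P–P distances
  (−5.8 Å backbone correction).
- **Superposition and interfaces** — Kabsch least-squares superposition
  and RMSD over arbitrary selections; inter-chain salt bridges (N–O ≤ 4 Å
  residue-pair convention); protein residues contacting DNA phosphate
  groups (≤ 5.5 Å).
- **Thermodynamics** — `ΔG = RT ln K_d`, `TΔS = ΔH − ΔG` from
  calorimetric constants; oligomer/complex molecular-weight bookkeeping;
  NMR minor-conformer population fractions.
- **Synthetic ground truth** — ideal and perturbed B-form duplexes of
  arbitrary sequence (full heavy atoms, default 36°/3.38 Å), toy helix
  bundles, and noisy two-component mixture profiles with known mixing
  fraction, so every stage is testable without downloading anything.

## Worked example

```r
library(clampscope)

## ideal B-form duplex of the high-affinity A-tract sequence
dna  <- buildBDNA("CCGAAAAAAAAAACGC")
geom <- dnaGeometry(dna, "A", "B")
mean(geom$steps$twist)                  # 36  (degrees per step)
table(geom$pairs$classification)        # watson_crick: 16
round(range(geom$grooves$minorWidth, na.rm = TRUE), 2)   # 5.74 5.74

## two-state decomposition of a mixed scattering profile
qs     <- seq(0.005, 0.25, length.out = 120)
closed <- scatteringProfile(qs, 1e4 * exp(-qs^2 * 26.9^2 / 3))
open   <- scatteringProfile(qs, 1e4 * exp(-qs^2 * 32.2^2 / 3))
mix    <- simulateMixtureProfile(closed, open, fractionOpen = 0.125,
                                 noiseLevel = 0.01, seed = 7)
twoStateFit(mix, closed, open)
#> TwoStateFit: open fraction 0.130 (closed 0.870), chi2 = 0.8835, scale = 1.005

## a 12.5 % open fraction raises the apparent Rg above the closed value
rgMix(87.5, 12.5, 26.9, 32.2)           # 27.618 (A)

## binding thermodynamics at 4 C
thermoFromKd(11.6e-9, 46.2)
#> ThermoRecord: Kd = 1.16e-08 M at 277.15 K
#>   deltaG = -42.10, deltaH = 46.20, TdeltaS = 88.30 kJ/mol
#>   (endothermic, entropy-driven)

## mass bookkeeping for the tetramer and its DNA complex
massLedger(monomerMw = 11.2, oligomerN = 4,
           dnaStrands = c("CCGAAAAAAAAAACGC", "GCGTTTTTTTTTTCGG"))
#> MassLedger: 4 x 11.20 kDa monomer = 44.80 kDa oligomer
#>   + DNA 9.76 kDa -> complex 54.56 kDa
```

The twist printed for the ideal duplex is the canonical B-form value the
builder was asked for — the geometry module recovers it through
least-squares base-frame fitting, not by reading the input back. The
two-state fit recovers the simulated 12.5 % open fraction to within one
fraction-grid step (0.5 %) at a reduced χ² near 1, mirroring how a conformational equilibrium is quantified from
solution scattering.

A command-line interface wrapping the same functions is installed at
`system.file("scripts", "clampscope", package = "clampscope")`, with
subcommands `synth`, `saxs`, `dna`, `compare`, `interface`, `thermo`,
`mass` and `run` (the last drives `runPipeline()` from a YAML config).

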