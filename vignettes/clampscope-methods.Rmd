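---
title: "Methods: models, conventions and design choices in clampscope"
author: "clampscope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampscope)
```

# Scientific setting

GapR, a nucleoid-associated protein of *Caulobacter crescentus*, is a
homotetramer that binds AT-rich duplex DNA by encircling it. Free GapR
exchanges between a closed clamp conformation (the major species) and
more open tetrameric conformers (minor species); the open form is thought
to be the species that loads onto DNA, after which the clamp closes. Two
classes of quantitative argument support this picture, and `clampscope`
implements both end to end:

1. **Solution scattering.** The apparent radius of gyration of a
   conformational mixture obeys
   $R_{g,app} = \sqrt{(C_A R_{gA}^2 + C_B R_{gB}^2) / (C_A + C_B)}$,
   so an apparent $R_g$ *larger* than the major conformer's calculated
   value can only arise if the minor conformer is larger still — a dimer
   (smaller $R_g$) is excluded, an open tetramer (larger $R_g$) is
   required. Fitting the measured curve as a scaled linear combination of
   the closed and open calculated curves quantifies the open fraction.
2. **DNA deformation.** Base-pair geometry (opening, twist), canonical
   hydrogen-bond inventories at a fixed acceptor–donor cutoff, and
   phosphate-based groove widths distinguish "overtwisted, narrowed"
   from "minor-groove-widened" DNA in the bound structures.

Closed-form thermodynamics ($\Delta G = RT\ln K_d$,
$T\Delta S = \Delta H - \Delta G$) and molecular-weight bookkeeping
($4 \times 11.2\,\mathrm{kDa}$ monomer $= 44.8$ kDa tetramer, plus the
duplex mass for the complex) complete the quantitative chain from
published constants to conclusions.

# Scattering model

**Debye profile.** The orientationally averaged intensity is the exact
double sum $I(q) = \sum_i\sum_j f_i(q) f_j(q)\,
\mathrm{sinc}(q r_{ij})$ over heavy-atom pairs. Atomic form factors use
the standard four-Gaussian parametrisation
$f(q) = c + \sum_k a_k e^{-b_k (q/4\pi)^2}$ for H, C, N, O, P, S; a unit
point scatterer ("X", $f \equiv 1$) is provided for analytic test cases.
The tabulated coefficients reproduce each element's electron count at
$q = 0$ to better than 0.1 e. With `contrast = "excluded_volume"` the
displaced-solvent term $\rho_s V_i\, e^{-\pi V_i^{2/3} q^2}$
($\rho_s = 0.334$ e/Å$^3$, Fraser-style displaced volumes) is subtracted
from each factor. The sum is evaluated exactly in $O(N^2)$ — the
assemblies of interest are a few thousand heavy atoms, which takes
seconds — rather than through a multipole expansion. Hydrogens are
excluded by default (the crystal structures carry none); a flag restores
them.

**Rigid-motion invariance** of the profile, and agreement of the
implementation with a literal, independently coded double sum to a
relative $10^{-10}$, are asserted in the test suite.

**Guinier analysis.** $\ln I$ is fit against $q^2$ (weighted by
$(I/\sigma)^2$ when uncertainties are present) over the largest low-$q$
window satisfying $qR_g \le 1.3$, iterating window and $R_g$ to a fixed
point; $R_g = \sqrt{-3\,\mathrm{slope}}$. The 1.3 limit is the
conventional globular-particle choice; for chain-like scatterers the
Guinier law fails sooner and a caller should restrict the window (the
tests use $qR_g \le 0.4$ for a Gaussian coil). Non-positive intensities
inside the window and windows of fewer than 5 points are errors, not
silent truncations.

**$\chi^2$ and decompositions.** Agreement between an experimental and a
calculated curve is $\chi^2 = \frac{1}{N-1}\sum_k \left[(I_{exp} -
c\,I_{calc})/\sigma\right]^2$ with the scale $c$ minimising $\chi^2$ in
closed form; the $1/(N-1)$ normalisation is the conventional definition
behind published reduced-$\chi^2$ values (an $1/N$ variant would differ
by under 1 % at realistic $N$). The two-state fit scans the open
fraction $w \in [0,1]$ exhaustively at a default step of 0.005 with a
per-$w$ analytic scale, returning the global minimum and resolving ties
towards the smaller $w$ (the more parsimonious, more-closed mixture).
The N-state generalisation solves a $\sigma$-weighted non-negative
least-squares problem and renormalises the coefficients into weights
plus an overall scale; with two components it agrees with the grid scan
to within the grid step, and the two routes serve as mutual checks. A
genetic-algorithm ensemble selection is deliberately out of scope: for
the two- and few-state questions asked here, direct scan/NNLS
decomposition is exact and reproducible.

**Hydration.** Calculated $R_g$ values from programs that model a
hydration layer run slightly above bare-coordinate values.
`coordinateRg()` therefore exposes an additive `shellDelta` (default 0)
and comparisons against layer-corrected published values should allow
about ±1 Å; this is a documented tolerance, not a fitted parameter.

# Synthetic generators

**B-form duplex builder.** Residues are assembled from heavy-atom base
geometries in the standard base-pair reference frame (base in the
$z = 0$ plane, $x$ into the major groove, the complementary base placed
by a 180° rotation about $x$) plus one shared idealized sugar–phosphate
backbone, and placed on an ideal helix: default twist 36°/step (the
canonical B-form value) and rise 3.38 Å/step. Per-pair propeller and
opening perturbations are applied symmetrically (±half-angle to each
base) in the pair frame, so the geometry module must read them back
exactly; `perturbPair()` moves a single base rigidly to create broken or
single-bond pairs with known ground truth.

The backbone template was derived once, by restrained least squares
under the 36°/3.38 Å helical symmetry, with standard bond lengths and
angles, a C2'-endo-like sugar, anti glycosidic torsion, exact
O3'(i)–P(i+1) chain closure (1.60 Å) and restraints keeping the
phosphate radius and the cross-strand P–P separations at canonical
B-form values (raw 11.5 Å on the minor-groove side, 17.7 Å on the
major); the resulting local coordinates are frozen in the package
source (`inst/scripts/derive_backbone.R` regenerates them). Exact backbone torsions are not load-bearing: every downstream
computation uses base atoms and phosphorus positions only. 5' termini
carry no phosphate, the convention for synthetic oligonucleotides.

What the generator emulates: designed pairing, designed helical
parameters, canonical hydrogen-bond geometry (all Watson–Crick bonds
2.85–3.05 Å when unperturbed), constant canonical groove widths.
What it does **not** emulate: sequence-dependent fine structure
(A-tract narrowing, TpA flexibility), thermal disorder, solvent and
counter-ions, crystal-packing distortions. Passing round-trip tests
therefore demonstrates the correctness of the geometric machinery, not
that real DNA is ideal; conclusions about real structures require the
deposited coordinates.

**Helix bundles** are poly-alanine α-helices (ideal φ/ψ backbone built
by internal-coordinate chaining, 5 heavy atoms per residue) on a square
lattice — deterministic toy assemblies for superposition, RMSD and
$R_g$/profile tests.

**Mixture profiles** are $I = (1-w) I_A + w I_B$ plus zero-mean Gaussian
noise with $\sigma(q) = \mathrm{noise} \times I(q)$, the simplest noise
model consistent with the $\chi^2$ definition (Poisson statistics are
not modelled). The $\sigma$ column is always populated — at zero noise a
nominal 1 % $\sigma$ is recorded so the profile remains usable in
$\chi^2$ fitting while the intensities stay exact. Draws are
reproducible under a seed.

# DNA geometry conventions

**Pairing.** Residue $i$ of strand 1 pairs with residue $L+1-i$ of
strand 2 (antiparallel register), validated by requiring C1'–C1'
distances below 15 Å for the majority of pairs; a failed validation is
an error suggesting an explicit register fix, never a silent guess.

**Hydrogen bonds.** Canonical inventories (A·T: N1–N3, N6–O4; G·C:
N1–N3, N2–O2, O6–N4) at an acceptor–donor cutoff of 3.5 Å.
Classification is *watson_crick* iff all canonical bonds are present,
*absent* iff none is, else *non_watson_crick*; it is monotone in the
cutoff by construction. Missing base atoms degrade to "bond absent"
with a warning.

**Frames and parameters.** Base frames come from least-squares
superposition of the standard reference base onto the observed ring
atoms (at least 6 required); the strand-2 frame is flipped 180° about
its $x$ axis, and the pair frame is the orthonormalised average. Pair
(buckle, propeller, opening) and step (tilt, roll, twist) parameters use
the conventional mid-frame angular decomposition — the 3DNA-style
scheme rather than a curvilinear-axis scheme. The two conventions
differ by fractions of a degree in twist and tenths of an Å in grooves,
which does not affect threshold or ordering statements (e.g.
"opening above 20°", "minor groove wider by 1–3 Å"); this package's
numbers are defined by its own convention. Opening is reported signed
and as a magnitude; threshold comparisons use the magnitude, since sign
conventions differ between programs.

**Groove widths.** Per base-pair level, the minor (major) width is the
minimal cross-strand P–P distance within the characteristic stagger
window — strand-2 partner offsets −4…−2 for the minor groove, +3…+5 for
the major, in this package's level numbering — minus a 5.8 Å backbone
correction, floored at zero. Levels whose window leaves the duplex or
lacks phosphates are flagged undefined (NA), never zero-filled. The
refined P–P convention is used because the comparisons of interest are
relative; on the ideal builder duplex it yields 5.7 Å (minor) and
11.9 Å (major), the textbook B-form values.

# Superposition and interfaces

Superposition is the standard SVD-based least-squares (Kabsch) rotation
with reflection correction; collinear references and mismatched lengths
are errors. Correspondence across models is by file order or by
(residue number, insertion code, atom name), with unmatched residues
reported by name. An independent implementation (`bio3d`) serves as a
cross-check in the tests, never as the implementation.

Salt bridges use the common side-chain N–O ≤ 4.0 Å convention (Lys NZ;
Arg NE/NH1/NH2; Asp OD1/OD2; Glu OE1/OE2), counted per residue pair —
matching how interface bridge counts are usually quoted. Histidine is
excluded by default (protonation at crystallisation pH unknown) and can
be enabled; so can C-terminal OXT. Phosphate contacts list every
protein residue with a (by default side-chain) atom within 5.5 Å of a
DNA phosphate-group atom (P, OP1, OP2, O5', O3').

# Thermodynamics and bookkeeping

$\Delta G = RT\ln K_d$ with $K_d$ in molar and
$R = 8.314\,\mathrm{J/(mol\,K)}$; $T\Delta S = \Delta H - \Delta G$.
The default temperature is 277.15 K (4 °C), the calorimetry temperature
at which the published constants for GapR were measured — recomputing
every row of that table reproduces the published $\Delta G$ and
$T\Delta S$ columns within 0.2 kJ/mol, which is the package's
internal-consistency acceptance check. Binding with $\Delta H > 0$ and
$T\Delta S > 0$ is flagged endothermic/entropy-driven, the signature of
nonspecific electrostatic protein–DNA association.

Protein masses use average isotopic residue masses (via `seqinr`), one
water per peptide bond; affinity-tag residues are included only when
supplied in the sequence. DNA strands use average
nucleotide-monophosphate residue masses with 5'-OH termini
($\mathrm{MW} = \sum \mathrm{residue} - 61.96$), standard for synthetic
oligonucleotides and within the 0.1 kDa rounding of published complex
masses. NMR population fractions are unweighted means of per-probe
$I_{minor}/(I_{minor}+I_{major})$ ratios; whether peak heights or
volumes are used is the caller's choice of inputs.

# Numerical choices and degenerate inputs

- Altlocs resolve to the highest-occupancy conformer, ties to the first
  in file; zero-occupancy atoms are dropped; unknown elements are kept
  and flagged, and are rejected only where a form factor or mass is
  actually required.
- Frame averaging and rotation averaging use the SVD projection to the
  nearest proper rotation; the $q = 0$ and $r = 0$ sinc limits are
  handled explicitly; the two-state tie-break is the smaller fraction.
- The Guinier iteration is capped at 100 window updates (it converges in
  a handful); a non-negative slope is an error rather than an imaginary
  $R_g$.
- `pairStrands` requires equal strand lengths; explicit renumbering, not
  heuristics, handles overhangs.

# Problem sizes

The test suite and examples run on deliberately small problems — duplexes
of 2–16 bp, bundles of ≤ a few hundred atoms, profiles of 40–1000 points,
200-replicate recovery studies at 2 % noise — chosen so the whole suite
executes in well under a minute while still exercising every numerical
path at meaningful precision (the Debye oracle at $10^{-10}$, frame
round-trips at 0.1°).

# Known limitations

- No hydration-shell model for calculated profiles/$R_g$ (documented ±1 Å
  comparison tolerance instead); no $P(r)$ inversion, ab initio shapes,
  or ensemble genetic algorithms.
- DNA geometry covers canonical Watson–Crick duplexes: no curvilinear
  helical axis, no wobble/Hoogsteen taxonomy, no RNA.
- No crystallographic symmetry expansion or model rebuilding: analyses
  of multi-copy asymmetric units require the caller to name chains.
- Analyses of the deposited crystal structures (PDB 6K2J, 6JYK, 6CG8,
  4J2I) require those files locally
  (`options(clampscope.structure_dir = ...)`); they are not bundled.

```{r session}
sessionInfo()
```
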