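---
title: "Disulfide conformational landscapes under tensile force: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disulfide conformational landscapes under tensile force: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbridge)
```

## The model

A disulfide bridge carries two C–C–S–S dihedrals (χ1 and χ2, one per
cysteine, measured as Cα–Cβ–Sγ–Sγ′) and the central C–S–S–C dihedral χ3.
A dihedral within 180° ± 50° is *closed*; anything else is *open*. The
closed/closed combination blocks the collinear attack cone of an SN2-type
thiol–disulfide exchange at sulfur, so a bridge's conformational state gates
its redox chemistry. Because the closed/closed geometry is also the most
extended one, pulling on the molecule tilts the landscape toward it.

`ssbridge` studies this with a deliberately reduced representation: a
torsion-only model in which bond lengths and angles are frozen at standard
heavy-atom values (C–C 1.53 Å, C–S 1.82 Å, S–S 2.05 Å; C–S–S 103.7°,
C–C–S 114.7°, tetrahedral/peptide values elsewhere) and only the declared
rotatable dihedrals move. Three builtin compounds of increasing size are
provided:

| model | atoms | rotatable dihedrals | pulled atoms |
|---|---|---|---|
| `DEDS` (diethyl disulfide) | 6 | 3 (χ1, χ3, χ2) | terminal methyl carbons |
| `cystine` | 8 | 5 | N and C termini |
| `polypeptide-path` | 14 | 9 (peptide ω fixed at 180°) | terminal backbone atoms |

The polypeptide model is the force-bearing path of a disulfide-bridged loop
(flanking backbone, both cysteine side chains, the S–S bond). The loop
residues between the two cysteines are omitted deliberately: once the
bridge closes the loop, tension short-circuits through the S–S bond and
those residues carry no force. This keeps the sampler free of ring-closure
constraints; it is an approximation, stated as such.

The ensemble is isotensional (force-clamp): a constant collinear force `F`
acts on the pull pair, adding a work term so that

E(φ) = Σ_k Σ_n ½ V_n [1 + cos(nφ_k − γ_n)] − F · R(φ) · 0.06022,

with torsional Fourier coefficients in kJ/mol, `R` the pull-pair distance
in Å (the *mechanical coordinate*), F in pN, and
1 pN·Å = 0.06022 kJ/mol. Throughout, k_B = 0.0083145 kJ/(mol·K).

### Torsional parameters

No torsional coefficients are prescribed by the problem, so the package
ships an editable parameter file (`inst/extdata/torsion_params.tsv`) with
OPLS-AA-style values chosen once on physical grounds:

- **C–C–S–S** (`CCSS`): V1 = 0.8, V3 = 6.0 kJ/mol — trans (closed) and
  gauche (open) minima of comparable depth, trans lower by ~0.6 kJ/mol,
  interconversion barriers of ~6 kJ/mol. This is the load-bearing choice:
  it makes open states dominate the unstretched ensemble entropically
  (two gauche wells vs one trans well per dihedral) while modest forces
  flip the balance.
- **C–S–S–C** (`CSSC`): V1 = 12, V2 = −31, V3 = 7.13 kJ/mol — minima at
  ±90°, a ~21 kJ/mol trans barrier and a ~40 kJ/mol cis barrier, the
  classic disulfide torsion profile.
- **generic sp3** (`SP3`): a threefold 3.0 kJ/mol barrier for the remaining
  single bonds of the cystine and polypeptide paths.

Everything downstream (landscapes, rulers) is re-derived from whatever
parameters are in force, so users can substitute their own file.

## Sampling and its oracle

`metropolisSample()` performs single-dihedral Metropolis moves: pick one
rotatable dihedral uniformly, propose a wrapped Gaussian step (default SD
30°), accept with min(1, exp(−ΔE/k_BT)). Defaults: burn-in 10% of steps,
thinning 10, start from the all-180° conformation. The core is compiled
(Rcpp) and uses R's RNG, so runs are bit-reproducible given a seed. A
2×10⁶-step DEDS run takes under a second on one CPU.

The sampler is validated against an independent oracle,
`quadratureReference()`: midpoint sums of exp(−E/k_BT) on a regular grid of
the dihedral torus, restricted to models with ≤ 3 dihedrals (the grid blows
up beyond that). Two numerical details matter. A max-energy shift guards
the exponentials against underflow at large force. And when the oracle's
closed/closed probability is compared with sampled values, the grid size is
chosen divisible by 36 so the 130°/230° band edges coincide with bin
boundaries — otherwise the state probabilities acquire an O(bin width)
discretization bias that a 3-SE comparison at 10⁶ samples can detect.

Standard errors of ensemble averages use batch means over 20 batches, not
naive i.i.d. errors: Metropolis samples are autocorrelated, and the naive
SE would overstate precision severalfold.

## Landscapes

`histogram2d()` bins (χ1, χ2) on the periodic torus (default 72 bins/axis,
i.e. 5° resolution — the resolution is a display/robustness compromise, not
a physical constant), normalizes to probability per bin (not density per
square degree), and attaches the Boltzmann inversion
`G = −k_B T ln P`, min-shifted to zero. Bins never visited are flagged
*unsampled* and carry `NA` rather than `Inf`: finite sampling cannot
distinguish a true zero from an unvisited basin, and infinities poison
downstream arithmetic. `fesToP()` inverts exactly on sampled bins (round
trip to 1e−10).

`forceScan()` repeats the sampler along a force ladder (per-force seeds
derived deterministically from a master seed) and reports open character,
closed/closed occupancy, mean R, mean Cα–Cα distance and the mean absolute
deviation of χ3 from its nearer ±90° minimum — the last as a scalar summary
of how load twists the S–S torsion toward 180°.

## The survey

`parsePdb()` delegates ATOM/HETATM parsing to `bio3d::read.pdb`, then
layers on what the survey needs: SSBOND records (bio3d does not expose
them), validation of truncated ATOM lines with the offending line number,
first-model-only handling of multi-model files (with a notice), and altloc
resolution keeping the highest-occupancy conformer (ties by altloc order).
`findDisulfides()` unions declared SSBOND pairs with geometric Sγ–Sγ
contacts (default cutoff 2.5 Å — covalent S–S is ~2.05 Å, the margin
absorbs low-resolution coordinates), deduplicates, and drops pairs missing
any of Cα/Cβ/Sγ with a warning. Measured bridges with S–S lengths outside
[1.8, 2.5] Å are rejected as mis-declared or broken.

Design choices worth stating:

- **Angle convention.** All dihedrals are reported in [0°, 360°) so the
  closed state is the single interval [130°, 230°]; signed (−180°, 180°]
  companions (`chi1_signed`, `chi2_signed`) are included because published
  values near the closed basin are ambiguous between the two conventions.
  The band is inclusive at both endpoints: the boundary has measure zero in
  real data and inclusivity makes tests deterministic.
- **Pair order.** Which cysteine supplies χ1 vs χ2 is a labelling choice;
  the survey orders by (chain, residue number), and the relabelling
  symmetry (χ1 ↔ χ2 exchange, χ3 reversal-invariant, distances unchanged)
  is tested.
- **Protein classes** (TDi, DO, inter-/intrachain Ig) are user-supplied
  metadata via a mapping file; only the inter/intrachain distinction is
  derivable from the coordinates (differing chain identifiers).

## Ruler and Bell model

`calibrateRuler()` interpolates mean Cα–Cα distance against force with a
monotone shape-preserving cubic (Hyman-filtered spline) — a parametric
elasticity model is deliberately avoided since the relation is simply "the
nonlinear curve the simulation produced". Monte-Carlo noise can produce
small non-monotonic dips; dips within the combined 3 SE of adjacent points
are repaired by isotonic regression (plus an epsilon strictification),
larger violations refuse calibration. Rulers are calibrated per model; the
observation that different compounds fall on a common curve is a *result*
one can check, not an input assumption, so no pooled fit is forced.

`inferForce()` inverts the curve by root finding to 0.1 pN and propagates
the calibration SE through the local slope. Distances below the zero-force
mean return 0 pN flagged `compressive/unstrained`; distances beyond the
maximal calibrated extension are an error rather than an extrapolation.

`rateEnhancement()` implements Bell's law k(F)/k0 = exp(F·Δx/k_B T). The
length parameter Δx has no canonical value here and must be supplied
explicitly; for orientation, Δx in the 0.3–0.6 Å range gives a 2–5× rate
increase at 100 pN and 300 K.

## Synthetic data

The generator exists so the whole pipeline can be built and tested without
downloads. `writeDisulfidePdb()` emits a two-cysteine fragment at prescribed
(χ1, χ2, χ3) as standard PDB text. One consequence is a precision floor:
PDB coordinates print at 10⁻³ Å, which quantizes re-measured dihedrals at
the ~0.03° level over 1.5–2 Å bonds. File round trips are therefore asserted
at 0.05°, while the in-memory internal→Cartesian→dihedral round trip is
held to 10⁻⁶°. Fixture angles sit at least 1° away from the 130°/230° band
edges so rounding can never flip a prescribed classification.

`sampleClass()` draws (χ1, χ2) from wrapped-Gaussian mixtures — wrapped
normals rather than von Mises for simplicity; at the spreads used (≤ 25°)
the difference is negligible — and maps each draw to a Cα–Cα distance
through the geometric fragment builder plus Gaussian noise (SD 0.3 Å). The
default class specifications emulate the surveyed populations: intrachain
Ig as a single component at (180°, 180°) with 25° spread and n = 927;
TDi (n = 40), DO (n = 27) and interchain Ig (n = 69) as mixtures over
open-state centres in the ±60°/±85° gauche regions with 20° spreads. The
centres and spreads are *emulation parameters of this package*, chosen to
reproduce the qualitative structure (closed/closed-rich vs open-rich
scatter, longer mean Cα–Cα distance for the strained class), not measured
values. `closedClosedProb()` gives each spec's exact mixture probability of
the closed/closed state, which the empirical tables match within binomial
error — that is what passing tests demonstrate. What they do not
demonstrate is anything about real crystallographic scatter: real
populations have correlated χ1/χ2 deviations, resolution-dependent noise,
and class boundaries far fuzzier than a mixture spec.

## What the reduction does and does not capture

The torsional surrogate reproduces, from first principles of its own energy
function: the open-dominated unstretched ensemble; the collapse onto
closed/closed under a few hundred pN; monotone growth of R and of the
closed/closed fraction with force (a thermodynamic identity,
d⟨R⟩/dF = Var(R)/k_BT ≥ 0); and pull-distance increases from 0 to 2 nN of
~2 Å (DEDS), ~3.7 Å (cystine) and ~8 Å (polypeptide path). It omits
solvent, bond-length/angle flexibility and excluded volume, so absolute
numbers carry model error of order tens of percent — the polypeptide
extension, in particular, overshoots because the reduced path is more
compact at zero force than a solvated loop would be. Force-to-distance
rulers calibrated on it are smooth and invertible but inherit the same
caveat.

Problem sizes used by the shipped tests and the acceptance script — 2×10⁵
to 4×10⁶ Monte-Carlo steps per force, 72–288-point quadrature grids — were
chosen so that Monte-Carlo standard errors are comfortably below the
effects being asserted; all are package choices and scale up trivially.

## Limitations

- No explicit solvent, metadynamics bias, or QM treatment; no bond
  scission. The S–S rupture chemistry itself is outside scope — only the
  conformational gating is modelled.
- No mmCIF parsing (PDB-format text only); no solvent-accessibility
  computation; no spiral/hook/staple sub-taxonomy of open states.
- The quadrature oracle is limited to ≤ 3 dihedrals; for cystine and the
  polypeptide path, validation rests on properties (monotonicity, symmetry,
  determinism) rather than exact expectations.
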