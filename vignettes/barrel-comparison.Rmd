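---
title: "Methods: comparing lipocalin beta-barrels with barrelscope"
author: "barrelscope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing lipocalin beta-barrels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrelscope)
```

barrelscope quantifies how a peripheral, pheromone-acting mouse major
urinary protein (darcin/MUP20) differs from a central MUP (MUP11) that
shares the same lipocalin fold: an eight-stranded antiparallel
beta-barrel whose interior — the calyx — binds small hydrophobic
pheromones. This vignette documents the models and conventions each
stage uses, the defaults and why they were chosen, what the synthetic
generators do and do not emulate, and the numerical edge cases.

## Structure handling

Ensembles are ordered lists of topologically identical models (one per
NMR conformer). Internally all residue numbers use mature-protein
numbering (residue 1 = first residue after the signal peptide), because
that is the numbering in which individual residues such as E118 or the
L54/I103 cavity gate are discussed; `read_ensemble(offset =)` maps
deposited numbering onto it. Only the first chain is read (these are
monomeric solution structures), the highest-occupancy alternate location
is kept, and insertion codes are rejected outright rather than guessed
at. Hydrogens are retained on read but excluded from the default
selections: "backbone" means N, CA, C, O and "heavy" means all
non-hydrogen atoms, so precision statistics can be reported for both
backbone and heavy-atom selections.

## Superposition and ensemble precision

Superposition is the closed-form least-squares rigid alignment
(covariance SVD with proper-rotation enforcement). It is deterministic
and exact, and the test suite cross-checks it against a brute-force
quaternion-search oracle that shares no code with the SVD path.
Collinear selections leave the rotation underdetermined; they are
flagged with a warning rather than silently resolved.

The ensemble precision statistic follows the common NMR convention: all
models are superposed onto the current per-atom coordinate mean, the
mean is recomputed, and the cycle repeats until the mean moves less than
1e-6 Å (cap: 100 iterations, always reached in 2–4 here). The "mean
structure" is the plain arithmetic mean of superposed coordinates, not a
physically regularised structure; different ensemble-analysis programs
differ at the few-hundredths-of-an-Ångström level on this convention, so
comparisons against published precision values should allow roughly
±0.05 Å. Single-model measurements (distances, cavities) use the
representative model, i.e. the model with the lowest RMSD to the final
mean, with ties broken toward the lowest index.

Distance measurements come in two forms: named-atom pairs (the
loop-pair tables, Cα to Cα, reported to two decimals) and
minimum-distance between residue groups over heavy atoms (the
cavity-width gates 54–103, 69–118, 82–118), with deterministic lexical
tie-breaking.

## Cavity detection

The calyx is found by a voxel flood-fill, chosen over alpha-shape
methods because it is deterministic, dependency-free and directly
testable against analytic fixtures:

1. a grid (default spacing 0.5 Å) covers the bounding box padded by
   (max vdW radius + 2·probe); the lattice is anchored to absolute
   multiples of the spacing so different probe radii share voxel
   centres;
2. voxels within (vdW + probe) of any heavy atom are blocked — vdW
   radii default to a Bondi-style table (C 1.70, N 1.55, O 1.52,
   S 1.80, H 1.20 Å) and are fully overridable;
3. free voxels reachable from the box boundary (6-connectivity) are
   exterior solvent;
4. the remaining free voxels are interior void; the largest connected
   component is the cavity (smaller voids are reported but unused —
   these proteins have a single dominant calyx);
5. volume = voxel count × spacing³.

Lining residues are those with a heavy atom within
(vdW + probe + spacing) of the cavity. A cavity voxel centre is an
exact certificate for that test, but the lattice can miss a valid
certificate by up to half a voxel diagonal, which makes raw
voxel-thresholded contact counts flicker across a probe sweep. A
sub-voxel refinement therefore rechecks near-misses by walking from
nearby cavity voxels toward the atom through continuum-free space. The
continuum contact set has a useful exact property: a probe ball of
radius p placed to touch an atom is contained in any touching ball of
radius p' > p shifted along the same contact direction, so the set of
residues contactable by a probe can only shrink as the probe grows.
With the refinement, reported contact counts inherit this monotonicity,
matching the behaviour used to argue that the pheromone protein's
cavity closes up faster than the central MUP's as the probe grows from
1.4 to 1.7 Å.

Accuracy was calibrated on the hollow-sphere oracle (shell radius 8 Å,
atom radius 1.5 Å, 600 lattice atoms), where the interior is exactly a
ball of radius (8 − 1.5 − probe): the 0.5 Å grid is within ~2% of the
analytic volume and the 0.25 Å grid within ~1.5%. Two caveats follow
from the discretisation: (i) volumes move by a fraction of a percent
under rigid motion of the input (boundary voxels re-tile; the error
scales with cavity surface area, not with one voxel volume), and (ii)
agreement with published volumes from alpha-shape programs is expected
only at the ±20% cross-method level, not exactly.

## CSP mapping

The combined amide perturbation is Δδ = √(ΔH² + (0.15·ΔN)²) in ppm —
the standard nitrogen down-weighting reflecting the ~6.5-fold wider
¹⁵N shift dispersion. Classification uses the endpoint titration point
against the reference (the maximum-shift convention appropriate when the
final point is in several-fold ligand excess), a cut-off of
Δδ ≥ 0.15 ppm, and the verdict "binds" iff at least one residue
crosses it. Intermediate points are kept for trajectories but do not
enter classification. Peaks flagged overlapped or unresolved are
excluded from numerators and denominators alike.

## Denaturation persistence

For urea series, a reference peak counts as "observed" at a level when
the same residue appears within matching tolerances (defaults
tol_H = 0.04, tol_N = 0.4 ppm — typical HSQC linewidths; the original
analysis software's matching rule is not published, so these are
deliberate, configurable choices). Presence is positional only;
intensity is not thresholded by default. Percentages are reported per
secondary-structure element and overall; an element with zero reference
peaks is undefined (NA), never 0. One known ambiguity: a peak that
*shifts* beyond tolerance is counted as disappeared, which conflates
chemical-shift change with true loss of the native resonance; with the
default tolerances and the generators' schedules the two coincide.

Secondary-structure elements are configuration, not computation: the
shipped maps (`inst/extdata/sse_darcin.yaml`, `sse_mup11.yaml`) encode
the strand/helix inventory of the two solution structures, with loops
L1–L9 defined as the inter-element gaps. Short 3₁₀ stretches nested
inside loops are listed but own no residues of their own under the
first-match assignment rule, so they report NA in persistence tables.

## Relaxation

T1/T2 series are fitted as I(t) = I₀·exp(−t/T) by Levenberg–Marquardt
least squares initialised from the log-linear fit. Constant or rising
intensity profiles are refused ("no decay") rather than returned with a
meaningless negative or infinite time constant.

## ITC

The one-site forward model uses the Wiseman cumulative-heat expression
with perfusion dilution: each injection of volume dV displaces an equal
volume of cell contents, so the macromolecule concentration after
injection i is M₀·Π(1 − dVⱼ/V₀) and the titrant concentration is
X_s·(1 − Π(1 − dVⱼ/V₀)). The measured per-injection heat applies the
displaced-volume correction ΔQᵢ = Qᵢ − Qᵢ₋₁ + (dVᵢ/V₀)(Qᵢ + Qᵢ₋₁)/2.
An alternative derivation — solving the binding quadratic per injection
with a root-finder — is kept in the test suite as an independent oracle;
the two agree to 1e-9 relative.

Fitting minimises squared per-injection heat residuals over
(N, log K_a, ΔH) with Levenberg–Marquardt from an automatic start
(N from the molar ratio at half cumulative heat, ΔH from the early
plateau, K_a from c ≈ 10) plus five jittered multi-starts under a fixed
seed; the best of the converged starts wins. The first injection is
discarded by default (standard practice for the diffusion-compromised
first injection; the generators still simulate it). The c-value
(K_a × cell concentration) is reported and a warning raised outside
[1, 10⁴], where K_D is weakly determined by isotherm shape. Temperature
defaults to 298.15 K and R = 1.9872×10⁻³ kcal/(mol·K); the identity
ΔG = ΔH − TΔS holds by construction in every `thermo_summary()`.

Sign conventions deserve one note: the published decomposition for the
tight binder is ΔH ≈ −13.1 kcal/mol with a small *unfavourable* entropy,
which in this package's convention is TΔS ≈ −3.9 kcal/mol (so
ΔG = ΔH − TΔS ≈ −9.2 kcal/mol, consistent with K_D ≈ 0.18 µM). Summary
figures elsewhere sometimes print the entropic term with the opposite
sign; `kd_from_thermo()` makes the internal-consistency check a
one-liner.

ΔΔG between two proteins is RT·ln(K_D,a/K_D,b), negative when a binds
tighter. Note that the printed "20-fold" affinity difference and the
K_D ratio 2.76/0.173 ≈ 16 are both kept in view; the package reports
the ratio its own fits produce.

## Synthetic generators: what they emulate, and what they do not

The generators exist so that every stage has inputs with known answers:

- `make_toy_barrel()` — a closed cylinder of pseudo-Cα atoms (default
  8 strands, radius 6 Å, rise 3 Å: the strand count of the lipocalin
  barrel at roughly its dimensions) with an optional circular mouth of
  exact rim radius. It validates cavity topology, aperture/probe logic
  and ensemble statistics (with per-model Gaussian jitter, default
  0.25 Å in the workflow — typical of a tight NMR ensemble). It is not
  a protein: no side chains, no sequence, no realistic packing.
- `make_hollow_sphere()` — the Fibonacci-lattice shell whose interior
  volume is exactly analytic; the cavity oracle.
- `make_titration_series()` — per-residue linear shift trajectories to
  prescribed endpoints, disappearance at/after prescribed levels,
  optional Gaussian shift jitter. Amide positions are drawn uniformly
  from typical ranges (¹H 7.5–9.5, ¹⁵N 105–130 ppm). Real titrations
  curve with binding saturation and show exchange broadening; none of
  that is modelled, so passing tests demonstrate correct bookkeeping
  and classification, not spectroscopic realism.
- `simulate_itc()` — the forward model plus i.i.d. Gaussian heat noise.
  Baseline drift and first-injection artefacts are not modelled (the
  fitter's discard-first default covers the latter).

All generators are pure functions of (parameters, seed).

## Problem sizes and determinism

The test suite and the analysis workflow run on deliberately desk-scale
problems: 600–4000-atom fixtures, 0.5 Å grids (0.25 Å where the
convergence claim needs it), 40-injection isotherms, 100–160-residue
peak lists, 60-replicate noise studies. These sizes make every result
exactly reproducible in seconds while still exercising each code path;
nothing in the method is specific to them, and a full-size protein
model (~1300 heavy atoms) runs through `compute_cavity()` at the
default grid in a few seconds.

## Known limitations

- The cavity method is a voxel approximation: volumes carry ~1–2%
  discretisation error and cross-method comparisons (alpha-shape
  programs) only hold to ~±20%.
- Cross-ensemble RMSD between two *different* proteins is implemented
  as representative-vs-representative superposition over matched
  residue numbers; published cross-ensemble figures may use other
  pairing conventions and should be treated as approximate.
- Persistence counting conflates "shifted beyond tolerance" with
  "disappeared" (see above).
- Only the single-site binding model is implemented; multi-site,
  sequential and competitive schemes are out of scope, as are raw
  power-trace baseline extraction and spectral processing upstream of
  peak lists.
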