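# barrelscope

Quantitative comparison of pheromone-carrier lipocalins — mouse major
urinary proteins (MUPs) — from NMR structure ensembles, HSQC titration
peak lists and isothermal titration calorimetry. The package was built
around one concrete question: what makes the male-specific pheromone
protein darcin (MUP20) different from a generic central MUP (MUP11),
given that the two share the same eight-stranded antiparallel beta-barrel
fold? The answer the analyses quantify: a smaller, narrower internal
binding calyx, tighter (enthalpy-driven) pheromone binding, and far
greater resistance to chemical denaturation.

## What it computes

- **Ensemble geometry** — multi-model PDB I/O, Kabsch least-squares
  superposition, iterative per-model RMSD to the ensemble mean (the
  standard NMR precision statistic), closest-to-mean representative
  model selection, and inter-loop / cavity-width distance tables.
- **Cavity analysis** — grid flood-fill detection of the enclosed
  hydrophobic calyx: voxels within (vdW + probe) of any heavy atom are
  blocked, the exterior is removed by flood fill from the box boundary,
  and the largest 6-connected interior component is the cavity. Reports
  volume (|voxels| × spacing³), lining residues, and probe-radius sweeps
  (1.4 → 1.7 Å) whose volumes and contact counts are monotone
  non-increasing.
- **Chemical-shift perturbation (CSP) mapping** — per-residue combined
  amide shift change Δδ = √(ΔH² + (0.15·ΔN)²) between a reference and an
  endpoint HSQC, with a binding verdict at the Δδ ≥ 0.15 ppm cut-off.
- **Urea-denaturation persistence** — percentage of native backbone NH
  peaks still observed at each urea level, per secondary-structure
  element and overall.
- **Relaxation** — single-exponential T1/T2 fits and heteronuclear NOE
  ratios.
- **ITC** — the one-site (Wiseman) isotherm with perfusion dilution
  tracking, forward simulation, three-parameter least-squares fitting of
  (N, K_a, ΔH), thermodynamic decomposition ΔG = RT·ln K_D = ΔH − TΔS,
  and ΔΔG = RT·ln(K_D,a / K_D,b) between two proteins.
- **Synthetic data** — generators with analytically known answers (toy
  barrels, hollow-sphere cavity oracles, titration series with
  prescribed shift trajectories and disappearance schedules) so the
  whole pipeline is testable without any external data.

## Worked example

```r
library(barrelscope)

# one-site ITC: simulate the published darcin parameters and refit
expt <- itc_experiment(cell_volume_ul = 200, cell_conc_uM = 40,
                       syringe_conc_uM = 400, injections_ul = rep(1, 40),
                       temperature_K = 298)
darcin <- onesite_params(N = 1, Ka = 1 / 0.173e-6, dH = -13.1, T = 298)
fit <- fit_onesite(simulate_itc(darcin, expt))
fit$thermo
#> K_D = 1.73e-07 M; dG = -9.22, dH = -13.10, TdS = -3.88 kcal/mol

# the affinity difference between the two proteins
ddg(0.173e-6, 2.76e-6, T = 298)
#> [1] -1.640173        # kcal/mol in favour of the tighter binder

# cavity detection validated against an analytic oracle
s <- make_hollow_sphere(shell_radius = 8, atom_radius = 1.5, n_atoms = 600)
compute_cavity(s, probe_radius = 1.4, grid_spacing = 0.5,
               vdw_radii = c(X = 1.5))$volume
#> [1] 563.75           # analytic value: 555.6 A^3
```

The interpretation: darcin's binding is strongly enthalpy-driven
(ΔH = −13.1 kcal/mol) with a small unfavourable entropic term
(TΔS ≈ −3.9 kcal/mol), and it binds the thiazole pheromone mimetic about
16-fold tighter than MUP11 (ΔΔG ≈ −1.6 kcal/mol).

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
full comparison on synthetic inputs, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_inputs.R      # synthetic bundle
Rscript analysis/02_structure_precision.R  # ensemble RMSD + distances
Rscript analysis/03_cavity_analysis.R      # volumes, sweeps, oracle check
Rscript analysis/04_titration_analysis.R   # CSP + urea persistence
Rscript analysis/05_itc_analysis.R         # fits, thermodynamics, ddG
Rscript analysis/06_full_report.R          # combined JSON/text report
```

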