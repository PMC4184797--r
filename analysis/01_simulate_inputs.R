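#!/usr/bin/env Rscript
# Build the synthetic input bundle every later analysis step consumes:
# two toy-barrel "proteins" that differ only in barrel radius (narrow =
# darcin-like, wide = MUP11-like), ligand-titration peak-list series with
# engineered binding/non-binding endpoints, a urea series with a loop-8
# disappearance schedule, and noise-free one-site ITC isotherms at the
# published binding parameters. Everything is written through the
# package's file formats so downstream steps exercise real I/O.

library(barrelscope)
set.seed(20260925)

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# -- structures: 20-model ensembles, jitter ~ typical NMR precision -------
narrow <- make_toy_barrel(barrel_radius = 5.5, n_models = 20,
                          jitter_sd = 0.25, seed = 101)
wide <- make_toy_barrel(barrel_radius = 6.0, n_models = 20,
                        jitter_sd = 0.25, seed = 102)
write_ensemble(narrow, file.path(out, "narrow_barrel.pdb"))
write_ensemble(wide, file.path(out, "wide_barrel.pdb"))
cat("wrote two 20-model toy ensembles (radii 5.5 / 6.0 A)\n")

# -- ligand titrations: binder vs non-binder endpoints --------------------
# strong binder: several residues pushed well over the 0.15 ppm cut-off
binder <- make_titration_series(
  160, levels = c(0, 1, 2, 5),
  csp_endpoints = data.frame(residue = c(42, 54, 69, 82, 103, 118),
                             dh = c(0.30, 0.22, 0.18, 0.25, 0.20, 0.35),
                             dn = c(1.2, 0.8, 1.5, 0.6, 1.0, 2.0)),
  noise_sd = 0.003, axis_label = "ligand:protein molar ratio", seed = 201)
write_titration_series(binder, out, name = "sbt_titration")
# non-binder: nothing above 0.12 ppm
nonbinder <- make_titration_series(
  160, levels = c(0, 1, 2, 5),
  csp_endpoints = data.frame(residue = c(42, 54), dh = c(0.12, 0.08),
                             dn = c(0, 0.3)),
  noise_sd = 0.003, axis_label = "ligand:protein molar ratio", seed = 202)
write_titration_series(nonbinder, out, name = "npn_titration")
cat("wrote binder and non-binder titration series (160 residues)\n")

# -- urea denaturation: only loop 8 destabilised above 5 M ----------------
urea <- make_titration_series(
  160, levels = c(0, 1, 2.5, 4, 5, 5.5, 6.5, 7.5),
  disappearance = data.frame(residue = 122:127, level = 5.5),
  axis_label = "urea M", seed = 301)
write_titration_series(urea, out, name = "urea_series")
cat("wrote urea series with a loop-8 disappearance schedule\n")

# -- ITC: noise-free isotherms at the published parameter sets ------------
expt <- itc_experiment(cell_volume_ul = 200, cell_conc_uM = 40,
                       syringe_conc_uM = 400, injections_ul = rep(1, 40),
                       temperature_K = 298)
params <- list(darcin = onesite_params(1.0, 1 / 0.173e-6, -13.1, 298),
               mup11 = onesite_params(1.0, 1 / 2.76e-6, -9.8, 298))
for (nm in names(params)) {
  sim <- simulate_itc(params[[nm]], expt)
  write_itc_csv(sim, file.path(out, paste0("itc_", nm, ".csv")))
  yaml::write_yaml(list(cell_volume_ul = 200, cell_conc_uM = 40,
                        syringe_conc_uM = 400, temperature_K = 298),
                   file.path(out, paste0("itc_", nm, ".yaml")))
}
cat("wrote noise-free one-site isotherms (40 x 1 ul, 40 uM cell)\n")
cat("bundle complete under", out, "\n")
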