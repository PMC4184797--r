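#!/usr/bin/env Rscript
# Cavity detection: analytic validation on the hollow-sphere oracle, then
# volumes, lining residues, probe sweeps and central-width distances for
# the two synthetic barrels. The narrow barrel should show the smaller
# cavity and the sharper loss of volume as the probe grows - the
# behaviour that separates the pheromone protein from the central MUP.

library(barrelscope)
src <- "results/synthetic"
if (!dir.exists(src)) stop("run analysis/01_simulate_inputs.R first")
out <- "results/tables"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# -- oracle check ---------------------------------------------------------
sphere <- make_hollow_sphere(shell_radius = 8, atom_radius = 1.5,
                             n_atoms = 600)
truth <- sphere_cavity_volume(8, 1.5, 1.4)
oracle <- do.call(rbind, lapply(c(0.5, 0.25), function(g) {
  v <- compute_cavity(sphere, 1.4, grid_spacing = g,
                      vdw_radii = c(X = 1.5))$volume
  data.frame(grid = g, volume = v, analytic = round(truth, 1),
             rel_error = round(abs(v / truth - 1), 4))
}))
write.csv(oracle, file.path(out, "cavity_oracle.csv"), row.names = FALSE)
print(oracle, row.names = FALSE)

# -- synthetic barrels ----------------------------------------------------
radii <- seq(1.4, 1.7, by = 0.1)
rows <- list(); sweeps <- list()
for (nm in c("narrow", "wide")) {
  ens <- read_ensemble(file.path(src, paste0(nm, "_barrel.pdb")))
  model <- ens$models[[representative_model(ens)]]
  cav <- compute_cavity(model)
  sw <- probe_sweep(model, radii)
  rows[[nm]] <- data.frame(structure = nm, volume = cav$volume,
                           n_lining = nrow(cav$lining),
                           n_components = cav$n_components)
  sweeps[[nm]] <- cbind(structure = nm, sw$table)
}
cavities <- do.call(rbind, rows)
sweep_tab <- do.call(rbind, sweeps)
write.csv(cavities, file.path(out, "cavity_volumes.csv"), row.names = FALSE)
write.csv(sweep_tab, file.path(out, "probe_sweep.csv"), row.names = FALSE)
print(cavities, row.names = FALSE)
print(sweep_tab, row.names = FALSE)
stopifnot(cavities$volume[cavities$structure == "narrow"] <
            cavities$volume[cavities$structure == "wide"])
cat("narrow barrel cavity is smaller, as designed\n")
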