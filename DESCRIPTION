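Package: barrelscope
Title: Comparative Structural and Biophysical Analysis of Lipocalin Beta-Barrels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative comparison of pheromone-carrier lipocalins
    (mouse major urinary proteins) from NMR ensembles and titration data.
    Provides multi-model PDB ensemble handling, least-squares superposition
    and ensemble precision statistics, inter-loop and cavity-width distance
    measurements, grid flood-fill detection of the internal ligand-binding
    calyx with probe-radius sweeps, chemical-shift-perturbation mapping of
    ligand binding from HSQC peak lists, urea-denaturation peak-persistence
    profiles per secondary-structure element, relaxation curve fitting, and
    one-site isothermal titration calorimetry simulation and fitting with
    thermodynamic decomposition. Includes synthetic-data generators with
    analytically known answers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
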