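# end-to-end orchestration over a fully synthetic input bundle

make_bundle <- function(dir) {
  # two "proteins": ensembles with different barrel radii so the cavity
  # comparison has a direction
  for (spec in list(list(name = "alpha", radius = 5.5),
                    list(name = "beta", radius = 6))) {
    ens <- make_toy_barrel(barrel_radius = spec$radius, n_models = 3,
                           jitter_sd = 0.15, seed = 42)
    write_ensemble(ens, file.path(dir, paste0(spec$name, ".pdb")))
  }
  # titration with engineered binding for alpha only
  bind <- make_titration_series(40, levels = c(0, 2, 5),
                                csp_endpoints = data.frame(
                                  residue = c(5, 12), dh = 0.3, dn = 1))
  write_titration_series(bind, dir, name = "alpha_sbt")
  none <- make_titration_series(40, levels = c(0, 2, 5),
                                csp_endpoints = data.frame(
                                  residue = 5, dh = 0.10, dn = 0))
  write_titration_series(none, dir, name = "alpha_npn")
  # urea persistence: residues 30..39 vanish above level 5
  sse <- data.frame(name = c("b1", "L8"), start = c(1, 30),
                    end = c(20, 39), kind = c("strand", "loop"))
  yaml::write_yaml(list(elements = lapply(seq_len(nrow(sse)), function(i)
    as.list(sse[i, ]))), file.path(dir, "sse.yaml"))
  urea <- make_titration_series(40, levels = c(0, 3, 6),
                                disappearance = data.frame(residue = 30:39,
                                                           level = 6))
  write_titration_series(urea, dir, name = "urea")
  # ITC bundles for the two parameter sets
  for (x in list(list(name = "itc_a", p = fig6a_params()),
                 list(name = "itc_b", p = fig6b_params()))) {
    sim <- simulate_itc(x$p, standard_itc_expt())
    write_itc_csv(sim, file.path(dir, paste0(x$name, ".csv")))
    yaml::write_yaml(list(cell_volume_ul = 200, cell_conc_uM = 40,
                          syringe_conc_uM = 400, temperature_K = 298),
                     file.path(dir, paste0(x$name, ".yaml")))
  }
  list(
    structures = list(
      list(name = "alpha", pdb = file.path(dir, "alpha.pdb"),
           cavity = list(sweep = c(1.4, 1.7), widths = FALSE)),
      list(name = "beta", pdb = file.path(dir, "beta.pdb"))),
    titrations = list(
      list(name = "alpha_sbt", manifest = file.path(dir, "alpha_sbt.yaml")),
      list(name = "alpha_npn", manifest = file.path(dir, "alpha_npn.yaml"))),
    denaturation = list(
      list(name = "alpha_urea", manifest = file.path(dir, "urea.yaml"),
           sse = file.path(dir, "sse.yaml"))),
    itc = list(
      experiments = list(
        list(name = "alpha", data = file.path(dir, "itc_a.csv"),
             config = file.path(dir, "itc_a.yaml")),
        list(name = "beta", data = file.path(dir, "itc_b.csv"),
             config = file.path(dir, "itc_b.yaml"))),
      ddg = list(a = "alpha", b = "beta")))
}

test_that("a full synthetic bundle produces every report section", {
  dir <- withr::local_tempdir()
  config <- make_bundle(dir)
  report <- run_comparison(config)
  expect_s3_class(report, "comparison_report")
  expect_named(report$precision, c("alpha", "beta"))
  expect_named(report$cavity, c("alpha", "beta"))
  # the narrower barrel has the smaller cavity
  expect_lt(report$cavity$alpha$volume, report$cavity$beta$volume)
  expect_true(report$csp$alpha_sbt$binds)
  expect_false(report$csp$alpha_npn$binds)
  ov <- report$persistence$alpha_urea$overall
  expect_equal(ov$percent[1], 100)
  expect_equal(ov$percent[3], 75)          # 10 of 40 deleted at the top
  expect_equal(report$itc$alpha$K_D_uM, 0.173, tolerance = 1e-4)
  expect_equal(report$itc$beta$K_D_uM, 2.76, tolerance = 1e-4)
  expect_equal(report$itc$ddg$ddG, -1.64, tolerance = 0.005)
  expect_gt(length(report$provenance), 8)
})

test_that("reports are deterministic and partial configs degrade politely", {
  dir <- withr::local_tempdir()
  config <- make_bundle(dir)
  config$titrations <- NULL
  config$denaturation <- NULL
  config$itc <- NULL
  report <- suppressWarnings(run_comparison(config))
  expect_null(report$csp)
  expect_false(is.null(report$cavity))
  w <- capture_warnings(run_comparison(config))
  expect_true(any(grepl("titrations", w)))
  expect_true(any(grepl("denaturation", w)))
  out1 <- file.path(dir, "r1"); out2 <- file.path(dir, "r2")
  write_report(report, out1)
  write_report(suppressWarnings(run_comparison(config)), out2)
  expect_identical(readLines(file.path(out1, "report.json")),
                   readLines(file.path(out2, "report.json")))
  expect_true(file.exists(file.path(out1, "report.txt")))
})

test_that("an empty config is a validation error listing required keys", {
  expect_error(run_comparison(list()), "structures")
})
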