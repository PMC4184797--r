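test_that("forward isotherm matches the independent equilibrium solver", {
  p <- onesite_params(N = 1, Ka = 1e6, dH = -10, T = 298)
  e <- standard_itc_expt()
  h <- onesite_heats(p, e)
  ho <- oracle_itc_heats(p, e)
  expect_lt(max(abs(h - ho) / pmax(abs(ho), 1e-9)), 1e-6)
  # and for an asymmetric schedule
  e2 <- itc_experiment(cell_volume_ul = 200, cell_conc_uM = 100,
                       syringe_conc_uM = 1000,
                       injections_ul = c(0.5, rep(2, 19)),
                       temperature_K = 298)
  p2 <- onesite_params(N = 0.8, Ka = 3e5, dH = 5.5, T = 298)
  expect_lt(max(abs(onesite_heats(p2, e2) - oracle_itc_heats(p2, e2)) /
                  pmax(abs(oracle_itc_heats(p2, e2)), 1e-9)), 1e-6)
})

test_that("zero enthalpy gives zero heats", {
  p <- onesite_params(N = 1, Ka = 1e6, dH = 0, T = 298)
  expect_equal(onesite_heats(p, standard_itc_expt()), rep(0, 40))
})

test_that("the stoichiometric limit recovers dH times moles injected", {
  # Ka huge, titrant far below saturation: every mole injected binds
  p <- onesite_params(N = 1, Ka = 1e12, dH = -10, T = 298)
  e <- itc_experiment(cell_volume_ul = 200, cell_conc_uM = 100,
                      syringe_conc_uM = 400, injections_ul = rep(1, 10),
                      temperature_K = 298)
  h <- onesite_heats(p, e)
  moles <- 400e-6 * 10e-6                       # mol after 10 x 1 ul
  expect_equal(sum(h) * 1e-9, -10 * moles, tolerance = 0.01)
})

test_that("total heat approaches N M V0 dH at high c", {
  p <- onesite_params(N = 1, Ka = 5e7, dH = -12, T = 298)   # c = 2000
  e <- itc_experiment(cell_volume_ul = 200, cell_conc_uM = 40,
                      syringe_conc_uM = 800, injections_ul = rep(1, 40),
                      temperature_K = 298)
  h <- onesite_heats(p, e)
  expect_equal(sum(h) * 1e-9, 1 * 40e-6 * 200e-6 * -12, tolerance = 0.01)
})

test_that("simulation is deterministic under a fixed seed", {
  p <- fig6a_params()
  e <- standard_itc_expt()
  expect_identical(simulate_itc(p, e)$heats_ucal, onesite_heats(p, e))
  s1 <- simulate_itc(p, e, noise_sd = 0.1, seed = 7)
  s2 <- simulate_itc(p, e, noise_sd = 0.1, seed = 7)
  expect_identical(s1$heats_ucal, s2$heats_ucal)
  expect_false(identical(s1$heats_ucal,
                         simulate_itc(p, e, noise_sd = 0.1,
                                      seed = 8)$heats_ucal))
})

test_that("simulated noise has the requested scale", {
  p <- fig6a_params()
  e <- itc_experiment(cell_volume_ul = 200, cell_conc_uM = 40,
                      syringe_conc_uM = 400, injections_ul = rep(1, 5),
                      temperature_K = 298)
  base <- onesite_heats(p, e)
  set.seed(123)
  reps <- replicate(1000, simulate_itc(p, e, noise_sd = 0.1)$heats_ucal -
                            base)
  sds <- apply(reps, 1, sd)
  expect_true(all(abs(sds / 0.1 - 1) < 0.10))
})

test_that("noise-free fits recover generating parameters exactly", {
  e <- standard_itc_expt()
  for (p in list(fig6a_params(), fig6b_params())) {
    fit <- fit_onesite(simulate_itc(p, e))
    expect_equal(fit$params$N, p$N, tolerance = 1e-6)
    expect_equal(fit$params$Ka, p$Ka, tolerance = 1e-6)
    expect_equal(fit$params$dH, p$dH, tolerance = 1e-6)
    expect_equal(fit$thermo$dG, fit$thermo$dH - fit$thermo$TdS,
                 tolerance = 1e-12)
  }
})

test_that("noisy fits recover K_D within 10%", {
  p <- fig6b_params()
  e <- standard_itc_expt()
  fit <- fit_onesite(simulate_itc(p, e, noise_sd = 0.05, seed = 11))
  expect_lt(abs(fit$thermo$K_D / (1 / p$Ka) - 1), 0.10)
})

test_that("repeated noisy refits are unbiased for K_D", {
  p <- fig6b_params()
  e <- standard_itc_expt()
  kds <- vapply(1:60, function(s) {
    fit_onesite(simulate_itc(p, e, noise_sd = 0.05, seed = s))$thermo$K_D
  }, numeric(1))
  se <- sd(kds) / sqrt(length(kds))
  expect_lt(abs(mean(kds) - 1 / p$Ka), 2.5 * se + 1e-12)
})

test_that("degenerate heats and weak c-values are flagged", {
  e <- standard_itc_expt()
  e$heats_ucal <- rep(0, 40)
  expect_error(fit_onesite(e), "no heat signal")
  # c far below 1: fit proceeds with a warning
  weak <- onesite_params(N = 1, Ka = 1e3, dH = -10, T = 298)
  sim <- simulate_itc(weak, standard_itc_expt())
  expect_warning(try(fit_onesite(sim), silent = TRUE), "c-value")
  short <- itc_experiment(cell_conc_uM = 40, syringe_conc_uM = 400,
                          injections_ul = rep(1, 5), temperature_K = 298)
  short$heats_ucal <- rep(-1, 5)
  expect_error(fit_onesite(short), "at least 6")
})

test_that("thermodynamic identities and ddG behave as closed forms", {
  th <- thermo_summary(onesite_params(N = 1, Ka = 2e6, dH = -11, T = 300))
  expect_equal(th$dG, th$dH - th$TdS, tolerance = 1e-12)
  expect_equal(th$dG, 1.9872e-3 * 300 * log(th$K_D), tolerance = 1e-12)
  expect_equal(ddg(1e-6, 1e-6, 298), 0)
  # an e-fold affinity ratio costs exactly RT
  expect_equal(ddg(exp(1) * 1e-6, 1e-6, 298), 1.9872e-3 * 298)
  expect_equal(kd_from_thermo(-13.1, -3.9, 298),
               exp((-13.1 + 3.9) / (1.9872e-3 * 298)))
})
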