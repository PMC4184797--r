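# One-site ITC: forward isotherm (Wiseman model with perfusion dilution),
# simulation, three-parameter least-squares fitting, and thermodynamic
# decomposition.
#
# Perfusion convention: each injection of volume dV displaces an equal
# volume of cell contents, so after injection j the macromolecule
# concentration scales by (1 - dV_j/V0) and the total titrant
# concentration obeys X <- X (1 - dV_j/V0) + X_syr dV_j/V0; equivalently
# M_i = M0 prod(1 - dV_j/V0) and, for a constant syringe concentration,
# X_i = X_syr (1 - prod(1 - dV_j/V0)). The measured per-injection heat is
# dQ_i = Q_i - Q_{i-1} + (dV_i/V0) (Q_i + Q_{i-1})/2, the usual correction
# for heat carried out with the displaced volume.

#' One-site binding parameters
#'
#' @param N stoichiometry (sites per macromolecule), dimensionless, > 0.
#' @param Ka association constant, 1/M, > 0 (K_D = 1/Ka).
#' @param dH molar binding enthalpy, kcal/mol.
#' @param T temperature, K (default 298.15, i.e. 25 C).
#' @return list of class `"onesite_params"`.
#' @export
onesite_params <- function(N, Ka, dH, T = 298.15) {
  stopifnot(N > 0, Ka > 0, T > 0)
  structure(list(N = N, Ka = Ka, dH = dH, T = T), class = "onesite_params")
}

#' ITC experiment description
#'
#' @param cell_volume_ul calorimeter cell volume in microlitres
#'   (default 200, an ITC200-class cell).
#' @param cell_conc_uM starting macromolecule concentration in the cell,
#'   micromolar.
#' @param syringe_conc_uM titrant concentration in the syringe, micromolar.
#' @param injections_ul ordered injection volumes, microlitres.
#' @param heats_ucal observed per-injection heats, microcalories (NULL for
#'   a schedule awaiting simulation or measurement).
#' @param temperature_K experiment temperature (default 298.15).
#' @param discard_first drop the first injection from fits (default TRUE;
#'   standard practice for the diffusion-compromised first injection).
#' @return list of class `"itc_experiment"`.
#' @export
itc_experiment <- function(cell_volume_ul = 200, cell_conc_uM,
                           syringe_conc_uM, injections_ul = rep(1, 40),
                           heats_ucal = NULL, temperature_K = 298.15,
                           discard_first = TRUE) {
  stopifnot(cell_volume_ul > 0, cell_conc_uM > 0, syringe_conc_uM > 0,
            all(injections_ul > 0))
  if (!is.null(heats_ucal))
    stopifnot(length(heats_ucal) == length(injections_ul))
  structure(list(cell_volume_ul = cell_volume_ul,
                 cell_conc_uM = cell_conc_uM,
                 syringe_conc_uM = syringe_conc_uM,
                 injections_ul = injections_ul, heats_ucal = heats_ucal,
                 temperature_K = temperature_K,
                 discard_first = discard_first),
            class = "itc_experiment")
}

# cell concentrations (M) after each injection under the perfusion model
.itc_concentrations <- function(expt) {
  f <- expt$injections_ul / expt$cell_volume_ul
  dil <- cumprod(1 - f)
  M0 <- expt$cell_conc_uM * 1e-6
  Xs <- expt$syringe_conc_uM * 1e-6
  list(Mt = M0 * dil, Xt = Xs * (1 - dil), f = f)
}

#' Per-injection heats of the one-site binding isotherm
#'
#' Closed-form single-site model: with cell concentrations M_t (sites
#' N M_t) and total titrant X_t after injection i, the cumulative heat is
#' Q_i = (N M_t dH V0 / 2) (b - sqrt(b^2 - 4 X_t/(N M_t))) with
#' b = 1 + X_t/(N M_t) + 1/(N Ka M_t); per-injection heats apply the
#' displaced-volume correction (see source header).
#'
#' @param params a [onesite_params()].
#' @param expt an [itc_experiment()] (its heats, if any, are ignored).
#' @return numeric vector of per-injection heats in microcalories.
#' @export
onesite_heats <- function(params, expt) {
  stopifnot(inherits(params, "onesite_params"),
            inherits(expt, "itc_experiment"))
  cc <- .itc_concentrations(expt)
  V0 <- expt$cell_volume_ul * 1e-6                   # L
  sites <- params$N * cc$Mt
  b <- 1 + cc$Xt / sites + 1 / (params$Ka * sites)
  disc <- b^2 - 4 * cc$Xt / sites
  if (any(disc < -1e-12)) stop("negative discriminant in binding quadratic")
  disc[disc < 0] <- 0
  # cumulative heat in kcal, referenced to the cell volume
  Q <- sites * params$dH * V0 / 2 * (b - sqrt(disc))
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev + cc$f * (Q + Qprev) / 2
  dQ * 1e9                                           # kcal -> ucal
}

#' Simulate a one-site ITC experiment
#'
#' Forward model plus optional i.i.d. Gaussian noise on the per-injection
#' heats; reproducible under a fixed seed.
#'
#' @param params a [onesite_params()].
#' @param expt an [itc_experiment()] giving schedule and concentrations.
#' @param noise_sd Gaussian noise SD in microcalories (default 0).
#' @param seed RNG seed (used only when `noise_sd > 0`; NULL = current RNG
#'   state).
#' @return the experiment with `heats_ucal` filled in.
#' @export
simulate_itc <- function(params, expt, noise_sd = 0, seed = NULL) {
  stopifnot(noise_sd >= 0)
  heats <- onesite_heats(params, expt)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    heats <- heats + rnorm(length(heats), 0, noise_sd)
  }
  expt$heats_ucal <- heats
  expt
}

.auto_init <- function(expt) {
  heats <- expt$heats_ucal
  cc <- .itc_concentrations(expt)
  ratio <- cc$Xt / cc$Mt
  Qcum <- cumsum(heats)
  half <- which.min(abs(Qcum - 0.5 * Qcum[length(Qcum)]))
  N0 <- max(ratio[half], 0.1)
  # enthalpy from the early plateau: heat per mole injected
  mol1 <- expt$syringe_conc_uM * 1e-6 * expt$injections_ul[2] * 1e-6
  dH0 <- heats[2] * 1e-9 / mol1
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -1
  Ka0 <- 10 / (expt$cell_conc_uM * 1e-6)   # c ~ 10 as a generic start
  onesite_params(N = N0, Ka = Ka0, dH = dH0, T = expt$temperature_K)
}

#' Thermodynamic decomposition of a one-site fit
#'
#' dG = R T ln(K_D), TdS = dH - dG, with R = 1.9872e-3 kcal/(mol K). The
#' identity dG = dH - TdS holds exactly by construction.
#'
#' @param params a [onesite_params()].
#' @return list of class `"thermo_summary"`: `dG`, `dH`, `TdS` (kcal/mol)
#'   and `K_D` (M).
#' @export
thermo_summary <- function(params) {
  K_D <- 1 / params$Ka
  dG <- R_KCAL * params$T * log(K_D)
  structure(list(dG = dG, dH = params$dH, TdS = params$dH - dG, K_D = K_D),
            class = "thermo_summary")
}

#' @export
print.thermo_summary <- function(x, ...) {
  cat(sprintf("K_D = %.3g M; dG = %.2f, dH = %.2f, TdS = %.2f kcal/mol\n",
              x$K_D, x$dG, x$dH, x$TdS))
  invisible(x)
}

#' Fit the one-site model to measured heats
#'
#' Least-squares minimisation of observed minus modelled per-injection
#' heats over (N, Ka, dH), with Ka optimised on the log scale.
#' Levenberg-Marquardt from an automatic initial guess plus jittered
#' multi-starts guards against local minima. The first injection is
#' excluded when `discard_first` is set on the experiment.
#'
#' @param expt an [itc_experiment()] with `heats_ucal`.
#' @param init optional [onesite_params()] initial guess (default: auto).
#' @param n_starts number of additional jittered starts (default 5).
#' @param seed RNG seed for the jitter (default 1; fixed for
#'   reproducibility).
#' @return list of class `"onesite_fit"`: `params` ([onesite_params()]),
#'   `thermo` ([thermo_summary()]), `residuals_ucal`, `sse`, `c_value`.
#' @export
fit_onesite <- function(expt, init = NULL, n_starts = 5, seed = 1) {
  stopifnot(inherits(expt, "itc_experiment"))
  heats <- expt$heats_ucal
  if (is.null(heats)) stop("experiment has no measured heats")
  use <- seq_along(heats)
  if (isTRUE(expt$discard_first)) use <- use[-1]
  if (length(use) < 6) stop("need at least 6 usable injections")
  if (max(abs(heats[use])) < 1e-9)
    stop("no heat signal: enthalpy not identifiable")
  model_heats <- function(par) {
    p <- onesite_params(N = par[1], Ka = exp(par[2]), dH = par[3],
                        T = expt$temperature_K)
    onesite_heats(p, expt)
  }
  resid_fn <- function(par) {
    if (par[1] <= 0) return(rep(1e6, length(use)))
    heats[use] - model_heats(par)[use]
  }
  if (is.null(init)) init <- .auto_init(expt)
  p0 <- c(init$N, log(init$Ka), init$dH)
  starts <- list(p0)
  if (n_starts > 0) {
    set.seed(seed)
    for (k in seq_len(n_starts))
      starts[[k + 1]] <- p0 * exp(rnorm(3, 0, 0.3))
  }
  best <- NULL
  for (s in starts) {
    f <- tryCatch(minpack.lm::nls.lm(par = s, fn = resid_fn,
          control = minpack.lm::nls.lm.control(maxiter = 500,
                                               ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(f)) next
    sse <- sum(f$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = f, sse = sse)
  }
  if (is.null(best)) stop("one-site fit did not converge from any start")
  par <- best$fit$par
  params <- onesite_params(N = par[1], Ka = exp(par[2]), dH = par[3],
                           T = expt$temperature_K)
  c_value <- params$Ka * expt$cell_conc_uM * 1e-6
  if (c_value < 1 || c_value > 1e4)
    warning(sprintf("c-value %.3g outside [1, 1e4]: K_D weakly determined",
                    c_value))
  structure(list(params = params, thermo = thermo_summary(params),
                 residuals_ucal = heats[use] - model_heats(par)[use],
                 sse = best$sse, c_value = c_value, convergence = best$fit),
            class = "onesite_fit")
}

#' @export
print.onesite_fit <- function(x, ...) {
  cat(sprintf("One-site fit: N = %.3f, K_D = %.3g M, dH = %.2f kcal/mol\n",
              x$params$N, x$thermo$K_D, x$params$dH))
  cat(sprintf("  c = %.3g, SSE = %.3g ucal^2\n", x$c_value, x$sse))
  invisible(x)
}

#' Binding free-energy difference from two dissociation constants
#'
#' ddG = R T ln(K_D_a / K_D_b), kcal/mol; negative when a binds tighter
#' than b.
#'
#' @param kd_a,kd_b dissociation constants, M.
#' @param T temperature, K (default 298).
#' @return ddG in kcal/mol.
#' @export
ddg <- function(kd_a, kd_b, T = 298) {
  stopifnot(kd_a > 0, kd_b > 0, T > 0)
  R_KCAL * T * log(kd_a / kd_b)
}

#' Dissociation constant implied by an enthalpy/entropy decomposition
#'
#' Inverts dG = dH - TdS and dG = R T ln(K_D): a desk check of the
#' internal consistency of printed thermodynamic values.
#'
#' @param dH molar enthalpy, kcal/mol.
#' @param TdS entropic term T*dS, kcal/mol (negative when entropy is
#'   unfavourable).
#' @param T temperature, K.
#' @return K_D in M.
#' @export
kd_from_thermo <- function(dH, TdS, T = 298) {
  exp((dH - TdS) / (R_KCAL * T))
}
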