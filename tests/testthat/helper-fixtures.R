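# Shared fixtures and independent brute-force oracles.

# tiny hand-built model: coordinates given as an n x 3 matrix
toy_model <- function(xyz, resno = seq_len(nrow(xyz)), atom = "CA",
                      element = "C", resname = "GLY") {
  n <- nrow(xyz)
  structure_model(resno = resno, resname = rep_len(resname, n),
                  atom = rep_len(atom, n), element = rep_len(element, n),
                  xyz = xyz)
}

rigid_move <- function(model, angle = 0.7, axis_shift = c(5, -3, 2)) {
  R <- matrix(c(cos(angle), sin(angle), 0,
                -sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3)
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% R
  xyz <- sweep(xyz, 2, axis_shift, "+")
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

# --- brute-force rotation-search oracle for superposition RMSD ------------

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# random quaternion sampling + simplex polish; shares no code with the
# SVD path it checks
oracle_superpose_rmsd <- function(P, Q, n_grid = 3000, seed = 42) {
  set.seed(seed)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  f <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  qs <- matrix(rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, f)
  best <- qs[which.min(vals), ]
  opt <- optim(best, f, control = list(reltol = 1e-15, maxit = 10000))
  opt <- optim(opt$par, f, control = list(reltol = 1e-15, maxit = 10000))
  opt$value
}

# --- independent per-injection equilibrium solver for the one-site model --

oracle_itc_heats <- function(params, expt) {
  f <- expt$injections_ul / expt$cell_volume_ul
  dil <- cumprod(1 - f)
  Mt <- expt$cell_conc_uM * 1e-6 * dil
  Xt <- expt$syringe_conc_uM * 1e-6 * (1 - dil)
  V0 <- expt$cell_volume_ul * 1e-6
  Q <- vapply(seq_along(Mt), function(i) {
    St <- params$N * Mt[i]
    g <- function(C)
      C - St * (Xt[i] - C) * params$Ka / (1 + params$Ka * (Xt[i] - C))
    C <- uniroot(g, c(0, min(St, Xt[i])), tol = 1e-16)$root
    C * params$dH * V0
  }, numeric(1))
  Qp <- c(0, Q[-length(Q)])
  (Q - Qp + f * (Q + Qp) / 2) * 1e9
}

fig6a_params <- function() onesite_params(N = 1, Ka = 1 / 0.173e-6,
                                          dH = -13.1, T = 298)
fig6b_params <- function() onesite_params(N = 1, Ka = 1 / 2.76e-6,
                                          dH = -9.8, T = 298)
standard_itc_expt <- function() itc_experiment(cell_volume_ul = 200,
                                               cell_conc_uM = 40,
                                               syringe_conc_uM = 400,
                                               injections_ul = rep(1, 40),
                                               temperature_K = 298)

extdata <- function(...) system.file("extdata", ..., package = "barrelscope")
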