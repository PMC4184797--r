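# Synthetic fixtures with analytically known answers: toy beta-barrel-like
# atom cylinders, hollow-sphere cavity oracles, and titration peak-list
# series with prescribed shift trajectories and disappearance schedules.
# All generators are pure functions of their arguments and seed, and write
# through the same on-disk formats the readers consume.

.ring <- function(radius, z, spacing = 2) {
  if (radius <= 0) return(matrix(c(0, 0, z), ncol = 3))
  n <- max(6L, ceiling(2 * pi * radius / spacing))
  phi <- 2 * pi * (seq_len(n) - 1) / n
  cbind(radius * cos(phi), radius * sin(phi), z)
}

.disk <- function(r_in, r_out, z, spacing = 2) {
  radii <- seq(r_in, r_out, by = spacing)
  do.call(rbind, lapply(radii, .ring, z = z, spacing = spacing))
}

#' Generate a toy closed "barrel" pseudo-C-alpha ensemble
#'
#' A cylinder of `n_strands` vertical strands of pseudo-C-alpha atoms on a
#' circle of radius `barrel_radius`, capped by atom disks at both ends.
#' `aperture_radius` > 0 opens a circular mouth of exactly that rim radius
#' in the top cap: a probe passes iff `aperture_radius` exceeds
#' (vdW + probe). The enclosed axial void makes the fixture a controllable
#' test bed for cavity detection. With `n_models` > 1, each model adds
#' independent Gaussian jitter of SD `jitter_sd` to every coordinate;
#' output is deterministic under `seed`.
#'
#' @param n_strands number of wall strands (>= 3; default 8, the lipocalin
#'   strand count).
#' @param residues_per_strand atoms per strand (default 10).
#' @param barrel_radius cylinder radius, Angstrom (default 6).
#' @param rise vertical spacing of atoms along a strand, Angstrom
#'   (default 3).
#' @param aperture_radius mouth radius in the top cap, Angstrom (0 =
#'   closed).
#' @param n_models ensemble size (default 1).
#' @param jitter_sd per-coordinate Gaussian jitter SD, Angstrom
#'   (default 0).
#' @param seed RNG seed (default 1).
#' @return a [structure_ensemble()] of carbon pseudo-atoms, one residue
#'   per atom.
#' @export
make_toy_barrel <- function(n_strands = 8, residues_per_strand = 10,
                            barrel_radius = 6, rise = 3,
                            aperture_radius = 0, n_models = 1,
                            jitter_sd = 0, seed = 1) {
  stopifnot(n_strands >= 3, residues_per_strand >= 2, barrel_radius > 0,
            rise > 0, aperture_radius >= 0, n_models >= 1)
  gap <- 2 * pi * barrel_radius / n_strands
  if (gap > 6 || rise > 6)
    stop("self-intersecting/open spec: strand or rise spacing too large ",
         "to close the wall")
  if (aperture_radius > 0 && aperture_radius >= barrel_radius)
    stop("aperture must be narrower than the barrel")
  z_top <- (residues_per_strand - 1) * rise
  wall <- do.call(rbind, lapply(seq_len(n_strands), function(s) {
    phi <- 2 * pi * (s - 1) / n_strands
    cbind(barrel_radius * cos(phi), barrel_radius * sin(phi),
          (seq_len(residues_per_strand) - 1) * rise)
  }))
  bottom <- .disk(0, barrel_radius - 2, z = 0)
  top <- if (aperture_radius == 0) .disk(0, barrel_radius - 2, z = z_top)
         else .disk(aperture_radius, barrel_radius - 1, z = z_top,
                    spacing = 1.5)
  xyz <- rbind(wall, bottom, top)
  n <- nrow(xyz)
  set.seed(seed)
  models <- lapply(seq_len(n_models), function(m) {
    x <- xyz
    if (jitter_sd > 0) x <- x + matrix(rnorm(3 * n, 0, jitter_sd), ncol = 3)
    structure_model(resno = seq_len(n), resname = rep("GLY", n),
                    atom = rep("CA", n), element = rep("C", n), xyz = x)
  })
  structure_ensemble(models, id = "toy_barrel")
}

#' Approximate analytic interior volume of a toy barrel
#'
#' Cylinder approximation: radius (barrel_radius - vdW - probe), height
#' (z_top - z_bottom - 2 (vdW + probe)). Coarse (the wall is an atom
#' lattice, not a smooth surface); use for sanity ranges, not tight
#' tolerances.
#'
#' @inheritParams make_toy_barrel
#' @param probe_radius probe radius, Angstrom.
#' @param vdw atom radius used in detection (default carbon, 1.7).
#' @return volume in Angstrom^3.
#' @export
barrel_cavity_volume <- function(n_strands = 8, residues_per_strand = 10,
                                 barrel_radius = 6, rise = 3,
                                 probe_radius = 1.4, vdw = 1.7) {
  r <- barrel_radius - vdw - probe_radius
  h <- (residues_per_strand - 1) * rise - 2 * (vdw + probe_radius)
  max(0, pi * r^2 * h)
}

#' Generate a hollow-sphere cavity oracle
#'
#' Atoms on a Fibonacci lattice over a sphere of radius `shell_radius`.
#' For a probe of radius p and a closed shell, the detected interior is
#' the ball of radius (shell_radius - atom_radius - p), so the volume is
#' known analytically ([sphere_cavity_volume()]). `n_atoms` must be large
#' enough that the lattice spacing (about sqrt(4 pi R^2 / n)) is below
#' 2 (atom_radius + p); 600 atoms close an 8 Angstrom shell comfortably.
#' `aperture_radius` > 0 cuts a polar hole and adds an exact rim ring at
#' that axis distance, so a probe passes iff aperture_radius >
#' (atom_radius + p).
#'
#' Atoms carry element "X": pass `vdw_radii = c(X = atom_radius)` to
#' [compute_cavity()].
#'
#' @param shell_radius sphere radius, Angstrom (default 8).
#' @param atom_radius radius to assign the shell atoms, Angstrom
#'   (default 1.5).
#' @param n_atoms lattice size (default 600).
#' @param aperture_radius polar mouth rim radius, Angstrom (0 = closed).
#' @return a single structure model, one residue per atom.
#' @export
make_hollow_sphere <- function(shell_radius = 8, atom_radius = 1.5,
                               n_atoms = 600, aperture_radius = 0) {
  stopifnot(shell_radius > 0, atom_radius > 0, n_atoms >= 10,
            aperture_radius >= 0)
  if (aperture_radius >= shell_radius)
    stop("aperture must be narrower than the shell")
  i <- seq_len(n_atoms) - 0.5
  theta <- acos(1 - 2 * i / n_atoms)
  golden <- pi * (1 + sqrt(5))
  phi <- golden * i
  xyz <- shell_radius * cbind(sin(theta) * cos(phi),
                              sin(theta) * sin(phi), cos(theta))
  if (aperture_radius > 0) {
    axis_d <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
    spacing <- sqrt(4 * pi * shell_radius^2 / n_atoms)
    keep <- !(xyz[, 3] > 0 & axis_d < aperture_radius + spacing)
    xyz <- xyz[keep, , drop = FALSE]
    z_rim <- sqrt(shell_radius^2 - aperture_radius^2)
    rim <- .ring(aperture_radius, z_rim, spacing = 0.8)
    xyz <- rbind(xyz, rim)
  }
  n <- nrow(xyz)
  structure_model(resno = seq_len(n), resname = rep("UNK", n),
                  atom = rep("X", n), element = rep("X", n), xyz = xyz)
}

#' Analytic interior volume of the hollow-sphere fixture
#'
#' @inheritParams make_hollow_sphere
#' @param probe_radius probe radius, Angstrom.
#' @return (4/3) pi (shell_radius - atom_radius - probe_radius)^3.
#' @export
sphere_cavity_volume <- function(shell_radius = 8, atom_radius = 1.5,
                                 probe_radius = 1.4) {
  r <- shell_radius - atom_radius - probe_radius
  if (r <= 0) return(0)
  4 / 3 * pi * r^3
}

#' Generate a synthetic HSQC titration series
#'
#' The reference list (level 0) draws per-residue NH positions uniformly
#' from typical amide ranges. At level L (with maximum level Lmax), each
#' peak sits at reference + (L/Lmax) * its endpoint displacement, with
#' optional Gaussian jitter of SD `noise_sd` on both shift axes, and is
#' absent from every level at or above its disappearance level.
#' Deterministic under `seed`.
#'
#' @param n_residues number of residues (numbered 1..n).
#' @param levels strictly increasing levels starting at 0.
#' @param csp_endpoints data.frame `residue`, `dh`, `dn`: endpoint shift
#'   displacements in ppm (residues not listed do not move).
#' @param disappearance data.frame `residue`, `level`: the level at and
#'   above which the peak vanishes (residues not listed never vanish).
#' @param noise_sd shift jitter SD in ppm applied at levels > 0
#'   (default 0).
#' @param axis_label series axis label.
#' @param seed RNG seed (default 1).
#' @return a [titration_series()].
#' @export
make_titration_series <- function(n_residues, levels,
                                  csp_endpoints = NULL,
                                  disappearance = NULL, noise_sd = 0,
                                  axis_label = "level", seed = 1) {
  stopifnot(n_residues >= 1, length(levels) >= 1, levels[1] == 0,
            all(diff(levels) > 0), noise_sd >= 0)
  set.seed(seed)
  res <- seq_len(n_residues)
  ref_h <- runif(n_residues, 7.5, 9.5)
  ref_n <- runif(n_residues, 105, 130)
  inten <- runif(n_residues, 50, 150)
  dh <- dn <- rep(0, n_residues)
  if (!is.null(csp_endpoints)) {
    i <- match(csp_endpoints$residue, res)
    if (any(is.na(i))) stop("csp_endpoints residue outside 1..n_residues")
    dh[i] <- csp_endpoints$dh
    dn[i] <- csp_endpoints$dn
  }
  vanish <- rep(Inf, n_residues)
  if (!is.null(disappearance)) {
    i <- match(disappearance$residue, res)
    if (any(is.na(i))) stop("disappearance residue outside 1..n_residues")
    vanish[i] <- disappearance$level
  }
  if (any(vanish <= 0)) stop("disappearance level must be above 0")
  lmax <- max(levels)
  pls <- lapply(levels, function(L) {
    frac <- if (lmax > 0) L / lmax else 0
    keep <- L < vanish
    h <- ref_h[keep] + frac * dh[keep]
    n <- ref_n[keep] + frac * dn[keep]
    if (L > 0 && noise_sd > 0) {
      h <- h + rnorm(sum(keep), 0, noise_sd)
      n <- n + rnorm(sum(keep), 0, noise_sd)
    }
    peak_list(data.frame(residue = res[keep], h_ppm = h, n_ppm = n,
                         intensity = inten[keep], flags = "",
                         stringsAsFactors = FALSE))
  })
  titration_series(levels, pls, axis_label = axis_label)
}
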