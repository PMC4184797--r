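# Rigid-body superposition, ensemble precision and distance measurements.

.paired_coords <- function(mobile, reference, resno = NULL,
                           atoms = "backbone") {
  im <- select_atoms(mobile, resno, atoms)
  ir <- select_atoms(reference, resno, atoms)
  km <- paste(mobile$resno[im], mobile$atom[im])
  kr <- paste(reference$resno[ir], reference$atom[ir])
  common <- intersect(km, kr)
  if (length(common) < 3) stop("need at least 3 paired atoms, got ",
                               length(common))
  list(P = coords(mobile)[im[match(common, km)], , drop = FALSE],
       Q = coords(reference)[ir[match(common, kr)], , drop = FALSE])
}

# closed-form least-squares rotation (Kabsch, via SVD) with proper-rotation
# enforcement; P, Q are n x 3 with rows paired
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  if (nrow(P) >= 3 && sv$d[2] < 1e-8 * max(sv$d[1], 1))
    warning("degenerate (collinear) selection: rotation poorly determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.vector(cq - R %*% cp))
}

#' Least-squares rigid-body superposition of two models
#'
#' Computes the proper rotation and translation minimising the RMSD between
#' paired atoms (matched by residue number and atom label within the
#' selection) and the RMSD after applying it.
#'
#' @param mobile,reference structure models.
#' @inheritParams select_atoms
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom) and `n_atoms`.
#' @export
superpose <- function(mobile, reference, resno = NULL, atoms = "backbone") {
  pq <- .paired_coords(mobile, reference, resno, atoms)
  tf <- .kabsch(pq$P, pq$Q)
  fitted <- sweep(pq$P %*% t(tf$R), 2, tf$t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - pq$Q)^2)))
  list(rotation = tf$R, translation = tf$t, rmsd = rmsd,
       n_atoms = nrow(pq$P))
}

#' Apply a rigid transform to a model
#'
#' @param model a structure model.
#' @param transform list with `rotation` and `translation` as returned by
#'   [superpose()].
#' @return the transformed model.
#' @export
apply_transform <- function(model, transform) {
  xyz <- sweep(coords(model) %*% t(transform$rotation), 2,
               transform$translation, "+")
  coords(model) <- xyz
  model
}

#' Per-model RMSD to the iteratively superposed ensemble mean
#'
#' All models are superposed onto the current per-atom coordinate mean, the
#' mean recomputed, and the cycle repeated until the mean moves by less than
#' `tol` (Angstrom). This is the standard NMR-ensemble precision statistic.
#'
#' @param ensemble a [structure_ensemble()] with at least two models.
#' @inheritParams select_atoms
#' @param tol convergence threshold on the mean-coordinate shift, Angstrom.
#' @param max_iter iteration cap.
#' @return list with `per_model` RMSDs (Angstrom), their `mean`, the final
#'   `mean_coords` matrix and `iterations` used.
#' @export
ensemble_rmsd_to_mean <- function(ensemble, resno = NULL, atoms = "backbone",
                                  tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (n_models(ensemble) < 2) stop("need at least 2 models")
  sel <- select_atoms(ensemble$models[[1]], resno, atoms)
  if (length(sel) == 0) stop("selection matches no atoms")
  X <- lapply(ensemble$models, function(m) coords(m)[sel, , drop = FALSE])
  mean_c <- X[[1]]
  for (it in seq_len(max_iter)) {
    X <- lapply(X, function(P) {
      tf <- .kabsch(P, mean_c)
      sweep(P %*% t(tf$R), 2, tf$t, "+")
    })
    new_mean <- Reduce(`+`, X) / length(X)
    shift <- max(abs(new_mean - mean_c))
    mean_c <- new_mean
    if (shift < tol) break
  }
  if (shift >= tol) stop("mean-structure iteration did not converge in ",
                         max_iter, " iterations")
  per <- vapply(X, function(P) sqrt(mean(rowSums((P - mean_c)^2))),
                numeric(1))
  list(per_model = per, mean = mean(per), mean_coords = mean_c,
       iterations = it)
}

.atom_xyz <- function(model, resno, atom) {
  i <- which(model$resno == resno & model$atom == atom)
  if (length(i) == 0) stop("atom not found: residue ", resno, " atom ", atom)
  coords(model)[i[1], ]
}

#' Distance between two named atoms
#'
#' @param model a structure model.
#' @param pair list or one-row data.frame with `residue_a`, `atom_a`,
#'   `residue_b`, `atom_b` (as in a loop-pair specification).
#' @return Euclidean distance in Angstrom.
#' @export
pair_distance <- function(model, pair) {
  a <- .atom_xyz(model, pair$residue_a, pair$atom_a)
  b <- .atom_xyz(model, pair$residue_b, pair$atom_b)
  sqrt(sum((a - b)^2))
}

#' Minimum distance between two atom groups
#'
#' Returns the smallest pairwise distance between two residue groups (by
#' default over non-hydrogen atoms) together with the achieving atom pair.
#' Ties break deterministically by the lexical order of the atom-name pair.
#'
#' @param model a structure model.
#' @param resno_a,resno_b residue numbers defining the two groups.
#' @param atoms atom class or label vector applied to both groups
#'   (default `"heavy"`).
#' @param exclude_self when the groups overlap, drop zero-distance
#'   self-pairs (default TRUE).
#' @return list with `distance` (Angstrom), `atom_a`, `atom_b` (each
#'   `list(resno, atom)`).
#' @export
min_group_distance <- function(model, resno_a, resno_b, atoms = "heavy",
                               exclude_self = TRUE) {
  ia <- select_atoms(model, resno_a, atoms)
  ib <- select_atoms(model, resno_b, atoms)
  if (length(ia) == 0 || length(ib) == 0) stop("empty atom group")
  A <- coords(model)[ia, , drop = FALSE]
  B <- coords(model)[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  if (exclude_self) {
    self <- outer(ia, ib, "==")
    d2[self] <- Inf
  }
  if (all(!is.finite(d2))) stop("no valid atom pair")
  dmin <- sqrt(min(d2))
  cand <- which(abs(sqrt(d2) - dmin) < 1e-12, arr.ind = TRUE)
  lab <- paste(model$atom[ia[cand[, 1]]], model$atom[ib[cand[, 2]]])
  pick <- cand[order(lab)[1], ]
  list(distance = dmin,
       atom_a = list(resno = model$resno[ia[pick[1]]],
                     atom = model$atom[ia[pick[1]]]),
       atom_b = list(resno = model$resno[ib[pick[2]]],
                     atom = model$atom[ib[pick[2]]]))
}

#' Inter-loop distance table for a model
#'
#' Evaluates [pair_distance()] for every row of a loop-pair specification
#' table, reported to two decimals.
#'
#' @param model a structure model.
#' @param pairs data.frame with columns `name`, `residue_a`, `atom_a`,
#'   `residue_b`, `atom_b` (see [read_loop_pairs()]).
#' @return data.frame with columns `name` and `distance`.
#' @export
loop_distance_report <- function(model, pairs) {
  d <- vapply(seq_len(nrow(pairs)),
              function(i) pair_distance(model, pairs[i, ]), numeric(1))
  data.frame(name = pairs$name, distance = round(d, 2),
             stringsAsFactors = FALSE)
}
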