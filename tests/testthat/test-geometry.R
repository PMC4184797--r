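test_that("superposition recovers rigid motions exactly", {
  set.seed(11)
  m <- toy_model(matrix(rnorm(30, sd = 4), 10, 3))
  expect_equal(superpose(m, m, atoms = "all")$rmsd, 0, tolerance = 1e-10)
  shifted <- m
  shifted$x <- shifted$x + 10
  expect_equal(superpose(shifted, m, atoms = "all")$rmsd, 0,
               tolerance = 1e-10)
  rotated <- rigid_move(m)
  fit <- superpose(rotated, m, atoms = "all")
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  back <- apply_transform(rotated, fit)
  expect_lt(max(abs(coords(back) - coords(m))), 1e-9)
})

test_that("superposition RMSD matches the brute-force rotation oracle", {
  # 4-atom set with one atom displaced by 1 A: non-zero optimum
  P <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  Q <- P
  Q[4, ] <- Q[4, ] + c(0, 0, 1)
  fit <- superpose(toy_model(P), toy_model(Q), atoms = "all")
  expect_gt(fit$rmsd, 0)
  expect_equal(fit$rmsd, oracle_superpose_rmsd(P, Q), tolerance = 1e-4)
  # and on an irregular 6-atom cloud
  set.seed(5)
  P2 <- matrix(rnorm(18, sd = 3), 6, 3)
  Q2 <- P2 + matrix(rnorm(18, sd = 0.4), 6, 3)
  fit2 <- superpose(toy_model(P2), toy_model(Q2), atoms = "all")
  expect_equal(fit2$rmsd, oracle_superpose_rmsd(P2, Q2), tolerance = 1e-4)
})

test_that("superposition rmsd is invariant under common rigid motion", {
  set.seed(21)
  a <- toy_model(matrix(rnorm(24, sd = 3), 8, 3))
  b <- toy_model(coords(a) + matrix(rnorm(24, sd = 0.5), 8, 3))
  base <- superpose(a, b, atoms = "all")$rmsd
  for (ang in c(0.3, 1.2, 2.9)) {
    moved <- superpose(rigid_move(a, ang), rigid_move(b, ang),
                       atoms = "all")$rmsd
    expect_equal(moved, base, tolerance = 1e-6)
  }
})

test_that("degenerate selections are flagged", {
  line <- toy_model(cbind(0:4, 0, 0))
  expect_warning(superpose(line, line, atoms = "all"), "degenerate")
  m <- toy_model(diag(3))
  expect_error(superpose(m[1:2, ], m[1:2, ], atoms = "all"), "3 paired")
})

test_that("ensemble RMSD to mean is zero for equivalent models", {
  m <- make_toy_barrel()$models[[1]]
  same <- structure_ensemble(list(m, m, m))
  expect_equal(ensemble_rmsd_to_mean(same, atoms = "all")$mean, 0,
               tolerance = 1e-9)
  moved <- structure_ensemble(list(m, rigid_move(m), rigid_move(m, 1.4)))
  expect_equal(ensemble_rmsd_to_mean(moved, atoms = "all")$mean, 0,
               tolerance = 1e-7)
})

test_that("ensemble RMSD statistics are consistent and non-negative", {
  ens <- make_toy_barrel(n_models = 6, jitter_sd = 0.4, seed = 3)
  r <- ensemble_rmsd_to_mean(ens, atoms = "all")
  expect_true(all(r$per_model >= 0))
  expect_equal(mean(r$per_model), r$mean)
  expect_gt(r$mean, 0.1)
})

test_that("pair distances are plain Euclidean distances", {
  m <- toy_model(rbind(c(0, 0, 0), c(3, 4, 0)), resno = c(1, 2))
  expect_equal(pair_distance(m, list(residue_a = 1, atom_a = "CA",
                                     residue_b = 2, atom_b = "CA")), 5)
  expect_equal(pair_distance(m, list(residue_a = 1, atom_a = "CA",
                                     residue_b = 1, atom_b = "CA")), 0)
  expect_error(pair_distance(m, list(residue_a = 9, atom_a = "CA",
                                     residue_b = 2, atom_b = "CA")),
               "residue 9")
})

test_that("minimum group distance agrees with exhaustive enumeration", {
  set.seed(8)
  xyz <- rbind(matrix(rnorm(9, sd = 2), 3, 3),
               matrix(rnorm(6, sd = 2) + 4, 2, 3))
  m <- structure_model(resno = c(1, 1, 1, 2, 2),
                       resname = rep("LEU", 5),
                       atom = c("CA", "CB", "CD1", "CA", "CD1"),
                       element = rep("C", 5), xyz = xyz)
  r <- min_group_distance(m, 1, 2)
  all_pairs <- expand.grid(i = 1:3, j = 4:5)
  d <- apply(all_pairs, 1, function(p)
    sqrt(sum((xyz[p[1], ] - xyz[p[2], ])^2)))
  expect_equal(r$distance, min(d))
  # single-atom groups reduce to pair_distance
  r1 <- min_group_distance(m, 1, 2, atoms = "CD1")
  expect_equal(r1$distance,
               pair_distance(m, list(residue_a = 1, atom_a = "CD1",
                                     residue_b = 2, atom_b = "CD1")))
  # group vs itself with self-pairs excluded: smallest intra-group distance
  rs <- min_group_distance(m, 1, 1)
  intra <- apply(expand.grid(i = 1:3, j = 1:3), 1, function(p)
    if (p[1] == p[2]) Inf else sqrt(sum((xyz[p[1], ] - xyz[p[2], ])^2)))
  expect_equal(rs$distance, min(intra))
  # min over groups never exceeds any specific pair within them
  expect_lte(r$distance, r1$distance)
})

test_that("loop distance report evaluates the shipped pair table", {
  pairs <- read_loop_pairs(extdata("loop_pairs.yaml"))
  expect_equal(nrow(pairs), 4)
  # place the 8 needed residues at known positions
  res <- sort(unique(c(pairs$residue_a, pairs$residue_b)))
  xyz <- cbind(seq_along(res) * 3, 0, 0)
  m <- toy_model(xyz, resno = res)
  rep <- loop_distance_report(m, pairs)
  for (i in seq_len(nrow(pairs))) {
    expected <- 3 * abs(match(pairs$residue_a[i], res) -
                        match(pairs$residue_b[i], res))
    expect_equal(rep$distance[i], expected)
  }
})
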