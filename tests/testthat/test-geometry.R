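test_that("kabsch_superpose recovers exact rigid transforms", {
  set.seed(11)
  ref <- matrix(rnorm(30 * 3, sd = 4), 30, 3)
  sp <- kabsch_superpose(ref, ref)
  expect_equal(sp$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)

  R <- rotation_z(90)
  mob <- sweep(ref %*% t(R), 2, c(1, 2, 3), `+`)
  sp <- kabsch_superpose(mob, ref)
  expect_lt(sp$rmsd, 1e-9)
  expect_lt(max(abs(apply_superposition(mob, sp) - ref)), 1e-8)
  # proper rotation always
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-9)

  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "3 atoms")
  expect_error(kabsch_superpose(ref, ref[1:10, ]), "shapes")
})

test_that("kabsch agrees with the quaternion-eigenvalue oracle", {
  set.seed(21)
  for (k in 1:10) {
    ref <- matrix(rnorm(100 * 3, sd = 5), 100, 3)
    mob <- ref %*% t(random_rotation()) +
      matrix(rnorm(300, sd = 0.5), 100, 3)
    expect_equal(kabsch_superpose(mob, ref)$rmsd,
                 quaternion_rmsd_oracle(mob, ref), tolerance = 1e-6)
  }
  # uniform weights equal the unweighted optimum
  w <- rep(2.5, 100)
  mob <- ref + matrix(rnorm(300, sd = 1), 100, 3)
  expect_equal(kabsch_superpose(mob, ref, weights = w)$rmsd,
               kabsch_superpose(mob, ref)$rmsd, tolerance = 1e-12)
})

test_that("degenerate collinear input still yields a proper rotation", {
  line <- cbind(seq_len(10), 0, 0)
  sp <- kabsch_superpose(line + 0.0, line %*% t(rotation_z(30)))
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_lt(sp$rmsd, 1e-9)
})

test_that("rmsd_all_to_all matches structure and a brute-force oracle", {
  h <- helix42()
  f <- get_frame(h, 1)
  same <- trajectory(h$topology, list(f, f, f))
  m <- rmsd_all_to_all(same)
  expect_true(all(m < 1e-10))

  set.seed(5)
  B <- f + matrix(rnorm(length(f), sd = 2), nrow(f), 3)
  mixed <- trajectory(h$topology,
                      list(f, sweep(f %*% t(rotation_z(45)), 2, 1:3, `+`), B))
  m <- rmsd_all_to_all(mixed)
  expect_lt(m[1, 2], 1e-9)
  expect_equal(m[1, 3], m[2, 3], tolerance = 1e-9)
  expect_equal(m, t(m), tolerance = 1e-10)
  expect_true(all(diag(m) == 0))

  frames <- lapply(1:10, function(i) f + matrix(rnorm(length(f)), nrow(f), 3))
  tr <- trajectory(h$topology, frames)
  sel <- select_atoms(tr, atom_names = "CA")
  m <- rmsd_all_to_all(tr, sel)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(m[i, j],
                 quaternion_rmsd_oracle(frames[[j]][sel, ], frames[[i]][sel, ]),
                 tolerance = 1e-8)
  }
})

test_that("radius of gyration matches closed forms and is rigid-invariant", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1.0)
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(radius_of_gyration(square), sqrt(0.5))
  # mass weighting shifts the centre toward the heavy atom
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)),
                                  masses = c(3, 1)),
               sqrt((3 * 0.5^2 + 1 * 1.5^2) / 4))
  h <- helix42()
  f <- get_frame(h, 1)
  set.seed(2)
  g <- sweep(f %*% t(random_rotation()), 2, rnorm(3, sd = 50), `+`)
  m <- h$topology$mass
  expect_equal(radius_of_gyration(f, m), radius_of_gyration(g, m),
               tolerance = 1e-10)
  expect_error(radius_of_gyration(f, rep(0, nrow(f))), "zero total mass")
})

test_that("pca_modes finds programmed motion and conserves variance", {
  h <- build_backbone("AAAAAA", dihedral_schedule("alpha", 6))
  base <- get_frame(h, 1)
  ca <- select_atoms(h, atom_names = "CA")
  # atom 1 of the selection translating along x only (no superposition
  # confound: motion applied to a far-away decoy topology instead)
  n <- nrow(base)
  frames <- lapply(0:9, function(k) { x <- base; x[ca[1], 1] <- x[ca[1], 1] + 0.3 * k; x })
  tr <- trajectory(h$topology, frames)
  # without superposition the programmed motion is exactly mode 1
  p0 <- pca_modes(tr, ca, superpose = FALSE)
  expect_equal(p0$variance_fraction[1], 1, tolerance = 1e-9)
  m1 <- matrix(p0$modes[, 1], ncol = 3)
  expect_equal(abs(m1[1, 1]), 1, tolerance = 1e-9)
  # with the default superposition the mode is still atom-1 dominated
  p <- pca_modes(tr, ca)
  expect_gt(p$variance_fraction[1], 0.95)
  m1s <- matrix(p$modes[, 1], ncol = 3)
  expect_equal(which.max(rowSums(m1s^2)), 1L)

  # full-mode reconstruction and variance conservation
  k <- length(p$variances)
  recon_err <- max(abs(p$projections %*% t(p$modes[, seq_len(k)]) -
                         scale(t(sapply(1:10, function(f)
                           as.numeric(apply_superposition(
                             frames[[f]][ca, ],
                             kabsch_superpose(frames[[f]][ca, ],
                                              frames[[1]][ca, ]))))),
                           scale = FALSE)))
  expect_lt(recon_err, 1e-6)
  p_all <- pca_modes(tr, ca, n_modes = 3 * length(ca))
  expect_equal(sum(p_all$variances), p_all$total_variance,
               tolerance = 1e-8 * p_all$total_variance)
  expect_error(pca_modes(tr, ca, n_modes = 3 * length(ca) + 1), "n_modes")
})

test_that("isotropic noise spreads variance across ~3n equal modes", {
  h <- build_backbone("AAAAAA", dihedral_schedule("alpha", 6))
  base <- get_frame(h, 1)
  ca <- select_atoms(h, atom_names = "CA")
  set.seed(33)
  frames <- lapply(1:600, function(f) {
    x <- base
    x[ca, ] <- x[ca, ] + matrix(rnorm(length(ca) * 3, sd = 0.2),
                                length(ca), 3)
    x
  })
  p <- pca_modes(trajectory(h$topology, frames), ca, n_modes = 1)
  expected <- 1 / (3 * length(ca))
  expect_gt(p$variance_fraction[1], 0.5 * expected)
  expect_lt(p$variance_fraction[1], 2.5 * expected)
})
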