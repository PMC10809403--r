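test_that("direct Coulomb energy matches closed-form pair sums", {
  zero <- charge_system(rbind(c(0, 0, 0), c(1, 1, 1)), charges = c(0, 0))
  expect_equal(direct_coulomb_energy(zero), 0)

  expect_equal(direct_coulomb_energy(dimer_system(0.5)), -277.870916,
               tolerance = 1e-9)

  # alternating unit charges on a unit square: 4 edges and 2 diagonals
  sq <- charge_system(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                      charges = c(1, -1, 1, -1))
  expect_equal(direct_coulomb_energy(sq), F_C * (-4 + 2 / sqrt(2)),
               tolerance = 1e-12)

  dup <- charge_system(rbind(c(0, 0, 0), c(0, 0, 0)), charges = c(1, 1))
  expect_error(direct_coulomb_energy(dup), "coincident")
  expect_error(direct_coulomb_energy(sq, integer(0)), "nonempty")
})

test_that("Ewald energy agrees with the brute-force lattice oracle", {
  zero <- charge_system(rbind(c(0.5, 0.5, 0.5), c(1, 1, 1)),
                        charges = c(0, 0), box_edge = 3)
  expect_equal(as.numeric(ewald_energy(zero, ewald_params(r_cut = 1.5))), 0)

  for (s in 1:5) {
    cl <- random_neutral_cloud(4, L = 3, min_sep = 0.3, seed = s)
    e <- as.numeric(ewald_energy(cl, ewald_params(r_cut = 1.5)))
    b <- brute_force_lattice_energy(cl, n_shells = 8)
    expect_lt(abs(e - b) / abs(b), 1e-4)
  }
})

test_that("the rock-salt cell reproduces the Madelung constant", {
  rs <- rocksalt_cell(a = 0.564)
  d_nn <- 0.564 / 2
  b <- brute_force_lattice_energy(rs, n_shells = 8)
  expect_equal(b / 4 / (F_C / d_nn), -1.747565, tolerance = 1e-4)
  e <- as.numeric(ewald_energy(rs, ewald_params(r_cut = d_nn,
                                                rel_tol = 1e-7)))
  expect_lt(abs(e - b) / abs(b), 1e-4)
})

test_that("raw brute-force shells converge monotonically in magnitude", {
  rs <- rocksalt_cell(a = 0.564)
  e8 <- brute_force_lattice_energy(rs, 8, extrapolate = FALSE)
  e12 <- brute_force_lattice_energy(rs, 12, extrapolate = FALSE)
  expect_lt(abs(e8 - e12) / abs(e12), 1e-5)

  # isolated-dipole limit: with a huge box the lattice sum approaches the
  # plain Coulomb energy of the pair
  big <- dimer_system(0.5, L = 50)
  expect_equal(brute_force_lattice_energy(big, 6),
               direct_coulomb_energy(big), tolerance = 1e-3)

  ion <- born_ion(1, 0.2, L = 3)
  expect_error(brute_force_lattice_energy(ion), "non-neutral")
})

test_that("Ewald energy is invariant under rigid translation", {
  cl <- random_neutral_cloud(4, L = 3, min_sep = 0.3, seed = 11)
  prm <- ewald_params(r_cut = 1.5)
  e0 <- as.numeric(ewald_energy(cl, prm))
  sh <- cl
  sh$positions <- sweep(cl$positions, 2, c(0.731, -1.22, 4.01), `+`)
  expect_equal(as.numeric(ewald_energy(sh, prm)), e0,
               tolerance = 1e-8)
})

test_that("Ewald energy is stable across the alpha working range", {
  # real-space truncation error ~ erfc(alpha * r_cut): over
  # alpha * r_cut in [2.8, 3.5] the energy should be parameter-independent
  # to a few parts in 1e4
  cl <- random_neutral_cloud(4, L = 3, min_sep = 0.3, seed = 4)
  es <- vapply(c(2.8, 3.0, 3.2, 3.5), function(a)
    as.numeric(ewald_energy(cl, ewald_params(alpha = a / 1.5, r_cut = 1.5,
                                             rel_tol = 1e-7))),
    numeric(1))
  expect_lt(diff(range(es)) / abs(mean(es)), 2e-4)
})

test_that("the energy is a homogeneous quadratic in the charges", {
  cl <- random_neutral_cloud(3, L = 3, min_sep = 0.35, seed = 9)
  prm <- ewald_params(r_cut = 1.5)
  e1 <- as.numeric(ewald_energy(cl, prm))
  cl$charges <- 2.5 * cl$charges
  expect_equal(as.numeric(ewald_energy(cl, prm)), 2.5^2 * e1,
               tolerance = 1e-12)
})

test_that("raising k_max beyond the auto choice changes nothing material", {
  cl <- random_neutral_cloud(4, L = 3, min_sep = 0.3, seed = 6)
  p1 <- ewald_params(r_cut = 1.5)
  e1 <- ewald_energy(cl, p1)
  p2 <- ewald_params(r_cut = 1.5, k_max = attr(e1, "k_max") + 3)
  expect_lt(abs(as.numeric(ewald_energy(cl, p2)) - as.numeric(e1)) /
              abs(as.numeric(e1)), p1$rel_tol)
})

test_that("parameter and usage errors are raised", {
  cl <- random_neutral_cloud(2, L = 3, seed = 2)
  expect_error(ewald_energy(cl, ewald_params(r_cut = 2)), "L/2")
  nop <- charge_system(matrix(0, 1, 3), 1)
  expect_error(ewald_energy(nop), "periodic")
})

test_that("the direct-interaction correction has its closed-form limits", {
  # identity perturbation: exactly zero
  cl <- random_neutral_cloud(3, L = 3, seed = 8)
  top <- identity_topology(cl$charges)
  r <- delta_g_dir(list(cl, cl), list(cl, cl), top)
  expect_identical(r$dG, 0)
  expect_equal(unname(r$n_snapshots), c(2L, 2L))

  # one-particle charging: the change in the Wigner self-interaction,
  # U_PBC = -xi * f * q^2 / (2 L), U_NPBC = 0
  L <- 3
  ion <- born_ion(1, 0.2, L = L)
  top1 <- perturbation_topology(0, 1, 0, 0, per_atom_A = 0, per_atom_B = 1)
  r1 <- delta_g_dir(list(ion), list(ion), top1)
  expect_equal(r1$dG, F_C * 2.837297 / (2 * L), tolerance = 1e-5)

  # image-interaction decay: a dipolar solute in a doubled box
  d1 <- dimer_system(0.4, L = 3)
  d1$charges <- c(0, 0)
  d2 <- d1; d2$box_edge <- 6
  topd <- perturbation_topology(0, 0, 0, 0, per_atom_A = c(0, 0),
                                per_atom_B = c(1, -1))
  rL <- delta_g_dir(list(d1), list(d1), topd)
  r2L <- delta_g_dir(list(d2), list(d2), topd)
  expect_lt(abs(r2L$dG), abs(rL$dG))
})

test_that("frame validation catches empty and inconsistent snapshot sets", {
  cl <- random_neutral_cloud(3, L = 3, seed = 8)
  top <- identity_topology(cl$charges)
  expect_error(delta_g_dir(list(), list(cl), top), "at least one")
  cl2 <- random_neutral_cloud(2, L = 3, seed = 8)
  expect_error(delta_g_dir(list(cl, cl2), list(cl), top), "mismatched")
})

test_that("the discrete-solvent term is a documented zero", {
  top <- build_coalchemical_perturbation(-1, c(0, -1), 1)
  z <- delta_g_dsm(top)
  expect_identical(z$dG, 0)
  expect_warning(delta_g_dsm(perturbation_topology(0, 1, 0, 0)),
                 "NOT zero")
})

test_that("correction results assemble with the documented sign convention", {
  pol <- structure(list(term = "pol", dG = -2, se = 0.1),
                   class = "finsize_correction")
  dir <- structure(list(term = "dir", dG = 0.5, se = 0.05),
                   class = "finsize_correction")
  res <- correction_result(pol, dir)
  expect_equal(res$total, -1.5)
  expect_equal(res$dG_dsm, 0)
  expect_equal(res$se, sqrt(0.1^2 + 0.05^2))
})
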