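test_that("the dielectric cavity discretization is geometrically sound", {
  spec <- grid_spec(spacing = 0.05)
  # no atoms: uniform solvent permittivity
  empty <- charge_system(matrix(1.5, 1, 3), charges = 0, radii = 0,
                         box_edge = 3)
  eps <- build_dielectric_grid(empty, spec, "periodic")
  expect_true(all(eps$epsx == spec$eps_out))
  expect_false(any(eps$node_inside))

  # single sphere: interior node count ~ sphere volume in cell units
  ion <- born_ion(1, 0.2, L = 2)
  eps1 <- build_dielectric_grid(ion, spec, "periodic")
  vol_cells <- 4 / 3 * pi * (0.2 / 0.05)^3
  expect_lt(abs(sum(eps1$node_inside) - vol_cells) / vol_cells, 0.15)
  # boundary-crossing edges carry intermediate (harmonically averaged) values
  expect_true(any(eps1$epsx > spec$eps_in & eps1$epsx < spec$eps_out))

  # two disjoint spheres have disjoint interiors
  two <- charge_system(rbind(c(0.5, 1, 1), c(1.5, 1, 1)), charges = c(0, 0),
                       radii = c(0.2, 0.2), box_edge = 2)
  eps2 <- build_dielectric_grid(two, spec, "periodic")
  ax <- 0.05 * (0:39)
  ins <- which(eps2$node_inside, arr.ind = TRUE)
  d1 <- sqrt((ax[ins[, 1]] - 0.5)^2 + (ax[ins[, 2]] - 1)^2 +
               (ax[ins[, 3]] - 1)^2)
  d2 <- sqrt((ax[ins[, 1]] - 1.5)^2 + (ax[ins[, 2]] - 1)^2 +
               (ax[ins[, 3]] - 1)^2)
  expect_true(all(d1 <= 0.2 + 1e-9 | d2 <= 0.2 + 1e-9))
  expect_false(any(d1 <= 0.2 & d2 <= 0.2))

  # a cavity reaching past a nonperiodic grid is refused
  fat <- charge_system(matrix(0, 1, 3), 1, radii = 0.5)
  tight <- grid_spec(spacing = 0.05, padding = 1)
  expect_error(build_dielectric_grid(fat, tight, "nonperiodic"),
               "grid too small")
})

test_that("charge spreading is an exact partition of unity", {
  spec <- grid_spec(spacing = 0.1)
  # exactly on a node: all charge on that node
  on_node <- charge_system(matrix(c(1, 1, 1), 1, 3), charges = 1,
                           box_edge = 2)
  rho <- spread_charges(on_node, spec, "periodic")
  expect_equal(max(rho), 1)
  expect_equal(sum(rho != 0), 1L)

  # at a cell centre: 1/8 per corner
  mid <- charge_system(matrix(c(1.05, 1.05, 1.05), 1, 3), charges = 1,
                       box_edge = 2)
  rho2 <- spread_charges(mid, spec, "periodic")
  expect_equal(sort(unique(as.vector(rho2))), c(0, 0.125))
  expect_equal(sum(rho2 != 0), 8L)

  # arbitrary configuration: grid sum equals the net charge
  cl <- random_neutral_cloud(5, L = 2, min_sep = 0.2, seed = 13)
  cl$charges <- cl$charges * c(0.3, 1.7)
  rho3 <- spread_charges(cl, spec, "periodic")
  expect_equal(sum(rho3), net_charge(cl), tolerance = 1e-12)

  out <- charge_system(matrix(c(9, 9, 9), 1, 3), charges = 1, radii = 0.1)
  expect_error({
    g <- finsize:::.grid_for(born_ion(1, 0.1), grid_spec(), "nonperiodic")
    spread_charges(out, grid = g)
  }, "outside")
})

test_that("zero source gives a zero (or boundary-harmonic) potential", {
  spec <- grid_spec(spacing = 0.1)
  sys <- born_ion(0, 0.2, L = 1.6)
  rho <- spread_charges(sys, spec, "periodic")
  ph <- solve_poisson_fd(rho, NULL, spec, "periodic", eps_uniform = 1)
  expect_equal(max(abs(ph$values)), 0)
  expect_equal(mean(ph$values), 0)
})

test_that("the nonperiodic solve reproduces the Coulomb closed form", {
  spec <- grid_spec(spacing = 0.05, padding = 8, sor_tol = 1e-7)
  ion <- born_ion(1, 0.1)
  grid <- finsize:::.grid_for(ion, spec, "nonperiodic")
  rho <- spread_charges(ion, spec, grid = grid)
  ph <- solve_poisson_fd(rho, NULL, spec, "coulomb-dirichlet", system = ion,
                         eps_uniform = 1)
  probe <- rbind(c(0.5, 0, 0), c(0, 0.5, 0), c(0.3, 0.3, 0.2))
  got <- finsize:::.interp_trilinear(ph$values, grid, probe)
  want <- F_C / sqrt(rowSums(probe^2))
  expect_lt(max(abs(got - want) / want), 0.02)
})

test_that("spectral and relaxation solvers invert the same operator", {
  spec <- grid_spec(spacing = 0.1, sor_tol = 1e-9)
  cl <- random_neutral_cloud(4, L = 3, min_sep = 0.3, seed = 2)
  rho <- spread_charges(cl, spec, "periodic")
  fd <- solve_poisson_fd(rho, NULL, spec, "periodic", eps_uniform = 66.6)
  ff <- solve_poisson_fft(rho, spec, eps_uniform = 66.6)
  expect_lt(max(abs(fd$values - ff$values)) / max(abs(ff$values)), 1e-6)
  expect_error(solve_poisson_fft(rho, spec, eps_uniform = c(1, 2)),
               "uniform")
})

test_that("periodic potentials are zero-mean (gauge fixed)", {
  spec <- grid_spec(spacing = 0.1)
  ion <- born_ion(1, 0.2, L = 1.6)  # net charge: background subtraction
  rho <- spread_charges(ion, spec, "periodic")
  ph <- solve_poisson_fft(rho, spec, eps_uniform = 1)
  expect_lt(abs(mean(ph$values)), 1e-10)
})

test_that("Born ion solvation converges to the analytic value", {
  ion <- born_ion(1, 0.2)
  born <- born_energy(1, 0.2, 66.6)
  errs <- vapply(c(0.1, 0.05, 0.025), function(h)
    abs(as.numeric(solvation_free_energy(ion, grid_spec(spacing = h))) -
          born), numeric(1))
  expect_lt(errs[2] / abs(born), 0.03)   # 3% at 0.05 nm spacing
  expect_true(all(diff(errs) < 0))       # refinement improves monotonically
})

test_that("solvation response is quadratic in the charge", {
  spec <- grid_spec(spacing = 0.1)
  g1 <- as.numeric(solvation_free_energy(born_ion(1, 0.2), spec))
  g2 <- as.numeric(solvation_free_energy(born_ion(2, 0.2), spec))
  expect_equal(g2, 4 * g1, tolerance = 1e-9)
  expect_equal(as.numeric(solvation_free_energy(born_ion(0, 0.2), spec)), 0)
})

test_that("the grid reproduces the Wigner self-interaction scaling", {
  # the grid self-energy of a charge on a node is h-dependent but box-size
  # independent; the difference between two box sizes at equal spacing is the
  # Wigner term difference -f*xi/2 * (1/L1 - 1/L2)
  spec <- grid_spec(spacing = 0.05)
  self_e <- function(L) {
    ion <- born_ion(1, 0.1, L = L)
    grid <- finsize:::.make_grid(c(0, 0, 0), spec$spacing,
                                 rep(round(L / spec$spacing), 3), TRUE)
    rho <- spread_charges(ion, spec, grid = grid)
    ph <- solve_poisson_fft(rho, spec, eps_uniform = 1)
    0.5 * finsize:::.interp_trilinear(ph$values, grid, ion$positions)
  }
  got <- self_e(1.2) - self_e(2.4)
  want <- -F_C * 2.837297 / 2 * (1 / 1.2 - 1 / 2.4)
  expect_equal(got, want, tolerance = 0.02)
})

test_that("periodic heterogeneous solve agrees with the lattice sum", {
  # neutral dipole, uniform permittivity 1: grid interaction energy
  # (total minus per-charge self solves) vs the Ewald interaction energy
  L <- 3
  spec <- grid_spec(spacing = 0.05, sor_tol = 1e-8)
  pos <- rbind(c(1.0, 1.5, 1.5), c(1.6, 1.5, 1.5))
  pair <- charge_system(pos, charges = c(1, -1), box_edge = L)
  grid <- finsize:::.grid_for(pair, spec, "periodic")
  inter <- function(sys) {
    rho <- spread_charges(sys, spec, grid = grid)
    ph <- solve_poisson_fft(rho, spec, eps_uniform = 1)
    sum(0.5 * sys$charges *
          finsize:::.interp_trilinear(ph$values, grid, sys$positions))
  }
  one <- function(i) {
    s <- pair; s$charges[-i] <- 0
    inter(s)
  }
  grid_int <- inter(pair) - one(1) - one(2)
  prm <- ewald_params(r_cut = L / 2)
  ew_int <- as.numeric(ewald_energy(pair, prm)) -
    sum(vapply(1:2, function(i) {
      s <- pair; s$charges[-i] <- 0
      as.numeric(ewald_energy(s, prm))
    }, numeric(1)))
  expect_equal(grid_int, ew_int, tolerance = 0.03)
})

test_that("polarization correction vanishes for identity perturbations", {
  spec <- grid_spec(spacing = 0.1)
  cl <- random_neutral_cloud(2, L = 2, min_sep = 0.4, seed = 3)
  cl$radii <- rep(0.2, 4)
  top <- identity_topology(cl$charges)
  r <- delta_g_pol(list(cl), list(cl), top, spec)
  expect_identical(r$dG, 0)
  expect_equal(attr(r, "eps_out"), 66.6)
})

test_that("polarization correction shows leading 1/L image scaling", {
  ratio_pair <- function(L) {
    spec <- grid_spec(spacing = L / 32, sor_tol = 1e-6)
    sys <- born_ion(1, 0.4, L = L)
    top <- perturbation_topology(0, 1, 0, 0, per_atom_A = 0, per_atom_B = 1)
    delta_g_pol(list(sys), list(sys), top, spec)$dG
  }
  dg3 <- ratio_pair(3)
  dg6 <- ratio_pair(6)
  expect_lt(abs(dg6), abs(dg3))
  expect_gt(dg3 / dg6, 2 - 0.3)
  expect_lt(dg3 / dg6, 2 + 0.3)
})
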