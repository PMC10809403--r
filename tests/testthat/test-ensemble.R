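test_that("minimum-image self distance has its closed-form values", {
  one <- charge_system(matrix(c(1, 2, 0.3), 1, 3), charges = 0, box_edge = 3)
  expect_equal(min_image_self_distance(one), 1.5)

  two <- charge_system(rbind(c(0, 0, 0), c(1.3, 0, 0)), charges = c(0, 0),
                       box_edge = 2.5)
  expect_equal(min_image_self_distance(two), (2.5 - 1.3) / 2)

  # translation invariance
  sh <- two
  sh$positions <- sweep(two$positions, 2, c(5.2, -0.7, 0.33), `+`)
  expect_equal(min_image_self_distance(sh), min_image_self_distance(two),
               tolerance = 1e-12)

  # a point particle gives exactly L/2; self-overlap warns and returns 0
  over <- charge_system(rbind(c(0, 0, 0), c(2.5, 0, 0)), charges = c(0, 0),
                        box_edge = 2.5)
  expect_warning(v <- min_image_self_distance(over), "self-overlap")
  expect_equal(v, 0)
})

test_that("wall-distance summaries aggregate replicas and frames", {
  frame <- charge_system(rbind(c(0, 0, 0), c(1.3, 0, 0)), charges = c(0, 0),
                         box_edge = 2.5)
  const <- list(list(frame, frame), list(frame))
  s <- wall_distance_summary(const)
  expect_equal(unname(s), rep(0.6, 3))

  # a shrinking-distance replica: init from frame 1, min from the last
  stretch <- frame
  stretch$positions[2, 1] <- 1.7
  s2 <- wall_distance_summary(list(list(frame, stretch)))
  expect_equal(s2[["init"]], 0.6)
  expect_equal(s2[["min"]], 0.4)
  expect_equal(s2[["avg"]], 0.5)
  s3 <- wall_distance_summary(list(list(frame, stretch)),
                              avg_mode = "replica_min")
  expect_equal(s3[["avg"]], 0.4)
  expect_error(wall_distance_summary(list()), "at least one")
})

test_that("end-to-end distances follow the anchor atoms", {
  m <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(end_to_end(m, 1, 2), 0)
  expect_equal(end_to_end(m, 1, 3), 1)
  expect_equal(end_to_end_vector(m, 3, 1), c(-1, 0, 0))
  expect_error(end_to_end(m, 1, 9), "out of range")

  hx <- ideal_helix_octapeptide()
  d <- end_to_end(hx, attr(hx, "n_index"), attr(hx, "c_index"))
  expect_gt(d, 1.1)
  expect_lt(d, 1.5)
})

test_that("profiles recover a two-state generator's basin gap", {
  kT <- K_B * 300
  d <- two_state_distance_sampler(p_A = 0.2, n_frames = 4000, n_replicas = 8,
                                  seed = 42)
  prof <- free_energy_profile(d, bins = 50)
  expect_equal(min(prof$dG, na.rm = TRUE), 0)
  expect_equal(length(prof$bin_centers), 50)
  # the well depths differ by -kT log(p_B / p_A)
  iA <- which.min(abs(prof$bin_centers - 0.65))
  iB <- which.min(abs(prof$bin_centers - 2.2))
  gap <- prof$dG[iB] - prof$dG[iA]
  expect_equal(gap, -kT * log(0.8 / 0.2), tolerance = 0.15)

  bas <- basin_delta_g(d)
  expect_equal(bas$dG_AB, -kT * log(0.2 / 0.8), tolerance = 0.1)
  expect_lt(abs(bas$dG_AB - 3.457), 2 * bas$ci95 + 0.2)
})

test_that("uniform samples give a flat profile", {
  set.seed(7)
  reps <- lapply(1:6, function(i) runif(5000, 0, 1))
  prof <- free_energy_profile(reps, bins = 20, range = c(0, 1))
  spread <- max(prof$dG, na.rm = TRUE) - min(prof$dG, na.rm = TRUE)
  expect_lt(spread, 0.25)  # kJ/mol, pure counting noise at n = 5000
  expect_true(all(prof$ci95 >= 0, na.rm = TRUE))
})

test_that("confidence intervals shrink like 1/sqrt(n)", {
  ci_at <- function(n) {
    d <- two_state_distance_sampler(p_A = 0.3, n_frames = n,
                                    n_replicas = 30, seed = 99)
    basin_delta_g(d)$ci95
  }
  r <- ci_at(500) / ci_at(2000)  # quadrupled samples: expect ~2
  expect_gt(r, 1.5)
  expect_lt(r, 2.7)
})

test_that("basin comparisons are antisymmetric and handle degenerate input", {
  d <- two_state_distance_sampler(p_A = 0.5, n_frames = 2000,
                                  n_replicas = 6, seed = 3)
  ab <- basin_delta_g(d)
  ba <- basin_delta_g(d, range_A = c(1.8, 2.6), range_B = c(0.4, 0.9))
  expect_equal(ab$dG_AB, -ba$dG_AB, tolerance = 1e-12)
  expect_lt(abs(ab$dG_AB), ab$ci95 + 0.1)  # symmetric generator: ~0

  # equal counts give exactly zero
  even <- list(c(0.5, 0.5, 2.0, 2.0))
  expect_equal(basin_delta_g(even)$dG_AB, 0)

  # a replica with an empty window is excluded with a warning
  d2 <- list(c(0.5, 2.0, 2.1), c(2.0, 2.2))
  expect_warning(b2 <- basin_delta_g(d2), "excluded")
  expect_equal(length(b2$per_replica), 1L)
  expect_error(basin_delta_g(list(c(1.5))), "nonzero counts")
  expect_error(basin_delta_g(d, range_A = c(0.4, 2.0)), "disjoint")
})

test_that("orientation maps bin on equal areas and score face alignment", {
  # all vectors +z: one occupied bin in the top band
  vz <- matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE)
  m <- orientation_map(vz)
  expect_equal(sum(m$counts > 0), 1L)
  expect_equal(sum(m$counts[m$n_bands, ]), 10)
  expect_equal(m$face_alignment, 1)

  # isotropic ensemble: equal-area bins are statistically uniform
  v <- orientation_sampler("isotropic", n = 20000, seed = 21)
  mi <- orientation_map(v, n_bands = 8, n_sectors = 12)
  p <- suppressWarnings(stats::chisq.test(as.vector(mi$counts))$p.value)
  expect_gt(p, 1e-3)
  expect_lt(abs(mi$face_alignment - mi$isotropic_expectation), 0.02)

  # six-face mixture is detected by the alignment score
  vf <- orientation_sampler("six-face", concentration = 30, n = 5000,
                            seed = 22)
  mf <- orientation_map(vf)
  expect_gt(mf$face_alignment, 2 * mf$isotropic_expectation)

  expect_warning(orientation_map(rbind(c(0, 0, 0), c(0, 0, 1))), "skipped")
})

test_that("box series flag significant deviations from the largest box", {
  # identical values: all differences zero, nothing significant
  d0 <- expand.grid(box_edge = c(3, 6, 9), replica = 1:5)
  d0$value <- 1.7
  r0 <- box_series(d0)
  expect_equal(r0$diff_to_largest, rep(0, 3))
  expect_false(any(r0$significant))
  expect_equal(r0$diff_to_largest[r0$box_edge == 9], 0)

  # an injected offset far above the noise in the smallest box
  set.seed(5)
  d1 <- expand.grid(box_edge = c(3, 6, 9), replica = 1:5)
  d1$value <- rnorm(nrow(d1), 0, 0.05) + ifelse(d1$box_edge == 3, 2, 0)
  r1 <- box_series(d1)
  expect_true(r1$significant[r1$box_edge == 3])
  expect_false(r1$significant[r1$box_edge == 9])
  expect_equal(r1$diff_to_largest[r1$box_edge == 3], 2, tolerance = 0.2)

  expect_warning(box_series(data.frame(box_edge = c(3, 6), replica = 1,
                                       value = c(1, 2))), "single-replica")
})

test_that("replica CIs reproduce the textbook normal-approximation formula", {
  vals <- c(10.2, 9.8, 10.5, 10.1, 9.9)
  d <- data.frame(box_edge = rep(c(3, 9), each = 5), replica = rep(1:5, 2),
                  value = c(vals, rep(10, 5)))
  r <- box_series(d)
  se3 <- sd(vals) / sqrt(5)
  se9 <- sd(rep(10, 5)) / sqrt(5)
  expect_equal(r$ci95[r$box_edge == 3], 1.96 * sqrt(se3^2 + se9^2),
               tolerance = 1e-12)
})

test_that("equilibration discard removes the leading fraction per replica", {
  d <- data.frame(replica = rep(1:2, each = 10), frame = rep(1:10, 2),
                  value_nm = rep(1:10, 2))
  out <- discard_equilibration(d, 0.2)
  expect_equal(nrow(out), 16)
  expect_true(all(out$frame >= 3))
})
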