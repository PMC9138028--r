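test_that("frozen-lattice sum matches a closed-form single-chain oracle", {
  lj <- lj_params()
  a <- 2^(1 / 6) * lj$sigma
  c_ax <- 14
  zk <- (-10:10) * c_ax + c_ax / 2     # neighbour planes straddle z = 0
  lat <- bead_lattice(
    xyz = rbind(c(0, 0, 0), cbind(a, 0, zk)),
    chain = c(0L, rep(1L, length(zk))),
    spacing = a, axial_spacing = c_ax,
    sliding = 1, z_low = 0, z_high = c_ax / 2
  )
  cutoff <- 6 * lj$sigma
  direct <- function(z) {
    d <- sqrt(a^2 + (zk - z)^2)
    sum(lj_energy(d[d <= cutoff], lj))
  }
  expect_equal(fixed_lattice_barrier(lat, lj, cutoff),
               direct(c_ax / 2) - direct(0), tolerance = 1e-12)
})

test_that("lattice-sum barrier is converged in cutoff and invariant to symmetry ops", {
  lj <- lj_params()
  lat <- build_hex_lattice(n_rings = 12, n_axial = 28)
  b6 <- fixed_lattice_barrier(lat, lj, cutoff = 6 * lj$sigma)
  b12 <- fixed_lattice_barrier(lat, lj, cutoff = 12 * lj$sigma)
  expect_lt(abs(b12 / b6 - 1), 0.005)
  expect_error(fixed_lattice_barrier(lat, lj, cutoff = 20),
               "coordination shell")

  # translation by one axial period and 60-degree rotation about the
  # central chain leave the barrier unchanged
  base <- build_hex_lattice(n_rings = 6, n_axial = 20)
  cutoff <- 4 * lj$sigma
  b0 <- fixed_lattice_barrier(base, lj, cutoff)
  shifted <- bead_lattice(t(t(base$xyz) + c(0, 0, base$axial_spacing)),
                          base$chain, base$spacing, base$axial_spacing,
                          base$sliding,
                          base$z_low + base$axial_spacing,
                          base$z_high + base$axial_spacing)
  expect_equal(fixed_lattice_barrier(shifted, lj, cutoff), b0,
               tolerance = 1e-9)
  th <- pi / 3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rotated <- bead_lattice(base$xyz %*% R, base$chain, base$spacing,
                          base$axial_spacing, base$sliding,
                          base$z_low, base$z_high)
  expect_equal(fixed_lattice_barrier(rotated, lj, cutoff), b0,
               tolerance = 1e-9)
})

test_that("barrier profile is periodic and starts at zero", {
  lat <- build_hex_lattice(n_rings = 4, n_axial = 16)
  prof <- barrier_profile(lat, n = 21)
  expect_identical(prof$energy_kcal_mol[1], 0)
  expect_equal(prof$energy_kcal_mol[21], 0, tolerance = 1e-6)
  expect_rel(max(prof$energy_kcal_mol),
             fixed_lattice_barrier(lat), 1e-9)
})

test_that("barrier-to-pullout reproduces the published conversion chain", {
  b1 <- barrier_to_pullout(6.29)
  expect_identical(b1$regime, "harmonic")
  expect_rel(b1$delta_r, 0.86, 0.01)
  expect_rel(b1$F_pull_N, 1.02e-9, 0.01)
  b2 <- barrier_to_pullout(11.36)
  expect_rel(b2$delta_r, 1.15, 0.01)
  expect_rel(b2$F_pull_N, 1.37e-9, 0.01)
  b3 <- barrier_to_pullout(187)
  expect_identical(b3$regime, "hyperelastic")
  expect_rel(b3$delta_r, 4.59, 0.01)
  expect_rel(b3$r_sliding, 18.59, 0.01)
  expect_gt(b3$r_sliding, molecule_params()$r1)
  expect_rel(b3$F_pull_N, 7.67e-9, 0.01)
})

test_that("pull-out conversion is monotone in the barrier and continuous at the regime switch", {
  p <- molecule_params()
  de <- seq(0.5, 300, length.out = 120)
  res <- lapply(de, barrier_to_pullout, params = p)
  dr <- vapply(res, `[[`, numeric(1), "delta_r")
  fp <- vapply(res, `[[`, numeric(1), "F_pull_N")
  expect_true(all(diff(dr) > 0))
  expect_true(all(diff(fp) > 0))
  # at delta_E = KT0/2 (r1-r0)^2 both formulas give the same elongation
  e_sw <- p$KT0 / 2 * (p$r1 - p$r0)^2
  h <- barrier_to_pullout(e_sw, p, regime = "harmonic")
  y <- barrier_to_pullout(e_sw, p, regime = "hyperelastic")
  expect_rel(h$delta_r, y$delta_r, 1e-9)
  expect_rel(h$F_pull_N, y$F_pull_N, 1e-9)
  # forcing the hyperelastic branch below C1 is rejected
  expect_error(barrier_to_pullout(1, p, regime = "hyperelastic"), "C1")
  expect_error(barrier_to_pullout(-2), "delta_E")
})

test_that("relaxed barrier: frozen reduction is exact and relaxation lowers energy pointwise", {
  lj <- lj_params()
  lat <- build_hex_lattice(n_rings = 3, n_axial = 6)
  cutoff <- 3 * lj$sigma
  frozen <- relaxed_barrier(lat, lj, n_path = 5, cutoff = cutoff,
                            max_iter = 0)
  expect_equal(frozen$delta_E, fixed_lattice_barrier(lat, lj, cutoff),
               tolerance = 1e-9)
  expect_equal(frozen$profile$E_relaxed, frozen$profile$E_frozen,
               tolerance = 1e-12)

  rb <- relaxed_barrier(lat, lj, n_path = 5, cutoff = cutoff)
  expect_gte(rb$delta_E, 0)
  expect_true(all(rb$profile$E_relaxed <= rb$profile$E_frozen + 1e-9))
  expect_true(all(diff(rb$profile$E_relaxed) > 0))  # rest is the minimum
  # non-convergence surfaces the last gradient norm
  expect_error(relaxed_barrier(lat, lj, n_path = 2, cutoff = cutoff,
                               tol = 1e-10, max_iter = 2),
               "gradient norm")
})

test_that("an attached divalent crosslink multiplies the sliding barrier", {
  lj <- lj_params()
  lat <- build_hex_lattice(n_rings = 3, n_axial = 6)
  plain <- relaxed_barrier(lat, lj, n_path = 4, cutoff = 3 * lj$sigma)
  linked <- relaxed_barrier(lat, lj, crosslink = crosslink_params("divalent"),
                            n_path = 4, cutoff = 3 * lj$sigma)
  expect_gt(linked$delta_E, 10 * plain$delta_E)
})
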