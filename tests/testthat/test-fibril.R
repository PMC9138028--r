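test_that("uncrosslinked fibril: yield equals ultimate on a perfectly plastic plateau", {
  uf <- uncrosslinked_curve(25)
  s <- fibril_summary(uf)
  expect_rel(s$UTS_Pa, 445e6, 0.015)
  expect_rel(s$yield_strain, 0.0970, 0.01)
  expect_rel(s$E2_Pa, 5.24e9, 0.015)
  # plateau: stress constant beyond the sliding onset
  expect_equal(evaluate_curve(uf, 0.15), evaluate_curve(uf, 0.50),
               tolerance = 1e-12)
  # its unfolding stage is numerically the molecule's
  sm <- curve_segments(molecule_curve())
  su <- curve_segments(uf)
  expect_equal(su[1, -1], sm[1, -1], tolerance = 1e-12, ignore_attr = TRUE)
  # a hyperelastic-regime barrier is rejected for sliding without crosslinks
  expect_error(uncrosslinked_curve(25, barrier_uf = barrier_to_pullout(187)),
               "harmonic")
})

test_that("crosslinked fibril: two stretching stages, then a drop to the plain plateau", {
  cf <- crosslinked_curve(25)
  uf <- uncrosslinked_curve(25)
  s <- fibril_summary(cf)
  expect_rel(s$UTS_Pa, 3.24e9, 0.015)
  expect_rel(s$yield_strain, 0.346, 0.015)
  expect_rel(s$E2_Pa, 6.96e9, 0.015)
  expect_rel(s$E3_Pa, 39.65e9, 0.015)
  seg <- curve_segments(cf)
  expect_rel(seg$sigma_start[3], 2.115e9, 0.015)
  # the post-drop plateau equals the uncrosslinked plateau of the same phi
  expect_equal(evaluate_curve(cf, 0.40),
               fibril_summary(uf)$UTS_Pa, tolerance = 1e-12)
  # exactly one drop, at the crosslink rupture strain
  expect_identical(length(cf$drops), 1L)
  expect_rel(cf$drops, 0.346, 0.015)
  # a harmonic-regime crosslink barrier contradicts the sliding bond length
  expect_error(crosslinked_curve(25, barrier_cf = barrier_to_pullout(100)),
               "hyperelastic")
  expect_error(crosslinked_curve(25, barrier_cf = barrier_to_pullout(187),
                                 barrier_uf = barrier_to_pullout(190)),
               "exceed")
})

test_that("partial crosslinking is the beta^2 pointwise mixture of the pure laws", {
  phi <- 25
  uf <- uncrosslinked_curve(phi)
  cf <- crosslinked_curve(phi)
  expect_equal(partial_curve(phi, 0)$segments, uf$segments, tolerance = 1e-12)
  expect_equal(partial_curve(phi, 1)$segments, cf$segments, tolerance = 1e-12)
  eps <- strain_grid()
  for (beta in c(0.25, 0.5, 0.8)) {
    pc <- partial_curve(phi, beta)
    blend <- beta^2 * evaluate_curve(cf, eps) +
      (1 - beta^2) * evaluate_curve(uf, eps)
    expect_equal(evaluate_curve(pc, eps), blend, tolerance = 1e-9)
  }
  expect_error(partial_curve(phi, -0.1), "beta")
  expect_error(partial_curve(phi, 1.1), "beta")
})

test_that("stress is pointwise non-decreasing in the crosslink density", {
  eps <- strain_grid()
  betas <- seq(0, 1, by = 0.1)
  stress <- sapply(betas, function(b)
    evaluate_curve(partial_curve(100, b), eps))
  expect_true(all(apply(stress, 1, function(x) all(diff(x) >= -1e-6))))
})

test_that("UTS grows quadratically with crosslink density and saturates diameter effects", {
  betas <- seq(0, 1, by = 0.1)
  sw <- sweep_beta(betas, phi = 25)
  gain <- sw$UTS_Pa - sw$UTS_Pa[1]
  fit <- lm(gain ~ I(betas^2))
  expect_gt(suppressWarnings(summary(fit))$r.squared, 0.9999)
  # beta = 0: UTS increases with diameter (surface fraction shrinks)
  swd <- sweep_diameter(c(20, 50, 100, 300, 500), beta = 0)
  expect_true(all(diff(swd$UTS_Pa) > 0))
  # beta = 1: UTS independent of diameter (all molecules anchored)
  swc <- sweep_diameter(c(20, 50, 100, 300, 500), beta = 1)
  expect_lt(diff(range(swc$UTS_Pa)) / mean(swc$UTS_Pa), 1e-12)
})

test_that("strain endpoints are independent of diameter, density and cross-section", {
  e1 <- curve_segments(partial_curve(25, 0.5))$eps_start
  e2 <- curve_segments(partial_curve(400, 0.5))$eps_start
  expect_equal(e1, e2, tolerance = 1e-12)
  p_big <- molecule_params(D_mol = 16.52 * sqrt(2))
  e3 <- curve_segments(partial_curve(25, 0.5, params = p_big,
    barrier_uf = barrier_to_pullout(11.36, p_big),
    barrier_cf = barrier_to_pullout(187, p_big)))$eps_start
  expect_equal(e3, e1, tolerance = 1e-12)
})

test_that("gap/overlap bookkeeping does not change the stress", {
  g1 <- fibril_geometry(100, gap_ratio = 0.54)
  g2 <- fibril_geometry(100, gap_ratio = 0.60)
  for (b in c(0, 0.5, 1))
    expect_equal(partial_curve(g1, b)$segments, partial_curve(g2, b)$segments,
                 tolerance = 1e-12)
})

test_that("summaries label provenance and match the curve maxima", {
  s <- fibril_summary(partial_curve(80, 0.3))
  expect_identical(s$phi, 80)
  expect_identical(s$beta, 0.3)
  crv <- partial_curve(80, 0.3)
  eps <- strain_grid(0.4, 2001)
  expect_gte(s$UTS_Pa + 1e-6, max(evaluate_curve(crv, eps)))
})
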