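test_that("hexagonal packing fraction matches closed form and Monte-Carlo", {
  expect_equal(c_pack(), pi / (2 * sqrt(3)), tolerance = 1e-15)
  expect_rel(100 * c_pack(), 90.7, 0.01)
  # hit-or-miss oracle on the hexagonal unit cell: circles of radius 1/2
  # on lattice points a1 = (1,0), a2 = (1/2, sqrt(3)/2)
  set.seed(42)
  n <- 1e6
  u <- runif(n); v <- runif(n)
  px <- u + v / 2
  py <- v * sqrt(3) / 2
  inside <- rep(FALSE, n)
  for (i in 0:1) for (j in 0:1) {
    cx <- i + j / 2; cy <- j * sqrt(3) / 2
    inside <- inside | ((px - cx)^2 + (py - cy)^2 < 0.25)
  }
  expect_lt(abs(mean(inside) - c_pack()), 0.002)
})

test_that("surface coefficient behaves as the bulk-molecule fraction", {
  expect_rel(c_surf(20), 0.70, 0.01)
  expect_rel(c_surf(500), 0.99, 0.01)
  expect_lt(abs(c_surf(1e6) - 1), 1e-5)
  phi <- seq(10, 500, by = 5)
  expect_true(all(diff(c_surf(phi)) > 0))
  expect_error(c_surf(3), "2\\*D_mol")
  expect_error(c_surf(3.304), "2\\*D_mol")
})

test_that("fibril geometry stores coefficients and validates its inputs", {
  g <- fibril_geometry(100)
  expect_equal(g$c_pack, c_pack())
  expect_equal(g$c_surf, c_surf(100))
  expect_equal(g$D_period, 67)
  expect_true(g$gap_ratio > 0.54 - 1e-9 && g$gap_ratio < 0.60 + 1e-9)
  expect_error(fibril_geometry(100, gap_ratio = 1.2), "gap_ratio")
  expect_error(fibril_geometry(2), "2\\*D_mol")
})

test_that("hex lattice geometry: spacings, central sliding bead, chain count", {
  lat <- build_hex_lattice(n_rings = 1, n_axial = 4)
  expect_identical(length(unique(lat$chain)), 7L)   # slider + 6 neighbours
  expect_equal(lat$spacing, 2^(1 / 6) * 14.72, tolerance = 1e-12)
  expect_equal(lat$axial_spacing, 14)
  # in-plane nearest-neighbour distance equals the lattice spacing
  ctr <- unique(lat$xyz[lat$chain != 0, 1:2])
  d <- as.matrix(dist(ctr))
  expect_equal(min(d[d > 0]), lat$spacing, tolerance = 1e-9)
  # slider rests midway between the two central axial planes
  z <- sort(unique(lat$xyz[lat$chain != 0, 3]))
  below <- max(z[z < lat$z_low]); above <- min(z[z > lat$z_low])
  expect_equal(lat$z_low - below, above - lat$z_low, tolerance = 1e-9)
  expect_equal(lat$z_high - lat$z_low, lat$axial_spacing / 2, tolerance = 1e-12)
  expect_error(build_hex_lattice(n_rings = 0), "n_rings")
  expect_error(build_hex_lattice(n_axial = 2), "n_axial")
})

test_that("coordination classes: 12 in bulk, reduced classes on the surface", {
  lat <- build_hex_lattice(n_rings = 4, n_axial = 6)
  expect_identical(coordination_class(lat$sliding, lat), 12L)
  zmid <- sort(unique(lat$xyz[lat$chain != 0, 3]))[3]
  idx <- which(lat$chain != 0 & lat$xyz[, 3] == zmid)
  cc <- vapply(idx, coordination_class, integer(1), lattice = lat)
  # an interior chain bead is coordinated to 6 beads in each adjacent
  # layer (second ring: away from both the surface and the slider's
  # single-bead site, which defines no layer)
  d_pl <- sqrt(lat$xyz[idx, 1]^2 + lat$xyz[idx, 2]^2)
  ring2 <- d_pl > 1.5 * lat$spacing & d_pl < 2.2 * lat$spacing
  expect_true(all(cc[ring2] == 12L))
  expect_true(all(cc %in% c(4L, 6L, 8L, 10L, 12L)))
  expect_true(any(cc == 10L))   # flat-surface beads: 5 per adjacent layer
  # corner bead of the smallest cluster has two neighbour chains
  lat1 <- build_hex_lattice(n_rings = 1, n_axial = 4)
  z1 <- sort(unique(lat1$xyz[lat1$chain != 0, 3]))[2]
  corner <- which(lat1$chain != 0 & lat1$xyz[, 3] == z1)[1]
  expect_identical(coordination_class(corner, lat1), 4L)
})

test_that("under-coordinated (class-10) fraction shrinks with lattice radius", {
  frac10 <- function(nr) {
    lat <- build_hex_lattice(n_rings = nr, n_axial = 6)
    zmid <- sort(unique(lat$xyz[lat$chain != 0, 3]))[3]
    idx <- which(lat$chain != 0 & lat$xyz[, 3] == zmid)
    cc <- vapply(idx, coordination_class, integer(1), lattice = lat)
    mean(cc == 10)
  }
  f <- vapply(c(3, 8, 12), frac10, numeric(1))
  expect_true(all(diff(f) < 0))
})

test_that("XYZ export writes a well-formed coordinate file", {
  lat <- build_hex_lattice(n_rings = 1, n_axial = 4)
  path <- tempfile(fileext = ".xyz")
  write_xyz(lat, path)
  lines <- readLines(path)
  expect_identical(as.integer(lines[1]), nrow(lat$xyz))
  expect_identical(length(lines), nrow(lat$xyz) + 2L)
  fields <- strsplit(lines[3], "\\s+")[[1]]
  expect_identical(fields[1], "S")   # sliding bead listed first
  expect_equal(as.numeric(fields[2:4]), lat$xyz[1, ], ignore_attr = TRUE)
})
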