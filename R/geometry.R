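#' Hexagonal packing coefficient of the fibril cross-section
#'
#' Area fraction of circular molecule cross-sections in an ideal
#' hexagonal lattice cell: `pi / (2 sqrt(3))`, about 90.7%.
#'
#' @return The packing fraction (dimensionless).
#' @export
c_pack <- function() pi / (2 * sqrt(3))

#' Surface-layer correction coefficient
#'
#' Fraction of molecules in a fibril of diameter `phi` that are bulk
#' (fully coordinated) rather than in the one-molecule-thick surface
#' shell: `((phi - 2 D_mol) / phi)^2`.  Surface molecules are not
#' radially confined and do not resist sliding, so only this fraction
#' contributes to the strength of an uncrosslinked fibril.
#'
#' @param phi Fibril diameter (nm); must exceed `2 * D_mol`.
#' @param D_mol Molecule diameter (nm).
#' @return The bulk fraction (dimensionless); increasing in `phi`,
#'   tending to 1.
#' @examples
#' c_surf(20)    # ~0.70
#' c_surf(500)   # ~0.99
#' @export
c_surf <- function(phi, D_mol = 1.652) {
  stopifnot(is.numeric(phi), is.numeric(D_mol), D_mol > 0)
  if (any(phi <= 2 * D_mol))
    stop("`phi` must exceed 2*D_mol (fibril thinner than two molecules)",
         call. = FALSE)
  ((phi - 2 * D_mol) / phi)^2
}

#' Fibril cross-section geometry
#'
#' Bundles the geometric descriptors of a fibril: diameter, axial
#' D-period and gap fraction, molecule diameter, and the derived
#' packing and surface coefficients.  The gap/overlap bookkeeping is
#' stored for reference but does not enter the stress: molecules in the
#' gap region rearrange to a smaller cross-section, leaving the stress
#' equal in both regions.
#'
#' @param phi Fibril diameter (nm), > `2 * D_mol`.
#' @param D_period Axial periodicity (nm); one gap plus one overlap.
#' @param gap_ratio Gap fraction of the D-period, in (0, 1).
#' @param D_mol Molecule diameter (nm).
#' @return An object of class `fibril_geometry` with fields `phi`,
#'   `D_period`, `gap_ratio`, `D_mol`, `c_pack`, `c_surf`.
#' @export
fibril_geometry <- function(phi, D_period = 67, gap_ratio = 0.57,
                            D_mol = 1.652) {
  stopifnot(is.numeric(phi), length(phi) == 1)
  .check_field(gap_ratio > 0 && gap_ratio < 1,
               "`gap_ratio` must lie in (0, 1)")
  .check_field(D_period > 0, "`D_period` must be positive")
  cs <- c_surf(phi, D_mol)  # also validates phi > 2 D_mol
  structure(list(phi = phi, D_period = D_period, gap_ratio = gap_ratio,
                 D_mol = D_mol, c_pack = c_pack(), c_surf = cs),
            class = "fibril_geometry")
}

#' @export
print.fibril_geometry <- function(x, ...) {
  cat(sprintf("Fibril geometry: phi = %g nm, D-period = %g nm (gap ratio %.2f)\n",
              x$phi, x$D_period, x$gap_ratio))
  cat(sprintf("  D_mol = %.3f nm, Cpack = %.4f, Csurf = %.4f\n",
              x$D_mol, x$c_pack, x$c_surf))
  invisible(x)
}

# Hexagonal chain centres within n_rings lattice spacings of the origin.
.hex_centers <- function(n_rings, a) {
  ij <- expand.grid(i = -n_rings:n_rings, j = -n_rings:n_rings)
  x <- a * (ij$i + ij$j / 2)
  y <- a * (sqrt(3) / 2) * ij$j
  keep <- sqrt(x^2 + y^2) <= n_rings * a + 1e-6
  cbind(x = x[keep], y = y[keep])
}

#' Finite hexagonal bead lattice with a designated sliding bead
#'
#' Builds the local environment used for the sliding energy barrier:
#' parallel bead chains on a hexagonal grid in the cross-section plane,
#' in axial register, plus one central sliding bead that forms its own
#' single-bead chain.  Its rest position lies midway between the two
#' central axial planes of the neighbouring chains — the staggered site
#' that minimises the Lennard-Jones energy — and sliding carries it
#' half an axial spacing to the in-plane (coplanar) saddle.
#'
#' @param n_rings Number of hexagonal rings of chains around the centre
#'   (>= 1; >= 2 for barrier work so the first shell is interior).
#' @param n_axial Number of axial planes per chain (>= 3).
#' @param lattice_spacing In-plane chain spacing (Angstrom); defaults
#'   to the LJ minimum distance `2^(1/6) sigma` so the resting lattice
#'   is an energy minimum.
#' @param axial_spacing Axial bead spacing along each chain (Angstrom);
#'   defaults to the bond equilibrium length `r0 = 14`.
#' @return An object of class `bead_lattice`: fields `xyz` (matrix,
#'   Angstrom), `chain` (integer molecule id per bead; the sliding bead
#'   is chain 0), `spacing`, `axial_spacing`, `sliding` (row index of
#'   the sliding bead), `z_low`/`z_high` (rest and saddle axial
#'   positions of the sliding bead).
#' @examples
#' lat <- build_hex_lattice(n_rings = 1, n_axial = 4)
#' length(unique(lat$chain))   # 7: sliding bead + 6 neighbour chains
#' @export
build_hex_lattice <- function(n_rings = 4, n_axial = 16,
                              lattice_spacing = 2^(1 / 6) * 14.72,
                              axial_spacing = 14) {
  stopifnot(n_rings >= 1, n_axial >= 3,
            lattice_spacing > 0, axial_spacing > 0)
  a <- lattice_spacing
  c_ax <- axial_spacing
  centers <- .hex_centers(n_rings, a)
  central <- which(abs(centers[, 1]) < 1e-9 & abs(centers[, 2]) < 1e-9)
  centers <- centers[-central, , drop = FALSE]

  # planes symmetric about z = 0; for even n_axial the two central
  # planes straddle 0 and the sliding bead rests exactly at 0
  z_planes <- (seq_len(n_axial) - (n_axial + 1) / 2) * c_ax
  z_low <- if (n_axial %% 2 == 0) 0 else c_ax / 2
  z_high <- z_low + c_ax / 2

  nc <- nrow(centers)
  xyz <- cbind(
    x = rep(centers[, 1], each = n_axial),
    y = rep(centers[, 2], each = n_axial),
    z = rep(z_planes, times = nc)
  )
  chain <- rep(seq_len(nc), each = n_axial)
  xyz <- rbind(c(0, 0, z_low), xyz)
  chain <- c(0L, chain)

  structure(list(xyz = xyz, chain = as.integer(chain),
                 spacing = a, axial_spacing = c_ax,
                 n_rings = n_rings, n_axial = n_axial,
                 sliding = 1L, z_low = z_low, z_high = z_high),
            class = "bead_lattice")
}

#' Low-level bead lattice constructor
#'
#' Assembles a `bead_lattice` from explicit coordinates, for custom
#' environments (e.g. a single neighbour chain used as an analytic
#' check of the lattice sum).
#'
#' @param xyz Numeric matrix of bead coordinates (Angstrom), one row
#'   per bead.
#' @param chain Integer molecule id per bead; the sliding bead's chain
#'   must contain only itself.
#' @param spacing,axial_spacing In-plane and axial spacings (Angstrom).
#' @param sliding Row index of the sliding bead.
#' @param z_low,z_high Rest and saddle axial positions of the sliding
#'   bead.
#' @return A `bead_lattice` object.
#' @export
bead_lattice <- function(xyz, chain, spacing, axial_spacing,
                         sliding, z_low, z_high) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(chain),
            sliding >= 1, sliding <= nrow(xyz))
  if (sum(chain == chain[sliding]) != 1)
    stop("the sliding bead must be the only bead of its chain", call. = FALSE)
  colnames(xyz) <- c("x", "y", "z")
  structure(list(xyz = xyz, chain = as.integer(chain),
                 spacing = spacing, axial_spacing = axial_spacing,
                 n_rings = NA_integer_, n_axial = NA_integer_,
                 sliding = as.integer(sliding),
                 z_low = z_low, z_high = z_high),
            class = "bead_lattice")
}

#' @export
print.bead_lattice <- function(x, ...) {
  cat(sprintf("Hexagonal bead lattice: %d beads in %d chains (spacing %.2f A, axial %.2f A)\n",
              nrow(x$xyz), length(unique(x$chain)), x$spacing, x$axial_spacing))
  cat(sprintf("  sliding bead #%d rests at z = %.2f A; saddle at z = %.2f A\n",
              x$sliding, x$z_low, x$z_high))
  invisible(x)
}

#' Coordination class of a bead
#'
#' Number of nearest neighbours a bead has in the two adjacent axial
#' layers (those one axial half- or full spacing away, depending on the
#' bead's registration): 6 per layer for a bulk bead (12 total), fewer
#' on the fibril surface (10, 8, 6 or 4).  Beads with 8 or fewer
#' neighbours are not radially confined and cross no barrier when they
#' slide.
#'
#' @param bead Row index of the bead in `lattice$xyz`.
#' @param lattice A [build_hex_lattice()] result.
#' @return Integer neighbour count (2 x adjacent chains within one
#'   in-plane spacing).
#' @export
coordination_class <- function(bead, lattice) {
  stopifnot(inherits(lattice, "bead_lattice"),
            bead >= 1, bead <= nrow(lattice$xyz))
  xyz <- lattice$xyz
  p <- xyz[bead, ]
  # neighbour candidates: beads of other full chains (a designated
  # sliding bead forms a single-bead chain and defines no layer)
  tab <- table(lattice$chain)
  full <- lattice$chain %in% as.integer(names(tab)[tab > 1])
  other <- lattice$chain != lattice$chain[bead] & full
  d_plane <- sqrt((xyz[other, 1] - p[1])^2 + (xyz[other, 2] - p[2])^2)
  dz <- abs(xyz[other, 3] - p[3])
  # adjacent layers: nearest nonzero axial offset among in-plane neighbours
  near <- d_plane <= 1.1 * lattice$spacing
  if (!any(near)) return(0L)
  dz_adj <- min(dz[near & dz > 1e-6])
  as.integer(sum(near & abs(dz - dz_adj) < 1e-6) * 1L)
}

#' Write a bead lattice as an XYZ coordinate file
#'
#' Plain XYZ format (atom count, comment line, then one
#' `element x y z` row per bead) for inspection in molecular viewers.
#' Chains are distinguished by cycling element tags; the sliding bead
#' is tagged `S`.
#'
#' @param lattice A [build_hex_lattice()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_xyz <- function(lattice, path) {
  stopifnot(inherits(lattice, "bead_lattice"))
  tags <- c("C", "N", "O", "P", "B", "F")
  el <- tags[(lattice$chain %% length(tags)) + 1]
  el[lattice$sliding] <- "S"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(lattice$xyz)),
               "coarse-grained collagen bead lattice (Angstrom)"), con)
  writeLines(sprintf("%s %12.6f %12.6f %12.6f", el,
                     lattice$xyz[, 1], lattice$xyz[, 2], lattice$xyz[, 3]),
             con)
  invisible(path)
}
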