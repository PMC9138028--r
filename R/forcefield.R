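#' Continuity constants of the hyperelastic bond law
#'
#' The bond potential has three branches: harmonic about `r0` up to
#' `r1`, a stiffer harmonic about a shifted centre `r1_bar` up to the
#' breaking distance `rb`, and a constant beyond.  `r1_bar` and `C1`
#' are fixed by force and energy continuity at `r1`; `C2` by energy
#' continuity at `rb` (the force drops to zero there — the bond breaks).
#'
#' @param params A [molecule_params()] or [crosslink_params()] object
#'   (anything with fields `r0`, `r1`, `rb`, `KT0`, `KT1`).
#' @return An object of class `bond_law_constants` with fields
#'   `r1_bar`, `C1`, `C2` (kcal/mol and Angstrom).
#' @export
bond_law_constants <- function(params) {
  stopifnot(is.list(params),
            all(c("r0", "r1", "rb", "KT0", "KT1") %in% names(params)))
  r1_bar <- params$r1 - (params$KT0 / params$KT1) * (params$r1 - params$r0)
  C1 <- params$KT0 / 2 * (params$r1 - params$r0)^2 -
        params$KT1 / 2 * (params$r1 - r1_bar)^2
  C2 <- params$KT1 / 2 * (params$rb - r1_bar)^2 + C1
  structure(list(r1_bar = r1_bar, C1 = C1, C2 = C2),
            class = "bond_law_constants")
}

#' Bond potential energy
#'
#' Three-branch hyperelastic bond energy (kcal/mol): `KT0/2 (r-r0)^2`
#' for `r <= r1`, `KT1/2 (r-r1_bar)^2 + C1` for `r1 < r <= rb`, and the
#' constant `C2` beyond `rb` (broken bond).  Energy is continuous
#' everywhere; force is continuous except at `rb`.
#'
#' @param r Bond length(s), Angstrom; must be positive.
#' @param params A [molecule_params()] or [crosslink_params()] object.
#' @return Energy in kcal/mol (vectorised over `r`).
#' @export
bond_energy <- function(r, params) {
  stopifnot(is.numeric(r), all(r > 0))
  k <- bond_law_constants(params)
  e <- ifelse(r <= params$r1,
              params$KT0 / 2 * (r - params$r0)^2,
              ifelse(r <= params$rb,
                     params$KT1 / 2 * (r - k$r1_bar)^2 + k$C1,
                     k$C2))
  e
}

#' Bond force (dE/dr)
#'
#' @inheritParams bond_energy
#' @return Force in kcal mol^-1 A^-1 (vectorised); zero beyond `rb`.
#' @export
bond_force <- function(r, params) {
  stopifnot(is.numeric(r), all(r > 0))
  k <- bond_law_constants(params)
  ifelse(r <= params$r1,
         params$KT0 * (r - params$r0),
         ifelse(r <= params$rb,
                params$KT1 * (r - k$r1_bar),
                0))
}

#' Bending (angle) potential energy
#'
#' Harmonic three-body bending term `Ktheta (theta - theta0)^2` between
#' three consecutive beads.  Note the convention carries no 1/2 factor.
#'
#' @param theta Actual angle(s), radians, in (0, pi].
#' @param theta0 Equilibrium angle, radians.
#' @param params A [molecule_params()] object (supplies `Ktheta`).
#' @return Energy in kcal/mol.
#' @export
angle_energy <- function(theta, theta0, params) {
  stopifnot(is.numeric(theta), all(theta > 0), all(theta <= pi + 1e-12))
  params$Ktheta * (theta - theta0)^2
}

#' Lennard-Jones 12-6 potential and force
#'
#' Intermolecular bead-bead interaction `4 eps ((sigma/r)^12 -
#' (sigma/r)^6)`; minimum of depth `-epsilon` at `r = 2^(1/6) sigma`.
#' No cutoff is applied here; cutoffs belong to the lattice summation.
#'
#' @param r Separation(s), Angstrom; must be positive.
#' @param lj An [lj_params()] object.
#' @return `lj_energy`: energy in kcal/mol; `lj_force`: dE/dr in
#'   kcal mol^-1 A^-1 (negative where attractive force increases with r).
#' @export
lj_energy <- function(r, lj) {
  stopifnot(is.numeric(r), all(r > 0), inherits(lj, "lj_params"))
  s6 <- (lj$sigma / r)^6
  4 * lj$epsilon * (s6^2 - s6)
}

#' @rdname lj_energy
#' @export
lj_force <- function(r, lj) {
  stopifnot(is.numeric(r), all(r > 0), inherits(lj, "lj_params"))
  s6 <- (lj$sigma / r)^6
  # dE/dr = -24 eps (2 (sigma/r)^12 - (sigma/r)^6) / r
  -24 * lj$epsilon * (2 * s6^2 - s6) / r
}
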