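#' End state of the uncoiling (unfolding) stage
#'
#' A resting tropocollagen molecule is a kinked chain: its contour
#' length `n * r0` exceeds the end-to-end length `L0`, and a tensile
#' load first straightens the bead angles before any appreciable bond
#' stretching.  The stage ends at engineering strain
#' `eps1 = n r0 / L0 - 1`.  The peak force during straightening sits at
#' the most misaligned site: a bending torque `2 Ktheta (theta_max -
#' theta0)` acting over the two-bond span `2 r0`, i.e.
#' `F1 = Ktheta * d_theta / r0` with `d_theta = 180 deg - theta0_min`
#' (16 deg by default).
#'
#' @param params A [molecule_params()] object.
#' @return A list with `eps1` (strain), `F1_N` (force, N), `sigma1_Pa`
#'   (stress, Pa) and `E1_Pa` (stage modulus `sigma1/eps1`, Pa).
#' @examples
#' unfolding_endpoint(molecule_params())$eps1   # ~0.0136
#' @export
unfolding_endpoint <- function(params) {
  stopifnot(inherits(params, "molecule_params"))
  eps1 <- params$n_beads * params$r0 / params$L0 - 1
  if (eps1 <= 0)
    stop("contour length n*r0 must exceed L0 (molecule cannot be pre-stretched)",
         call. = FALSE)
  d_theta <- .deg2rad(180 - params$theta0_min)
  f1 <- 2 * params$Ktheta * d_theta / (2 * params$r0)  # kcal/mol/A
  F1_N <- force_kcalmolA_to_N(f1)
  sigma1 <- F1_N / molecule_area(params)
  list(eps1 = eps1, F1_N = F1_N, sigma1_Pa = sigma1, E1_Pa = sigma1 / eps1)
}

# Stage moduli from the bond stiffnesses: E = K * L0 / (n * A_mol),
# with K converted from kcal/mol/A^2 to N/m.
.stage_modulus <- function(K, params) {
  K_SI <- force_kcalmolA_to_N(K) / 1e-10           # N/m
  K_SI * (params$L0 * 1e-10) / (params$n_beads * molecule_area(params))
}

#' Analytical stress-strain law of a single tropocollagen molecule
#'
#' Builds the three-regime piecewise-linear curve: (i) uncoiling up to
#' `eps1 = n r0 / L0 - 1`; (ii) backbone stretching on the soft bond
#' branch up to `eps2 = n r1 / L0 - 1`, slope `KT0 L0 / (n A_mol)`;
#' (iii) hyperelastic stretching on the stiff branch up to
#' `eps3 = n rb / L0 - 1`, slope `KT1 L0 / (n A_mol)`; beyond `eps3`
#' the bonds break and the stress is zero.  Stage stresses superpose
#' the unfolding stress additively: `sigma = sigma1 + F / A_mol`.
#'
#' @param params A [molecule_params()] object.
#' @return A [stress_strain_curve()] with four segments.
#' @examples
#' mc <- molecule_curve(molecule_params())
#' evaluate_curve(mc, 0.3) / 1e9   # GPa a little below the hyperelastic onset
#' @export
molecule_curve <- function(params = molecule_params()) {
  stopifnot(inherits(params, "molecule_params"))
  u <- unfolding_endpoint(params)
  A <- molecule_area(params)
  k <- bond_law_constants(params)

  eps2 <- params$n_beads * params$r1 / params$L0 - 1
  eps3 <- params$n_beads * params$rb / params$L0 - 1
  F2 <- force_kcalmolA_to_N(params$KT0 * (params$r1 - params$r0))
  F3 <- force_kcalmolA_to_N(params$KT1 * (params$rb - k$r1_bar))
  sigma2 <- u$sigma1_Pa + F2 / A
  sigma3 <- u$sigma1_Pa + F3 / A

  seg <- data.frame(
    label = c("unfold", "stretch_pre_hyper", "stretch_post_hyper", "drop"),
    eps_start = c(0, u$eps1, eps2, eps3),
    eps_end = c(u$eps1, eps2, eps3, Inf),
    sigma_start = c(0, u$sigma1_Pa, sigma2, 0),
    modulus = c(u$E1_Pa,
                .stage_modulus(params$KT0, params),
                .stage_modulus(params$KT1, params),
                0),
    stringsAsFactors = FALSE
  )
  stress_strain_curve(seg, metadata = list(model = "molecule"))
}
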